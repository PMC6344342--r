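test_that("trend test: identical distributions give X2 = 0, p = 1", {
  r <- chi_square_trend(rbind(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
})

test_that("trend test matches the closed form, an independent implementation,
           and is label-symmetric", {
  cnt <- rbind(c(10, 5, 1), c(4, 6, 8))
  r <- chi_square_trend(cnt)
  expect_equal(unname(r$statistic), 7.965397, tolerance = 1e-6)
  expect_equal(r$p.value, 0.004768, tolerance = 1e-4)
  # cross-check against stats::prop.trend.test (same statistic family)
  pt <- stats::prop.trend.test(cnt[1, ], colSums(cnt), score = 0:2)
  expect_equal(unname(r$statistic), unname(pt$statistic), tolerance = 1e-10)
  expect_equal(r$p.value, pt$p.value, tolerance = 1e-10)
  # swapping groups changes nothing
  r2 <- chi_square_trend(cnt[2:1, ])
  expect_equal(unname(r2$statistic), unname(r$statistic))
  expect_equal(r2$p.value, r$p.value)
})

test_that("trend statistic is invariant to affine rescaling of the scores", {
  set.seed(17)
  for (i in 1:10) {
    cnt <- matrix(rpois(8, 6) + 1, 2, 4)
    base <- chi_square_trend(cnt)$statistic
    a <- runif(1, 0.2, 5) * sample(c(-1, 1), 1); b <- runif(1, -10, 10)
    scaled <- chi_square_trend(cnt, scores = a * (0:3) + b)$statistic
    expect_equal(unname(scaled), unname(base), tolerance = 1e-10)
  }
})

# Agreement between the asymptotic chi-square p and the discrete
# margin-conditioned permutation p is tested on small tables with a clear
# trend; for mid-range p (~0.05-0.15) at N <= 30 the permutation null's tie
# mass alone exceeds the comparison band, so no implementation could agree
# there (see the methods vignette).
test_that("chi-square p agrees with a margin-conditioned permutation p on
           small trending tables", {
  tables <- list(rbind(c(6, 3, 1), c(2, 4, 6)),
                 rbind(c(10, 5, 1), c(4, 6, 8)),
                 rbind(c(8, 4, 2, 1), c(2, 3, 4, 6)))
  for (i in seq_along(tables)) {
    p_chi <- chi_square_trend(tables[[i]])$p.value
    p_perm <- perm_trend_p(tables[[i]], B = 2e4, seed = 100 + i)
    expect_lt(abs(p_chi - p_perm), 0.02)
  }
})

test_that("trend test rejects empty groups and degenerate scores", {
  expect_error(chi_square_trend(rbind(c(0, 0, 0), c(1, 2, 3))), "empty group")
  expect_error(chi_square_trend(rbind(c(0, 4, 0), c(0, 6, 0))),
               "degenerate scores")
})

test_that("compare_groups pools per-image histograms by bin and rejects
           mismatched bin specifications", {
  mk <- function(r, edges = c(0, 10, 20, 30))
    bin_histogram(measure_droplets(fake_circles(r), 1), edges)
  fake_circles <- function(r) data.frame(cy = 1, cx = 1, r = r, score = 1)
  # identical groups -> p = 1
  a <- mk(c(2, 6, 12)); b <- mk(c(2, 6, 12))
  expect_equal(compare_groups(list(a), list(b))$p.value, 1)
  # pooling adds counts bin-wise
  h1 <- mk(c(2, 6)); h2 <- mk(c(3, 7, 8, 12))
  pooled <- compare_groups(list(h1, h2), list(mk(c(2, 12))), labels = c("A", "B"))
  expect_s3_class(pooled, "htest")
  expect_error(compare_groups(list(mk(2)), list(mk(2, edges = c(0, 15, 30)))),
               "incompatible histograms")
})

test_that("stained-area fraction obeys its exact and additivity properties", {
  img <- array(0, c(100, 100, 3))
  img[, , 1][1:2500] <- 200                       # 2500 of 10000 red-positive
  expect_equal(positive_area_fraction(img, "red", ">=", 180), 0.25)
  expect_equal(positive_area_fraction(img, "red", ">=", 0), 1)
  expect_equal(positive_area_fraction(img, "red", ">", 255), 0)
  # permutation invariance
  set.seed(4)
  g <- matrix(sample(0:255, 400, TRUE), 20, 20)
  perm <- matrix(sample(g), 20, 20)
  expect_equal(positive_area_fraction(g, threshold = 99),
               positive_area_fraction(perm, threshold = 99))
  # additivity over a disjoint partition, weighted by pixel counts
  top <- g[1:8, , drop = FALSE]; bottom <- g[9:20, , drop = FALSE]
  f <- positive_area_fraction
  expect_equal(f(g, threshold = 99),
               (160 * f(top, threshold = 99) + 240 * f(bottom, threshold = 99)) / 400)
  # multi-image mean weights fields equally
  expect_equal(mean_positive_area_fraction(list(top, top, bottom), threshold = 99),
               (2 * f(top, threshold = 99) + f(bottom, threshold = 99)) / 3)
})

test_that("summary t test reproduces the closed form and Welch df", {
  r <- summary_ttest(10, 1, 6, 13, 1, 6)
  expect_equal(unname(r$statistic), -3 / sqrt(2), tolerance = 1e-6)
  expect_equal(unname(r$parameter), 10)
  expect_equal(r$p.value, 2 * pt(-3 / sqrt(2), 10), tolerance = 1e-10)
  expect_equal(r$p.value, 0.0599, tolerance = 1e-3)
  ident <- summary_ttest(7, 1.3, 5, 7, 1.3, 5)
  expect_equal(unname(ident$statistic), 0)
  expect_equal(ident$p.value, 1)
  expect_error(summary_ttest(1, 1, 1, 2, 1, 6), "insufficient group size")
})
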