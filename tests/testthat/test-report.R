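fake_circles <- function(r) data.frame(cy = seq_along(r), cx = seq_along(r),
                                       r = r, score = rep(1, length(r)))

test_that("diameter and area follow the calibration formulas exactly", {
  rec <- measure_droplets(fake_circles(10), 1)
  expect_equal(rec$diameter_um, 20)
  expect_equal(rec$area_um2, pi * 100)
  rec <- measure_droplets(fake_circles(10), 0.5)
  expect_equal(rec$diameter_um, 10)
  expect_equal(rec$area_um2, pi * 25)
  expect_error(measure_droplets(fake_circles(10), 0), "invalid calibration")
  # area strictly increasing in r for fixed calibration
  rec <- measure_droplets(fake_circles(1:20), 0.7)
  expect_true(all(diff(rec$area_um2) > 0))
  expect_equal(rec$droplet_id, 1:20)
})

test_that("histogram bins are half-open with explicit under/overflow", {
  rec <- measure_droplets(fake_circles(c(2, 6, 12.5)), 1)  # diameters 4, 12, 25
  h <- bin_histogram(rec, c(0, 10, 20, 30))
  expect_equal(h$counts, c(1L, 1L, 1L))
  expect_equal(h$underflow + h$overflow, 0L)
  # value exactly on an internal edge falls in the upper bin
  h <- bin_histogram(measure_droplets(fake_circles(5), 1), c(0, 10, 20))
  expect_equal(h$counts, c(0L, 1L))
  # beyond the last edge -> overflow
  h <- bin_histogram(measure_droplets(fake_circles(17.5), 1), c(0, 10, 20, 30))
  expect_equal(h$overflow, 1L)
  expect_equal(sum(h$counts) + h$underflow + h$overflow, h$total)
  expect_error(bin_histogram(rec, c(0, 10, 10, 30)), "invalid bin specification")
})

test_that("histogram counts are conserved and order-invariant", {
  set.seed(31)
  r <- runif(200, 1, 40)
  rec <- measure_droplets(fake_circles(r), 1)
  edges <- c(10, 25, 40, 60)
  h1 <- bin_histogram(rec, edges)
  h2 <- bin_histogram(rec[sample(200), ], edges)
  expect_equal(h1$counts, h2$counts)
  expect_equal(sum(h1$counts) + h1$underflow + h1$overflow, 200L)
})

test_that("steatosis summary aggregates correctly, including the empty case", {
  rec <- measure_droplets(fake_circles(c(5, 10)), 1)  # diameters 10, 20
  s <- droplet_summary(rec, 1e4)
  expect_equal(s$count, 2)
  expect_equal(s$mean_diameter_um, 15)
  expect_equal(s$area_fraction, sum(rec$area_um2) / 1e4)
  expect_equal(s$density_per_mm2, 2 / (1e4 / 1e6))
  e <- droplet_summary(rec[0, ], 1e4)
  expect_equal(e$count, 0)
  expect_equal(e$area_fraction, 0)
  expect_equal(e$density_per_mm2, 0)
  expect_error(droplet_summary(rec, 0), "invalid image area")
})

test_that("reports round-trip through CSV + JSON to 6 decimal places", {
  set.seed(8)
  rec <- measure_droplets(fake_circles(sample(3:25, 12, TRUE)), 0.466,
                          image_id = "im1")
  rec$score <- runif(12)
  h <- bin_histogram(rec, c(0, 10, 20, 30))
  s <- droplet_summary(rec, 256 * 256 * 0.466^2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_droplet_report(rec, h, s, f)
  back <- read_droplet_report(f)
  for (col in c("diameter_um", "area_um2", "score"))
    expect_equal(back$records[[col]], rec[[col]], tolerance = 1e-6)
  expect_equal(back$records$r_px, rec$r_px)
  expect_identical(back$histogram$counts, h$counts)
  expect_equal(back$histogram$edges, h$edges)
  expect_equal(back$summary$count, s$count)
})

test_that("empty reports and malformed files are handled", {
  rec <- measure_droplets(fake_circles(numeric(0)), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_droplet_report(rec, NULL, NULL, f)
  back <- read_droplet_report(f)
  expect_equal(nrow(back$records), 0)
  # missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,droplet_id,cy,cx", "a,1,2,3"), bad)
  expect_error(read_droplet_report(bad), "report parse error")
  # non-numeric field, error names the line
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,droplet_id,cy,cx,r_px,score,diameter_um,area_um2",
               "a,1,2,3,10,0.5,20.0,314.159265",
               "a,2,2,3,oops,0.5,20.0,314.159265"), bad2)
  expect_error(read_droplet_report(bad2), "report parse error.*line 3")
})
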