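#' Chi-square test for trend (Cochran-Armitage)
#'
#' One-degree-of-freedom chi-square test for a monotone shift across
#' ordered size bins between two groups — the standard way droplet
#' size-distribution differences are tested (and the meaning of
#' "chi-square test for trend" in GraphPad Prism).  For a 2 x K table
#' with group-1 counts \eqn{n_{1k}}, row totals \eqn{R_1, R_2}, column
#' totals \eqn{C_k}, grand total \eqn{N} and bin scores \eqn{s_k}:
#' \deqn{X^2 = \frac{N\,(N \sum_k s_k n_{1k} - R_1 \sum_k s_k C_k)^2}
#'   {R_1 R_2 \,(N \sum_k s_k^2 C_k - (\sum_k s_k C_k)^2)}}
#' with the population-variance (divide-by-N) form in the denominator,
#' referred to the upper tail of \eqn{\chi^2_1}.  Equally spaced integer
#' scores `0:(K-1)` are the default; the statistic is invariant to any
#' affine rescaling of the scores.
#'
#' @param counts 2 x K matrix of non-negative counts (rows = groups,
#'   columns = ordered bins), K >= 2.
#' @param scores Numeric bin scores, default `0:(K-1)`.
#' @param labels Optional group labels (for printing).
#' @return An object of class `htest` with `statistic` (X-squared),
#'   `parameter` (df = 1) and `p.value`.
#' @examples
#' chi_square_trend(rbind(c(10, 5, 1), c(4, 6, 8)))
#' @export
chi_square_trend <- function(counts, scores = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L)
    stop("counts must be a 2 x K matrix with K >= 2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  K <- ncol(counts)
  if (is.null(scores)) scores <- seq_len(K) - 1
  if (length(scores) != K) stop("need one score per bin", call. = FALSE)
  R <- rowSums(counts)
  if (any(R == 0)) stop("empty group: both row totals must be >= 1", call. = FALSE)
  Ck <- colSums(counts)
  N <- sum(Ck)
  occupied <- Ck > 0
  if (length(unique(scores[occupied])) < 2L)
    stop("degenerate scores: no score variance across occupied bins",
         call. = FALSE)
  R <- unname(R)
  num <- N * sum(scores * counts[1, ]) - R[1] * sum(scores * Ck)
  den <- R[1] * R[2] * (N * sum(scores^2 * Ck) - sum(scores * Ck)^2)
  stat <- N * num^2 / den
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- c("group 1", "group 2")
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = 1),
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "Chi-square test for trend (Cochran-Armitage)",
                 data.name = paste(labels, collapse = " vs ")),
            class = "htest")
}

#' Compare two groups of droplet-size histograms by trend test
#'
#' Pools each group's per-image histograms by summing bin counts (the
#' droplet is the counting unit, matching per-droplet distribution
#' figures) and applies [chi_square_trend()] with default equally spaced
#' scores.  Only the K shared bins enter the test; underflow and
#' overflow lie outside the specified size ranges and are excluded.
#'
#' @param reports_a,reports_b Lists of [bin_histogram()] results (one
#'   per image); all must share the same field and bin edges.
#' @param scores Optional bin scores passed to [chi_square_trend()].
#' @param labels Group labels, default `c("A", "B")`.
#' @return An `htest` as from [chi_square_trend()].
#' @export
compare_groups <- function(reports_a, reports_b, scores = NULL,
                           labels = c("A", "B")) {
  if (inherits(reports_a, "droplet_histogram")) reports_a <- list(reports_a)
  if (inherits(reports_b, "droplet_histogram")) reports_b <- list(reports_b)
  all_h <- c(reports_a, reports_b)
  if (!length(reports_a) || !length(reports_b))
    stop("each group needs at least one histogram", call. = FALSE)
  ref <- all_h[[1]]
  for (h in all_h) {
    if (!inherits(h, "droplet_histogram"))
      stop("incompatible histograms: inputs must be droplet_histogram objects",
           call. = FALSE)
    if (!identical(h$field, ref$field) || !isTRUE(all.equal(h$edges, ref$edges)))
      stop("incompatible histograms: all inputs must share one bin specification",
           call. = FALSE)
  }
  pool <- function(hs) Reduce(`+`, lapply(hs, `[[`, "counts"))
  counts <- rbind(pool(reports_a), pool(reports_b))
  rownames(counts) <- labels
  chi_square_trend(counts, scores = scores, labels = labels)
}

#' Positively stained area fraction
#'
#' Fraction of pixels satisfying a simple colour rule — the generic
#' stained-area quantification used for e.g. Picrosirius red (collagen)
#' or F4/80 (macrophage) readouts: positive pixels / total pixels.
#' Either supply a rule (`channel`, `comparator`, `threshold`) applied
#' to the image, or a precomputed logical mask.
#'
#' @param img RGB array or grayscale matrix (0--255).
#' @param channel `"red"`, `"green"`, `"blue"` or `"luminance"`
#'   (grayscale input uses its single channel regardless).
#' @param comparator One of `">="`, `">"`, `"<="`, `"<"`.
#' @param threshold Intensity cut on the 0--255 scale.
#' @param mask Optional logical matrix overriding the colour rule.
#' @return Fraction in `[0, 1]`.
#' @examples
#' img <- array(200, c(10, 10, 3))
#' positive_area_fraction(img, "red", ">=", 180)  # 1
#' @export
positive_area_fraction <- function(img, channel = c("red", "green", "blue",
                                                    "luminance"),
                                   comparator = c(">=", ">", "<=", "<"),
                                   threshold = 128, mask = NULL) {
  check_image(img)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2]))
      stop("mask must be a logical matrix matching the image grid", call. = FALSE)
    return(mean(mask))
  }
  channel <- match.arg(channel)
  comparator <- match.arg(comparator)
  x <- if (is_gray_image(img)) img
       else switch(channel,
                   red = img[, , 1L], green = img[, , 2L], blue = img[, , 3L],
                   luminance = to_luminance(img))
  mean(switch(comparator,
              ">=" = x >= threshold, ">" = x > threshold,
              "<=" = x <= threshold, "<" = x < threshold))
}

#' Mean stained-area fraction over several fields
#'
#' The per-section readout is conventionally the average of per-field
#' fractions over a few independently imaged areas; each image is
#' weighted equally regardless of size.
#'
#' @param imgs List of images.
#' @param ... Passed to [positive_area_fraction()].
#' @return Mean of the per-image fractions.
#' @export
mean_positive_area_fraction <- function(imgs, ...) {
  if (!length(imgs)) stop("invalid image: need at least one image", call. = FALSE)
  mean(vapply(imgs, positive_area_fraction, numeric(1), ...))
}

#' Two-sample t test from published summary statistics
#'
#' Welch-style t test computed from group means, SEMs and sizes — the
#' form needed to re-test published "mean +/- SEM (n)" values:
#' \eqn{t = (m_1 - m_2) / \sqrt{se_1^2 + se_2^2}} with
#' Welch-Satterthwaite degrees of freedom
#' \eqn{(se_1^2 + se_2^2)^2 / (se_1^4/(n_1-1) + se_2^4/(n_2-1))}
#' and a two-tailed p value.
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Standard errors of the means (>= 0, not both 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return An `htest` with `statistic` (t), `parameter` (df), `p.value`.
#' @examples
#' summary_ttest(10, 1, 6, 13, 1, 6)
#' @export
summary_ttest <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2)
    stop("insufficient group size: need n >= 2 in both groups", call. = FALSE)
  if (sem1 < 0 || sem2 < 0 || (sem1 == 0 && sem2 == 0))
    stop("SEMs must be >= 0 and not both zero", call. = FALSE)
  v <- sem1^2 + sem2^2
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(t), df),
                 estimate = c("mean difference" = mean1 - mean2),
                 method = "Welch two-sample t test from summary statistics",
                 data.name = sprintf("mean %g (SEM %g, n %d) vs mean %g (SEM %g, n %d)",
                                     mean1, sem1, n1, mean2, sem2, n2)),
            class = "htest")
}
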