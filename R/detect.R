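#' Detect lipid droplets in a histology image
#'
#' The full detection pipeline: luminance conversion ([to_luminance()]),
#' vacuole segmentation ([segment_vacuoles()]), circular Hough transform
#' with non-maximum suppression ([hough_circles()]) and geometric
#' filtering ([filter_droplets()]).  Fully deterministic for a fixed
#' image and parameter set.
#'
#' @param img RGB array or grayscale matrix (0--255), e.g. from
#'   [load_image()].
#' @param params [detection_params()].
#' @param um_per_px Optional pixel calibration carried into the result
#'   for later measurement (see [measure_droplets()]).
#' @param image_id Identifier recorded with the detection (defaults to
#'   `"image"`).
#' @return Object of class `droplet_detection`: a list with `circles`
#'   (`data.frame`: `cy`, `cx`, `r`, `score`; 0-based centres),
#'   `params`, `dim`, `um_per_px`, `image_id` and per-stage counts
#'   (`n_candidates` before filtering).
#' @examples
#' spec <- synthetic_spec(n_droplets = 5, seed = 7)
#' truth <- sample_ground_truth(spec)
#' img <- render_image(truth, spec)
#' det <- detect_droplets(img)
#' det
#' @export
detect_droplets <- function(img, params = detection_params(),
                            um_per_px = 1, image_id = "image") {
  check_image(img)
  gray <- to_luminance(img)
  mask <- segment_vacuoles(gray, params)
  cand <- hough_circles(mask, params)
  circles <- filter_droplets(cand, mask, params)
  structure(list(circles = circles, params = params,
                 dim = dim(gray), um_per_px = calibration(um_per_px),
                 image_id = image_id,
                 n_mask_px = sum(mask), n_candidates = nrow(cand)),
            class = "droplet_detection")
}

#' @export
print.droplet_detection <- function(x, ...) {
  cat(sprintf("Droplet detection: %s (%d x %d px, %.3g um/px)\n",
              x$image_id, x$dim[1], x$dim[2], x$um_per_px))
  cat(sprintf("  %d droplets kept (of %d Hough candidates; %d mask px)\n",
              nrow(x$circles), x$n_candidates, x$n_mask_px))
  if (nrow(x$circles) > 0L) {
    cat(sprintf("  radius range %d..%d px, median score %.2f\n",
                min(x$circles$r), max(x$circles$r),
                stats::median(x$circles$score)))
  }
  invisible(x)
}

#' @export
summary.droplet_detection <- function(object, ...) {
  rec <- measure_droplets(object$circles, object$um_per_px, object$image_id)
  area <- prod(object$dim) * unclass(object$um_per_px)^2
  droplet_summary(rec, area)
}

#' @export
as.data.frame.droplet_detection <- function(x, ...) x$circles

#' Plot detected droplets over the source image
#'
#' @param x A `droplet_detection`.
#' @param img Optional image to draw under the circles (the detection
#'   does not keep pixel data); omitted, only circle outlines are drawn.
#' @param ... Passed to [graphics::symbols()].
#' @export
plot.droplet_detection <- function(x, img = NULL, ...) {
  h <- x$dim[1]; w <- x$dim[2]
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "col (px)", ylab = "row (px)",
                 main = sprintf("%s: %d droplets", x$image_id, nrow(x$circles)))
  if (!is.null(img)) {
    check_image(img)
    graphics::rasterImage(grDevices::as.raster(pmin(pmax(img / 255, 0), 1)),
                          0, h, w, 0)
  }
  if (nrow(x$circles) > 0L)
    graphics::symbols(x$circles$cx, x$circles$cy, circles = x$circles$r,
                      inches = FALSE, add = TRUE, fg = "red", ...)
  invisible(x)
}
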