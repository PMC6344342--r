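#' Droplet-detection parameters
#'
#' Bundles every tunable of the detection pipeline.  The source method is
#' described only as Hough-transform based, so these knobs and their
#' defaults are this package's own design; the defaults are sized for
#' typical mouse-liver vacuoles at common scan resolutions (roughly
#' 3--60 um diameter at 0.5--1 um/px).
#'
#' @param r_min,r_max Radius search range in pixels; `2 <= r_min < r_max`.
#' @param r_step Radius step in pixels (integer grid; sub-pixel refinement
#'   is deliberately not done so results stay exactly reproducible).
#' @param vote_threshold Minimum normalized Hough score, as the fraction
#'   of the ideal rasterized perimeter supported by mask boundary pixels;
#'   0.5 means at least half the rim must be present.
#' @param nms_center_factor Non-maximum suppression radius factor: a
#'   candidate is suppressed when its centre lies within
#'   `nms_center_factor * (r_kept + r_candidate)` of an already-kept circle.
#' @param fill_min Minimum fraction of in-image disk pixels that must be
#'   mask-positive; rejects rim-only artifacts such as sinusoids.
#' @param border_inside_min Minimum fraction of the disk that must lie
#'   inside the image; excludes clipped edge droplets, as is common
#'   practice in histology quantification.
#' @param segmentation `"otsu"` for Otsu's threshold on the luminance
#'   histogram, or a single number for a fixed threshold (0--255 scale).
#' @param min_component_px Connected components (4-connectivity) smaller
#'   than this many pixels are removed from the vacuole mask.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(r_min = 3L, r_max = 30L, r_step = 1L,
                             vote_threshold = 0.5, nms_center_factor = 0.75,
                             fill_min = 0.6, border_inside_min = 0.9,
                             segmentation = "otsu", min_component_px = 9L) {
  r_min <- as.integer(r_min); r_max <- as.integer(r_max)
  r_step <- as.integer(r_step)
  if (is.na(r_min) || r_min < 2L) stop("r_min must be >= 2", call. = FALSE)
  if (is.na(r_max) || r_max <= r_min) stop("r_max must exceed r_min", call. = FALSE)
  if (is.na(r_step) || r_step < 1L) stop("r_step must be >= 1", call. = FALSE)
  stopifnot(vote_threshold > 0, vote_threshold <= 1,
            fill_min > 0, fill_min <= 1,
            border_inside_min > 0, border_inside_min <= 1,
            nms_center_factor > 0, min_component_px >= 0)
  if (!(identical(segmentation, "otsu") ||
        (is.numeric(segmentation) && length(segmentation) == 1L &&
         is.finite(segmentation))))
    stop("segmentation must be \"otsu\" or a single fixed threshold",
         call. = FALSE)
  structure(list(r_min = r_min, r_max = r_max, r_step = r_step,
                 vote_threshold = vote_threshold,
                 nms_center_factor = nms_center_factor,
                 fill_min = fill_min, border_inside_min = border_inside_min,
                 segmentation = segmentation,
                 min_component_px = as.integer(min_component_px)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Droplet detection parameters\n")
  cat(sprintf("  radius search: %d..%d px (step %d)\n", x$r_min, x$r_max, x$r_step))
  seg <- if (identical(x$segmentation, "otsu")) "Otsu"
         else sprintf("fixed threshold %.1f", x$segmentation)
  cat(sprintf("  segmentation: %s, min component %d px\n", seg, x$min_component_px))
  cat(sprintf("  vote threshold %.2f | NMS factor %.2f | fill >= %.2f | inside >= %.2f\n",
              x$vote_threshold, x$nms_center_factor, x$fill_min, x$border_inside_min))
  invisible(x)
}
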