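#' Segment candidate lipid vacuoles
#'
#' Lipid vacuoles are unstained and therefore bright in H&E sections:
#' the candidate mask is simply the pixels whose luminance exceeds a
#' threshold, with tiny connected components removed as speckle.
#' The threshold is Otsu's method on the image histogram by default, or a
#' fixed value via `params$segmentation`.  A zero-variance image carries
#' no vacuole evidence and yields an all-`FALSE` mask (Otsu is undefined
#' there).
#'
#' @param gray Grayscale matrix (0--255), e.g. from [to_luminance()].
#' @param params [detection_params()].
#' @return Logical matrix of the same shape: `TRUE` on vacuole candidates.
#' @export
segment_vacuoles <- function(gray, params = detection_params()) {
  if (!is_gray_image(gray)) stop("segment_vacuoles() expects a grayscale matrix",
                                 call. = FALSE)
  if (identical(params$segmentation, "otsu")) {
    if (stats::var(as.vector(gray)) == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
    thr <- EBImage::otsu(gray, range = c(0, 255), levels = 256L)
  } else {
    thr <- params$segmentation
  }
  mask <- gray > thr
  drop_small_components(mask, params$min_component_px)
}

# Remove 4-connected components below min_px pixels (EBImage::bwlabel is
# 4-connected, matching the rasterized-circle geometry used throughout).
drop_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Mask boundary: mask pixels with at least one background 4-neighbour;
# out-of-image neighbours count as background.  Returns 0-based (cy, cx).
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  idx <- which(core & !interior, arr.ind = TRUE)
  cbind(cy = idx[, 1] - 1L, cx = idx[, 2] - 1L)
}
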