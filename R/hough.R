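#' Detect circles in a vacuole mask by circular Hough transform
#'
#' Boundary pixels of the mask (mask pixels with a background
#' 4-neighbour) vote into a `(cy, cx, r)` accumulator along the
#' rasterized perimeter of every search radius.  Scores are normalized by
#' the ideal perimeter pixel count for each radius, removing the
#' large-radius vote bias, so a score of 1 means the whole rim is
#' supported.  Local accumulator maxima at or above
#' `params$vote_threshold` are then reduced by greedy non-maximum
#' suppression in descending score order: a candidate is dropped when its
#' centre lies within `nms_center_factor * (r_kept + r_cand)` of an
#' already-kept circle.  Score ties are broken towards the larger radius
#' (macrovesicular droplets dominate ambiguous evidence), then by
#' `(cy, cx)` lexicographic order, making the output fully deterministic.
#'
#' @param mask Logical matrix from [segment_vacuoles()].
#' @param params [detection_params()] (radius range, thresholds).
#' @return `data.frame` with columns `cy`, `cx` (0-based centre, px),
#'   `r` (px) and `score`, in kept order.
#' @export
hough_circles <- function(mask, params = detection_params()) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("hough_circles() expects a logical mask matrix", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  if (params$r_max >= min(h, w))
    stop("radius range exceeds image: r_max = ", params$r_max,
         " but image is ", h, " x ", w, call. = FALSE)
  empty <- data.frame(cy = integer(), cx = integer(), r = integer(),
                      score = numeric())
  if (!any(mask)) return(empty)

  bnd <- mask_boundary(mask)
  radii <- seq.int(params$r_min, params$r_max, by = params$r_step)
  offs <- lapply(radii, perimeter_offsets)
  cand <- hough_peaks_cpp(as.integer(bnd[, "cy"]), as.integer(bnd[, "cx"]),
                          h, w, as.integer(radii),
                          lapply(offs, function(o) as.integer(o[, 1])),
                          lapply(offs, function(o) as.integer(o[, 2])),
                          params$vote_threshold)
  if (nrow(cand) == 0L) return(empty)
  nms_circles(cand, params$nms_center_factor)
}

# Greedy NMS, deterministic order: score desc, then r desc, then (cy, cx).
nms_circles <- function(cand, factor) {
  o <- order(-cand[, "score"], -cand[, "r"], cand[, "cy"], cand[, "cx"])
  cand <- cand[o, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      d <- sqrt((cand[i, "cy"] - cand[j, "cy"])^2 +
                (cand[i, "cx"] - cand[j, "cx"])^2)
      if (d < factor * (cand[i, "r"] + cand[j, "r"])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  k <- cand[kept, , drop = FALSE]
  data.frame(cy = as.integer(k[, "cy"]), cx = as.integer(k[, "cx"]),
             r = as.integer(k[, "r"]), score = unname(k[, "score"]),
             row.names = NULL)
}

#' Filter detected circles by mask support and image coverage
#'
#' False-positive control after the Hough stage.  A circle is kept iff
#' (a) at least `fill_min` of its in-image disk pixels are mask-positive
#' (rejects rim-only structures such as sinusoids or vessel walls), and
#' (b) at least `border_inside_min` of its disk area lies inside the
#' image (discards droplets clipped by the field of view, the usual
#' edge-object rule in histology quantification).  Input order is
#' preserved.
#'
#' @param circles `data.frame` from [hough_circles()].
#' @param mask The same mask the circles were detected on.
#' @param params [detection_params()].
#' @return The retained subset of `circles`.
#' @export
filter_droplets <- function(circles, mask, params = detection_params()) {
  if (nrow(circles) == 0L) return(circles)
  h <- nrow(mask); w <- ncol(mask)
  offs <- lapply(sort(unique(circles$r)), disk_offsets)
  names(offs) <- sort(unique(circles$r))
  keep <- vapply(seq_len(nrow(circles)), function(i) {
    off <- offs[[as.character(circles$r[i])]]
    ys <- off[, 1] + circles$cy[i]
    xs <- off[, 2] + circles$cx[i]
    inb <- ys >= 0L & ys < h & xs >= 0L & xs < w
    n_in <- sum(inb)
    if (n_in == 0L) return(FALSE)
    fill <- mean(mask[cbind(ys[inb] + 1L, xs[inb] + 1L)])
    inside <- n_in / nrow(off)
    fill >= params$fill_min && inside >= params$border_inside_min
  }, logical(1))
  out <- circles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
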