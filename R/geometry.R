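# Shared circle rasterization.  The generator draws disks, the Hough
# transform votes along perimeters, and the fill filter counts disk pixels
# all from this one definition, so geometry tests are exact:
#   disk(r)      = integer offsets (dy, dx) with dy^2 + dx^2 <= r^2
#   perimeter(r) = disk pixels with at least one 4-neighbour outside the disk

disk_offsets <- function(r) {
  r <- as.integer(r)
  d <- -r:r
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

perimeter_offsets <- function(r) {
  g <- disk_offsets(r)
  r2 <- as.integer(r)^2
  outside <- function(dy, dx) dy^2 + dx^2 > r2
  on_rim <- outside(g[, 1] + 1L, g[, 2]) | outside(g[, 1] - 1L, g[, 2]) |
            outside(g[, 1], g[, 2] + 1L) | outside(g[, 1], g[, 2] - 1L)
  g[on_rim, , drop = FALSE]
}

# Rasterize one disk into logical H x W (centre 0-based).
disk_mask <- function(cy, cx, r, height, width) {
  off <- disk_offsets(r)
  ys <- off[, 1] + cy
  xs <- off[, 2] + cx
  keep <- ys >= 0L & ys < height & xs >= 0L & xs < width
  m <- matrix(FALSE, height, width)
  m[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  m
}
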