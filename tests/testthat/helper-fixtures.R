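# Fixture builders: tiny images constructed in code, no stored binaries.

# Grayscale matrix with disks painted at `fg` over a `bg` background.
# Circles given as data.frame(cy, cx, r), 0-based, same disk definition
# as the package (dy^2 + dx^2 <= r^2).
gray_with_disks <- function(h, w, circles, bg = 0, fg = 255) {
  m <- matrix(bg, h, w)
  for (i in seq_len(nrow(circles))) {
    yy <- rep(0:(h - 1), times = w)
    xx <- rep(0:(w - 1), each = h)
    inside <- (yy - circles$cy[i])^2 + (xx - circles$cx[i])^2 <= circles$r[i]^2
    m[cbind(yy[inside] + 1, xx[inside] + 1)] <- fg
  }
  m
}

gray_to_rgb <- function(m) array(m, c(dim(m), 3))

# Random RGB image with integer 0..255 values.
random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}
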