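# Independent oracles, written from the definitions rather than shared
# with the package internals.

# --- Exhaustive circular-Hough oracle -------------------------------------
# Accumulator built by shift-and-add of the boundary indicator over every
# rasterized perimeter offset; peak selection and suppression re-derived
# from the rules (>= all 26 neighbours in (cy, cx, r); greedy suppression
# by score desc, radius desc, then lexicographic centre).

oracle_perimeter_offsets <- function(r) {
  dy <- rep(-r:r, times = 2 * r + 1)
  dx <- rep(-r:r, each = 2 * r + 1)
  in_disk <- dy^2 + dx^2 <= r^2
  rim <- in_disk & ((dy + 1)^2 + dx^2 > r^2 | (dy - 1)^2 + dx^2 > r^2 |
                    dy^2 + (dx + 1)^2 > r^2 | dy^2 + (dx - 1)^2 > r^2)
  cbind(dy = dy[rim], dx = dx[rim])
}

oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-h, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -w, drop = FALSE])
  mask & !(up & dn & lf & rt)
}

oracle_hough <- function(mask, params) {
  h <- nrow(mask); w <- ncol(mask)
  b <- oracle_boundary(mask) * 1
  radii <- seq(params$r_min, params$r_max, by = params$r_step)
  nR <- length(radii)
  score <- array(0, c(h, w, nR))
  for (ri in seq_len(nR)) {
    off <- oracle_perimeter_offsets(radii[ri])
    A <- matrix(0, h, w)
    for (k in seq_len(nrow(off))) {
      dy <- off[k, 1]; dx <- off[k, 2]
      # centre (cy, cx) gains a vote if boundary at (cy + dy, cx + dx)
      cy <- max(1, 1 - dy):min(h, h - dy)
      cx <- max(1, 1 - dx):min(w, w - dx)
      A[cy, cx] <- A[cy, cx] + b[cy + dy, cx + dx]
    }
    score[, , ri] <- A / nrow(off)
  }
  idx <- which(score >= params$vote_threshold, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    cy <- idx[i, 1]; cx <- idx[i, 2]; ri <- idx[i, 3]
    s <- score[cy, cx, ri]
    nb <- score[max(1, cy - 1):min(h, cy + 1),
                max(1, cx - 1):min(w, cx + 1),
                max(1, ri - 1):min(nR, ri + 1)]
    keep[i] <- all(nb <= s)
  }
  cand <- idx[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(cy = integer(), cx = integer(), r = integer(),
                      score = numeric()))
  df <- data.frame(cy = cand[, 1] - 1L, cx = cand[, 2] - 1L,
                   r = radii[cand[, 3]],
                   score = score[cand])
  df <- df[order(-df$score, -df$r, df$cy, df$cx), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    d <- sqrt((df$cy[kept] - df$cy[i])^2 + (df$cx[kept] - df$cx[i])^2)
    if (all(d >= params$nms_center_factor * (df$r[kept] + df$r[i])))
      kept <- c(kept, i)
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- Permutation oracle for the trend test --------------------------------
# Conditions on the margins by permuting group membership of the N units.
# The trend statistic is a monotone function of |T - E T| where T is the
# sum of scores in group 1, so the permutation p for the chi-square equals
# the permutation p for |T - E T|.
perm_trend_p <- function(counts, scores = seq_len(ncol(counts)) - 1,
                         B = 1e4, seed = 42) {
  u <- rep(scores, colSums(counts))
  R1 <- sum(counts[1, ])
  Tobs <- sum(scores * counts[1, ])
  ET <- R1 * mean(u)
  set.seed(seed)
  Ts <- replicate(B, sum(sample(u, R1)))
  (1 + sum(abs(Ts - ET) >= abs(Tobs - ET) - 1e-9)) / (B + 1)
}
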