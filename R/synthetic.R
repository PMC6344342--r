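#' Specification for a synthetic H&E-like histology image
#'
#' Describes one rendered field: pink tissue background, white circular
#' vacuoles of known centre and radius, and i.i.d. Gaussian pixel noise.
#' The defaults define the package's standard benchmark conditions —
#' a 256 x 256 field with 15 non-overlapping droplets, integer radii
#' uniform on 5--25 px and noise sigma 5, spanning the micro- to
#' macrovesicular size range at a realistic droplet density.  Centres
#' and radii are integers, matching the detector's integer Hough grid so
#' geometry checks are exact.
#'
#' @param height,width Canvas size, px.
#' @param n_droplets Number of circles (>= 0).
#' @param radius_dist Either `list(dist = "uniform", r_lo, r_hi)`
#'   (integer radii uniform on `r_lo..r_hi`) or
#'   `list(dist = "lognormal", meanlog, sdlog, r_lo, r_hi)` (rounded and
#'   truncated to the range).
#' @param allow_overlap If `FALSE` (default), circles are packed with
#'   pairwise centre distance >= `r_i + r_j + margin_px` and kept
#'   `margin_px` clear of the borders.
#' @param margin_px Minimum gap between circles and to the borders, px.
#' @param background_rgb,droplet_rgb Colours (0--255 triples); defaults
#'   are eosin pink and near-white vacuole.
#' @param noise_sigma Gaussian noise SD per channel, clipped to 0--255.
#' @param seed RNG seed; the generator is fully deterministic given
#'   (spec, seed).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 256L, width = 256L, n_droplets = 15L,
                           radius_dist = list(dist = "uniform",
                                              r_lo = 5L, r_hi = 25L),
                           allow_overlap = FALSE, margin_px = 2L,
                           background_rgb = c(230, 180, 190),
                           droplet_rgb = c(250, 250, 250),
                           noise_sigma = 5, seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_droplets >= 0, margin_px >= 0,
            noise_sigma >= 0, length(background_rgb) == 3L,
            length(droplet_rgb) == 3L,
            all(background_rgb >= 0 & background_rgb <= 255),
            all(droplet_rgb >= 0 & droplet_rgb <= 255))
  if (is.null(radius_dist$dist) ||
      !radius_dist$dist %in% c("uniform", "lognormal"))
    stop("radius_dist$dist must be \"uniform\" or \"lognormal\"", call. = FALSE)
  r_hi <- radius_dist$r_hi
  if (is.null(r_hi) || r_hi >= min(height, width) / 2)
    stop("r_hi must be set and below min(height, width) / 2", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_droplets = as.integer(n_droplets),
                 radius_dist = radius_dist,
                 allow_overlap = isTRUE(allow_overlap),
                 margin_px = as.integer(margin_px),
                 background_rgb = as.numeric(background_rgb),
                 droplet_rgb = as.numeric(droplet_rgb),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

sample_radius <- function(rd, n) {
  if (rd$dist == "uniform") {
    sample(seq.int(rd$r_lo, rd$r_hi), n, replace = TRUE)
  } else {
    r <- integer(0)
    while (length(r) < n) {
      x <- as.integer(round(stats::rlnorm(n, rd$meanlog, rd$sdlog)))
      r <- c(r, x[x >= rd$r_lo & x <= rd$r_hi])
    }
    r[seq_len(n)]
  }
}

#' Sample a ground-truth circle list
#'
#' Rejection-samples `n_droplets` circle placements satisfying the
#' packing invariants of the spec (non-overlap with margin, clear of the
#' borders), capped at 10 000 attempts per circle.  Deterministic for a
#' fixed `(spec, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @return `data.frame` of class `ground_truth` with 0-based `cy`, `cx`
#'   and `r` (px).
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    cy <- cx <- r <- integer(spec$n_droplets)
    m <- spec$margin_px
    for (i in seq_len(spec$n_droplets)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        ri <- sample_radius(spec$radius_dist, 1L)
        lo_y <- ri + m; hi_y <- spec$height - 1L - ri - m
        lo_x <- ri + m; hi_x <- spec$width - 1L - ri - m
        if (hi_y < lo_y || hi_x < lo_x) next
        yi <- sample(lo_y:hi_y, 1L); xi <- sample(lo_x:hi_x, 1L)
        if (!spec$allow_overlap && i > 1L) {
          j <- seq_len(i - 1L)
          d <- sqrt((cy[j] - yi)^2 + (cx[j] - xi)^2)
          if (any(d < r[j] + ri + m)) next
        }
        cy[i] <- yi; cx[i] <- xi; r[i] <- ri
        placed <- TRUE
        break
      }
      if (!placed)
        stop("cannot place droplets: packed ", i - 1L, " of ",
             spec$n_droplets, call. = FALSE)
    }
    structure(data.frame(cy = cy, cx = cx, r = r),
              class = c("ground_truth", "data.frame"))
  })
}

#' Render a synthetic histology image from ground truth
#'
#' Fills the canvas with the background colour, rasterizes each circle's
#' disk in the droplet colour (the same disk definition the detector's
#' fill test uses, so the geometry is exact), then adds i.i.d. Gaussian
#' noise per channel and clips to 0--255.  Deterministic for a fixed
#' `(spec, seed)`.
#'
#' @param truth A [sample_ground_truth()] result (or any data frame with
#'   0-based `cy`, `cx`, `r`).
#' @param spec The [synthetic_spec()] used for colours, noise and canvas.
#' @return RGB array `height x width x 3`, values 0--255.
#' @export
render_image <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  img <- array(rep(spec$background_rgb, each = h * w), c(h, w, 3L))
  if (nrow(truth) > 0L) {
    dm <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(truth)))
      dm <- dm | disk_mask(truth$cy[i], truth$cx[i], truth$r[i], h, w)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[dm] <- spec$droplet_rgb[ch]
      img[, , ch] <- plane
    }
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    })
    img <- pmin(pmax(img, 0), 255)
  }
  img
}

#' Simulate one image together with its ground truth
#'
#' Convenience wrapper: `sample_ground_truth()` then `render_image()`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` and `truth`.
#' @export
simulate_histology <- function(spec) {
  truth <- sample_ground_truth(spec)
  list(image = render_image(truth, spec), truth = truth)
}

#' Match detected circles to ground truth
#'
#' Greedy one-to-one matching in ascending centre-distance order among
#' pairs within tolerance: a detection and a truth circle may pair iff
#' their centre distance is <= `center_tol` and their radius difference
#' is <= `radius_tol`.  Precision is matched/detected and recall is
#' matched/truth, each defined as 1 when its denominator is 0 (an empty
#' detection set makes no false claims).
#'
#' @param detected `data.frame` with `cy`, `cx`, `r` (0-based px), e.g.
#'   `detect_droplets(img)$circles`, or a `droplet_detection`.
#' @param truth Ground truth from [sample_ground_truth()].
#' @param center_tol,radius_tol Matching tolerances, px (> 0).
#' @return List with `precision`, `recall`, `center_mae`, `radius_mae`
#'   (pixel MAEs over matched pairs; `NaN` when nothing matched),
#'   `n_matched`, and `pairs` (data.frame of matched index pairs with
#'   their centre distance and radius error).
#' @export
match_detections <- function(detected, truth, center_tol = 3, radius_tol = 3) {
  if (inherits(detected, "droplet_detection")) detected <- detected$circles
  stopifnot(center_tol > 0, radius_tol > 0)
  nd <- nrow(detected); nt <- nrow(truth)
  pairs <- data.frame(detected = integer(), truth = integer(),
                      center_dist = numeric(), radius_err = numeric())
  if (nd > 0L && nt > 0L) {
    cand <- expand.grid(detected = seq_len(nd), truth = seq_len(nt))
    cand$center_dist <- sqrt((detected$cy[cand$detected] - truth$cy[cand$truth])^2 +
                             (detected$cx[cand$detected] - truth$cx[cand$truth])^2)
    cand$radius_err <- abs(detected$r[cand$detected] - truth$r[cand$truth])
    cand <- cand[cand$center_dist <= center_tol & cand$radius_err <= radius_tol, ,
                 drop = FALSE]
    cand <- cand[order(cand$center_dist, cand$detected, cand$truth), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (i in seq_len(nrow(cand))) {
      di <- cand$detected[i]; ti <- cand$truth[i]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE; used_t[ti] <- TRUE
        pairs <- rbind(pairs, cand[i, ])
      }
    }
  }
  m <- nrow(pairs)
  list(precision = if (nd == 0L) 1 else m / nd,
       recall = if (nt == 0L) 1 else m / nt,
       center_mae = if (m) mean(pairs$center_dist) else NaN,
       radius_mae = if (m) mean(pairs$radius_err) else NaN,
       n_matched = m,
       pairs = pairs)
}
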