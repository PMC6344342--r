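# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Atomic file write: run `writer(tmp)` then rename tmp onto `path`, so a
# failure mid-write never leaves a truncated output file behind.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("failed to write output file: ", path, call. = FALSE)
  invisible(path)
}

is_rgb_image <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 3L

is_gray_image <- function(img) is.matrix(img)

check_image <- function(img, arg = "img") {
  if (!is_rgb_image(img) && !is_gray_image(img))
    stop("invalid image: `", arg, "` must be an H x W matrix or H x W x 3 array",
         call. = FALSE)
  if (any(dim(img)[1:2] < 1L)) stop("invalid image: empty grid", call. = FALSE)
  invisible(img)
}

# Format numbers for CSV/JSON output: fixed 6 decimal places, no scientific
# notation, so serialized reports are byte-stable and round-trip to 6 dp.
num6 <- function(x) sprintf("%.6f", x)
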