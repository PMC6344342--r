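#' Convert detected circles to calibrated droplet records
#'
#' One record per circle, in emission order: `diameter_um = 2 r s` and
#' `area_um2 = pi (r s)^2` for pixel size `s` (um/px).
#'
#' @param circles `data.frame` with `cy`, `cx`, `r`, `score` (e.g.
#'   `detect_droplets(img)$circles`), or a `droplet_detection`.
#' @param calib [calibration()] or a positive number (um/px).
#' @param image_id Identifier stored in each record.
#' @return `data.frame` with columns `image_id`, `droplet_id` (1-based),
#'   `cy`, `cx`, `r_px`, `score`, `diameter_um`, `area_um2`.
#' @examples
#' measure_droplets(data.frame(cy = 10, cx = 10, r = 10, score = 1), 0.5)
#' @export
measure_droplets <- function(circles, calib = 1, image_id = "image") {
  if (inherits(circles, "droplet_detection")) {
    if (missing(calib)) calib <- circles$um_per_px
    if (missing(image_id)) image_id <- circles$image_id
    circles <- circles$circles
  }
  s <- tryCatch(unclass(calibration(unclass(calib))),
                error = function(e) stop("invalid calibration: um/px must be positive",
                                         call. = FALSE))
  n <- nrow(circles)
  data.frame(image_id = rep(image_id, n),
             droplet_id = seq_len(n),
             cy = circles$cy, cx = circles$cx,
             r_px = circles$r, score = circles$score,
             diameter_um = 2 * circles$r * s,
             area_um2 = pi * (circles$r * s)^2)
}

#' Bin droplet sizes into a histogram
#'
#' Assigns each droplet to a half-open bin `[lo, hi)` over either
#' diameter or area; values below the first edge go to `underflow`,
#' values at or above the last edge to `overflow`, so every droplet is
#' accounted for: `sum(counts) + underflow + overflow == total`.
#'
#' @param records Droplet records from [measure_droplets()].
#' @param edges Strictly increasing numeric vector of `K + 1` bin
#'   boundaries (`K >= 2` bins are needed for trend testing).
#' @param field `"diameter_um"` (default) or `"area_um2"`.
#' @return Object of class `droplet_histogram`: list with `field`,
#'   `edges`, `counts`, `underflow`, `overflow`, `total`.
#' @examples
#' rec <- measure_droplets(data.frame(cy = 0, cx = 0, r = c(2, 6, 12),
#'                                    score = 1), 1)
#' bin_histogram(rec, c(0, 10, 20, 30))
#' @export
bin_histogram <- function(records, edges, field = c("diameter_um", "area_um2")) {
  field <- match.arg(field)
  if (length(edges) < 3L || any(diff(edges) <= 0))
    stop("invalid bin specification: edges must be strictly increasing, K >= 2",
         call. = FALSE)
  x <- records[[field]]
  k <- findInterval(x, edges)           # 0 = underflow, K + 1 = overflow
  K <- length(edges) - 1L
  structure(list(field = field, edges = as.numeric(edges),
                 counts = as.integer(tabulate(k[k >= 1L & k <= K], nbins = K)),
                 underflow = sum(k == 0L),
                 overflow = sum(k == K + 1L),
                 total = length(x)),
            class = "droplet_histogram")
}

#' @export
print.droplet_histogram <- function(x, ...) {
  K <- length(x$counts)
  lab <- sprintf("[%g, %g)", x$edges[-(K + 1)], x$edges[-1])
  cat(sprintf("Droplet size histogram on %s (%d droplets)\n", x$field, x$total))
  print(stats::setNames(x$counts, lab))
  if (x$underflow + x$overflow > 0)
    cat(sprintf("  underflow %d, overflow %d\n", x$underflow, x$overflow))
  invisible(x)
}

#' @export
plot.droplet_histogram <- function(x, ...) {
  K <- length(x$counts)
  graphics::barplot(x$counts,
                    names.arg = sprintf("[%g,%g)", x$edges[-(K + 1)], x$edges[-1]),
                    xlab = x$field, ylab = "droplets", ...)
  invisible(x)
}

#' Per-image steatosis summary
#'
#' Aggregates a droplet table into the numbers a steatosis readout
#' needs: droplet count, mean and median diameter, total droplet area,
#' droplet area fraction of the imaged field, and droplet density per
#' square millimetre.
#'
#' @param records Droplet records from [measure_droplets()].
#' @param image_area_um2 Physical area of the imaged field (um^2), i.e.
#'   `height * width * um_per_px^2`.
#' @return List with `count`, `mean_diameter_um`, `median_diameter_um`,
#'   `total_area_um2`, `area_fraction`, `density_per_mm2`.
#' @export
droplet_summary <- function(records, image_area_um2) {
  if (!is.numeric(image_area_um2) || length(image_area_um2) != 1L ||
      !is.finite(image_area_um2) || image_area_um2 <= 0)
    stop("invalid image area: must be a single positive number (um^2)",
         call. = FALSE)
  n <- nrow(records)
  list(count = n,
       mean_diameter_um = if (n) mean(records$diameter_um) else 0,
       median_diameter_um = if (n) stats::median(records$diameter_um) else 0,
       total_area_um2 = sum(records$area_um2),
       area_fraction = sum(records$area_um2) / image_area_um2,
       density_per_mm2 = n / (image_area_um2 / 1e6))
}

report_columns <- c("image_id", "droplet_id", "cy", "cx", "r_px", "score",
                    "diameter_um", "area_um2")

#' Write a droplet report (CSV table + JSON sidecar)
#'
#' The per-droplet table goes to `path` as CSV with the fixed header
#' `image_id, droplet_id, cy, cx, r_px, score, diameter_um, area_um2`;
#' the histogram and summary go to a JSON sidecar next to it
#' (`<path without .csv>.json`).  Numeric fields are written with six
#' decimal places — below measurement meaningfulness, above float noise —
#' and [read_droplet_report()] is the exact inverse at that precision.
#' Files are written atomically (temp file + rename).
#'
#' @param records Droplet records ([measure_droplets()]).
#' @param histogram A [bin_histogram()] result, or `NULL`.
#' @param summary A [droplet_summary()] result, or `NULL`.
#' @param path Destination CSV path.
#' @return Invisible character vector of the files written.
#' @export
write_droplet_report <- function(records, histogram = NULL, summary = NULL,
                                 path) {
  stopifnot(all(report_columns %in% names(records)))
  tab <- records[report_columns]
  for (col in c("score", "diameter_um", "area_um2")) tab[[col]] <- num6(tab[[col]])
  write_atomic(path, function(tmp)
    utils::write.csv(tab, tmp, row.names = FALSE, quote = FALSE))
  side <- sidecar_path(path)
  payload <- list(
    histogram = if (!is.null(histogram)) unclass(histogram),
    summary = if (!is.null(summary)) lapply(summary, function(v)
      if (is.numeric(v)) as.numeric(num6(v)) else v)
  )
  write_atomic(side, function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE))
  invisible(c(path, side))
}

sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' Read a droplet report back
#'
#' Inverse of [write_droplet_report()].  Malformed input fails with a
#' "report parse error" naming the offending line or column.
#'
#' @param path CSV path written by [write_droplet_report()].
#' @return List with `records` (data.frame), `histogram`
#'   (`droplet_histogram` or `NULL`) and `summary` (list or `NULL`).
#' @export
read_droplet_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("report parse error: ", conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(report_columns, names(tab))
  if (length(missing_cols))
    stop("report parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("droplet_id", "cy", "cx", "r_px", "score",
                "diameter_um", "area_um2")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("report parse error: non-numeric ", col, " at line ",
           bad[1] + 1L, call. = FALSE)
    tab[[col]] <- v
  }
  tab$droplet_id <- as.integer(tab$droplet_id)
  side <- sidecar_path(path)
  histogram <- summary <- NULL
  if (file.exists(side)) {
    js <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                   error = function(e)
                     stop("report parse error: ", conditionMessage(e), call. = FALSE))
    if (!is.null(js$histogram)) {
      h <- js$histogram
      histogram <- structure(list(field = h$field, edges = as.numeric(h$edges),
                                  counts = as.integer(h$counts),
                                  underflow = as.integer(h$underflow),
                                  overflow = as.integer(h$overflow),
                                  total = as.integer(h$total)),
                             class = "droplet_histogram")
    }
    summary <- js$summary
  }
  list(records = tab, histogram = histogram, summary = summary)
}
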