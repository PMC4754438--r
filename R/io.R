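#' Read an RR series from a tachogram file
#'
#' Accepts either a plain-text file with one interval per line, or a CSV file
#' containing a column named `rr`. Intervals are interpreted in seconds by
#' default; with `units = "ms"` they are divided by 1000 on read. Values that
#' are missing, non-numeric, non-finite or not strictly positive are rejected
#' with the offending line named.
#'
#' @param path Path to the tachogram file.
#' @param units `"s"` (default) or `"ms"`.
#' @param subject_id Identifier; defaults to the file name without extension.
#' @param group Group label for the series.
#' @return An [rr_series].
#' @export
read_rr <- function(path, units = c("s", "ms"),
                    subject_id = sub("\\.[^.]*$", "", basename(path)),
                    group = "unknown") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"rr" %in% names(df))
      stop("CSV file ", path, " has no column named 'rr'")
    vals <- suppressWarnings(as.numeric(df$rr))
    lines <- seq_along(vals) + 1L   # header is line 1
  } else {
    raw <- trimws(readLines(path, warn = FALSE))
    keep <- nzchar(raw)
    if (!any(keep)) stop("empty tachogram file: ", path)
    lines <- which(keep)
    vals <- suppressWarnings(as.numeric(raw[keep]))
  }
  if (!length(vals)) stop("empty tachogram file: ", path)
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad))
    stop(sprintf("invalid RR value at line %d of %s: '%s' (must be a finite number > 0)",
                 lines[bad[1L]], path,
                 if (is.na(vals[bad[1L]])) "non-numeric" else vals[bad[1L]]))
  if (units == "ms") vals <- vals / 1000
  rr_series(vals, subject_id = subject_id, group = group)
}

#' Write an RR series as a plain-text tachogram
#'
#' One interval per line, seconds. The companion format of [read_rr()].
#'
#' @param rr An [rr_series].
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, digits = 10) {
  rr <- as_rr_series(rr)
  writeLines(formatC(rr$intervals, digits = digits, format = "g"), path)
  invisible(path)
}

#' Write / read an r(j,k) matrix as CSV
#'
#' The CSV has a header row of following counts k = 1..n, a leading `j`
#' column of preceding counts, and empty cells where r(j,k) is undefined.
#' `read_matrix_csv()` restores an identical [gpp_matrix] (defined cells
#' round-trip bit-exactly at the written precision).
#'
#' @param matrix A [gpp_matrix].
#' @param path CSV path.
#' @return `path` (write) or a [gpp_matrix] (read).
#' @export
write_matrix_csv <- function(matrix, path) {
  gm <- as_gpp_matrix(matrix)
  df <- as.data.frame(gm$r)
  names(df) <- seq_len(gm$n)
  df <- cbind(j = seq_len(gm$m), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"j" %in% names(df)) stop("not a matrix CSV (no 'j' column): ", path)
  r <- as.matrix(df[, setdiff(names(df), "j"), drop = FALSE])
  as_gpp_matrix(r)
}

#' Write per-subject asymmetry results as CSV
#'
#' One row per fitted [gpp] object: subject_id, group, grid size, mean
#' absolute correlation and the three asymmetry indices, plus the surrogate
#' provenance (number of reshufflings and master seed).
#'
#' @param fits A list of fitted [gpp] objects (or a single fit).
#' @param path CSV path.
#' @return The written data frame, invisibly.
#' @export
write_asymmetry_csv <- function(fits, path) {
  if (inherits(fits, "gpp")) fits <- list(fits)
  rows <- lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, group = f$group,
               m = f$matrix$m, n = f$matrix$n,
               r_bar = f$r_bar, nai = f$nai, nai_sh = f$nai_sh,
               naic = f$naic, n_reshuffles = f$n_reshuffles,
               seed = f$seed, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write pooled local maxima as CSV
#'
#' Columns: subject_id, group, j, k, r.
#'
#' @param pooled Maxima data frame ([find_local_maxima()] or [pool_maxima()]
#'   output).
#' @param path CSV path.
#' @return The written data frame, invisibly.
#' @export
write_maxima_csv <- function(pooled, path) {
  df <- as.data.frame(pooled)[, c("subject_id", "group", "j", "k", "r")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
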