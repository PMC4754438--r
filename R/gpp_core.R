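#' Summed-window point set of a generalized Poincare plot
#'
#' The generalized Poincare plot of order (j, k) scatters the summed duration
#' of j preceding RR intervals against the summed duration of the k following
#' intervals, for every anchor position moving along the tachogram. The
#' classical Poincare plot is the order (1, 1) case. For a series of N
#' intervals exactly N - j - k points exist.
#'
#' With intervals indexed 1..N, the point at anchor i (i = 1..N-j-k) is
#' x = sum(rr[i..i+j-1]), y = sum(rr[i+j..i+j+k-1]); both windows are computed
#' from one cumulative-sum pass, so the cost is O(N) per order.
#'
#' @param rr An [rr_series] or numeric vector of intervals (seconds).
#' @param j Number of preceding intervals summed for the abscissa (>= 1).
#' @param k Number of following intervals summed for the ordinate (>= 1).
#' @return An object of class `gpp_points`: a list with numeric vectors `x`
#'   and `y` (each of length N - j - k), the order `j`, `k`, and `n_points`.
#' @examples
#' pts <- gpp_points(c(0.8, 0.9, 1.0, 1.1, 0.7), j = 1, k = 1)
#' cbind(pts$x, pts$y)
#' @seealso [gpp_matrix()] for the full r(j,k) grid, [sd1_sd2()] for the
#'   dispersion descriptors, [plot.gpp_points()].
#' @export
gpp_points <- function(rr, j, k) {
  rr <- as_rr_series(rr)
  j <- as.integer(j); k <- as.integer(k)
  if (is.na(j) || is.na(k) || j < 1L || k < 1L)
    stop("order (j, k) must be positive integers")
  n <- length(rr$intervals)
  npts <- n - j - k
  if (npts < 1L)
    stop(sprintf("insufficient intervals: N = %d cannot support order (j = %d, k = %d); need N > j + k",
                 n, j, k))
  s <- c(0, cumsum(rr$intervals))
  i <- seq_len(npts)
  structure(
    list(x = s[i + j] - s[i],
         y = s[i + j + k] - s[i + j],
         j = j, k = k, n_points = npts,
         subject_id = rr$subject_id),
    class = "gpp_points"
  )
}

#' @export
print.gpp_points <- function(x, ...) {
  cat(sprintf("gPp point set, order (j = %d, k = %d): %d points\n",
              x$j, x$k, x$n_points))
  invisible(x)
}

#' Pearson correlation of a generalized Poincare point set
#'
#' Product-moment correlation of the summed preceding vs following window
#' durations. When either coordinate has zero variance the correlation is
#' undefined and `NA` is returned (never an error), so one degenerate cell
#' cannot abort a whole matrix computation.
#'
#' @param points A [gpp_points] object.
#' @return A single correlation in \[-1, 1\], or `NA` if undefined.
#' @export
gpp_cor <- function(points) {
  stopifnot(inherits(points, "gpp_points"))
  if (points$n_points < 3L)
    stop("insufficient points for a correlation: need at least 3, got ",
         points$n_points)
  pearson_or_na(points$x, points$y)
}

# cor() with a zero-variance guard; returns NA_real_ instead of warning.
pearson_or_na <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

#' SD1/SD2 dispersion of a Poincare point set
#'
#' SD1 measures dispersion perpendicular to the identity line, SD2 along it;
#' they are the standard deviations of the rotated coordinates
#' (x - y)/sqrt(2) and (x + y)/sqrt(2). The population standard deviation
#' (divisor n) is used by default; set `sample = TRUE` for the divisor n - 1.
#' For the classical order (1, 1) these reduce to the conventional HRV SD1 and
#' SD2 of the tachogram.
#'
#' @param points A [gpp_points] object with at least 2 points.
#' @param sample Use the sample (n - 1) convention instead of population.
#' @return Named numeric vector `c(sd1 = , sd2 = )`, in seconds.
#' @examples
#' pts <- gpp_points(c(0.8, 0.9, 1.0, 1.1, 0.7, 0.85), j = 1, k = 1)
#' sd1_sd2(pts)
#' @export
sd1_sd2 <- function(points, sample = FALSE) {
  stopifnot(inherits(points, "gpp_points"))
  if (points$n_points < 2L)
    stop("need at least 2 points for SD1/SD2, got ", points$n_points)
  u <- (points$x - points$y) / sqrt(2)
  v <- (points$x + points$y) / sqrt(2)
  n <- length(u)
  denom <- if (sample) n - 1L else n
  c(sd1 = sqrt(sum((u - mean(u))^2) / denom),
    sd2 = sqrt(sum((v - mean(v))^2) / denom))
}

#' Correlation matrix r(j,k) over a grid of gPp orders
#'
#' Tabulates the Pearson correlation of the order-(j, k) generalized Poincare
#' plot for every j = 1..m and k = 1..n. The orientation convention is fixed
#' throughout the package: the FIRST index (matrix row) is j, the number of
#' preceding intervals (abscissa of the contour plots); the SECOND (column)
#' is k, the number of following intervals (ordinate).
#'
#' Cells whose order leaves fewer than 3 points (j + k >= N - 2), or whose
#' point set is degenerate (zero variance), are undefined: their value is `NA`
#' and the `defined` mask is `FALSE` there.
#'
#' @param rr An [rr_series] or numeric vector of intervals (seconds).
#' @param m Maximum preceding count (rows), default 100.
#' @param n Maximum following count (columns), default 100.
#' @return Object of class `gpp_matrix`: list with `r` (m x n numeric matrix,
#'   dimnames j/k), `defined` (logical matrix), `m`, `n`, `n_intervals`,
#'   `subject_id`.
#' @examples
#' rr <- generate_white_noise_series(300, seed = 1)
#' gm <- gpp_matrix(rr, m = 5, n = 5)
#' round(gm$r, 3)
#' @export
gpp_matrix <- function(rr, m = 100L, n = 100L) {
  rr <- as_rr_series(rr)
  m <- as.integer(m); n <- as.integer(n)
  if (is.na(m) || is.na(n) || m < 1L || n < 1L)
    stop("grid bounds m and n must be >= 1")
  nint <- length(rr$intervals)
  s <- c(0, cumsum(rr$intervals))
  r <- matrix(NA_real_, m, n, dimnames = list(j = 1:m, k = 1:n))
  for (j in seq_len(m)) {
    for (k in seq_len(n)) {
      npts <- nint - j - k
      if (npts < 3L) next
      i <- seq_len(npts)
      r[j, k] <- pearson_or_na(s[i + j] - s[i], s[i + j + k] - s[i + j])
    }
  }
  new_gpp_matrix(r, nint, rr$subject_id)
}

new_gpp_matrix <- function(r, n_intervals = NA_integer_, subject_id = NA_character_) {
  structure(
    list(r = r, defined = !is.na(r),
         m = nrow(r), n = ncol(r),
         n_intervals = n_intervals, subject_id = subject_id),
    class = "gpp_matrix"
  )
}

#' Wrap a plain matrix as a gpp_matrix
#'
#' Useful for analytic tests and for matrices read back from CSV. `NA` entries
#' are treated as undefined cells.
#'
#' @param r Numeric matrix of correlations, rows indexed by j, columns by k.
#' @param subject_id Optional identifier carried along.
#' @return A `gpp_matrix`.
#' @export
as_gpp_matrix <- function(r, subject_id = NA_character_) {
  if (inherits(r, "gpp_matrix")) return(r)
  r <- as.matrix(r)
  storage.mode(r) <- "double"
  dimnames(r) <- list(j = seq_len(nrow(r)), k = seq_len(ncol(r)))
  ok <- r[!is.na(r)]
  if (length(ok) && any(ok < -1 - 1e-9 | ok > 1 + 1e-9))
    stop("correlation values must lie in [-1, 1]")
  new_gpp_matrix(r, subject_id = subject_id)
}

#' @export
print.gpp_matrix <- function(x, ...) {
  cat(sprintf("gPp correlation matrix r(j,k): %d x %d, %d/%d cells defined\n",
              x$m, x$n, sum(x$defined), x$m * x$n))
  if (any(x$defined)) {
    idx <- which(x$r == max(x$r, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    cat(sprintf("  max r = %.4f at (j = %d, k = %d)\n",
                max(x$r, na.rm = TRUE), idx[1L], idx[2L]))
  }
  invisible(x)
}
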