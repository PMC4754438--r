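#' Mean absolute element of a correlation matrix
#'
#' The normalization constant of the asymmetry index: the mean of |r(j,k)|
#' over the full m x n grid. Undefined cells contribute 0 to the sum while the
#' denominator stays m x n, so the index remains defined on matrices with
#' isolated degenerate cells and reduces to the plain mean when none are
#' undefined.
#'
#' @param matrix A [gpp_matrix] (or plain numeric matrix).
#' @return Non-negative scalar, the mean absolute correlation.
#' @export
mean_abs_r <- function(matrix) {
  matrix <- as_gpp_matrix(matrix)
  if (!any(matrix$defined))
    stop("matrix has no defined cells; mean |r| is undefined")
  sum(abs(matrix$r[matrix$defined])) / (matrix$m * matrix$n)
}

#' Normalized asymmetry index (NAI) of an r(j,k) matrix
#'
#' Quantifies how correlation mass is distributed around the identity
#' diagonal of the r(j,k) matrix. For a square m x n matrix,
#' \deqn{NAI = \frac{1}{m n}\,\frac{1}{\bar r} \sum_{j=1}^{m}\sum_{k=j+1}^{n}
#'   \big(r(k,j) - r(j,k)\big),}
#' where \eqn{\bar r} is the mean absolute element ([mean_abs_r()]). The
#' normalization by \eqn{\bar r} makes indices comparable between matrices of
#' different overall correlation magnitude and different sizes.
#'
#' Sign semantics (with j on the abscissa and k on the ordinate): NAI is
#' negative when the region above the identity diagonal (k > j: fewer
#' preceding, more following intervals) carries more total correlation than
#' the region below it, and positive in the opposite case. A symmetric matrix
#' has NAI = 0. Diagonal cells enter \eqn{\bar r} but not the difference sum.
#'
#' Undefined cells contribute 0 to both sums. The matrix must be square; the
#' transpose pairing r(k,j)/r(j,k) only exists then, and non-square input is
#' rejected rather than silently cropped.
#'
#' @param matrix A square [gpp_matrix] (or plain numeric matrix).
#' @return Dimensionless scalar index.
#' @examples
#' m <- rbind(c(0, 0.5), c(0.1, 0))
#' nai(m)  # (1/4) * (1/0.15) * (0.1 - 0.5) = -2/3
#' @export
nai <- function(matrix) {
  matrix <- as_gpp_matrix(matrix)
  if (matrix$m != matrix$n)
    stop("NAI requires a square matrix (m == n); got ",
         matrix$m, " x ", matrix$n)
  r_bar <- mean_abs_r(matrix)
  if (r_bar == 0)
    stop("undefined NAI: mean |r| of the matrix is zero")
  d <- matrix$r
  d[!matrix$defined] <- 0
  diffs <- t(d) - d                     # [j,k] entry: r(k,j) - r(j,k)
  sum(diffs[upper.tri(diffs)]) / (matrix$m * matrix$n * r_bar)
}

#' Averaged reshuffled-surrogate correlation matrix
#'
#' Computes r(j,k) for `n_reps` independent random reshufflings of the series
#' and averages them element-wise. Reshuffling preserves the interval
#' distribution but destroys temporal order, so the averaged surrogate matrix
#' estimates the correlation structure attributable to the histogram alone.
#' A cell is defined in the average only if it was defined in every
#' repetition.
#'
#' @param rr An [rr_series] or numeric vector of intervals.
#' @inheritParams gpp_matrix
#' @param n_reps Number of reshufflings averaged (default 10).
#' @param seed Master seed; `n_reps` child seeds are spawned from it
#'   reproducibly.
#' @return A [gpp_matrix] whose `r` is the element-wise mean; attribute
#'   fields `n_reps` and `child_seeds` record provenance.
#' @export
surrogate_matrix <- function(rr, m = 100L, n = 100L, n_reps = 10L, seed = 1L) {
  rr <- as_rr_series(rr)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  seeds <- spawn_seeds(seed, n_reps)
  acc <- NULL
  any_na <- NULL
  for (s in seeds) {
    gm <- gpp_matrix(reshuffle_rr(rr, seed = s), m = m, n = n)
    if (is.null(acc)) {
      acc <- matrix(0, m, n)
      any_na <- matrix(FALSE, m, n)
    }
    any_na <- any_na | !gm$defined
    v <- gm$r
    v[!gm$defined] <- 0
    acc <- acc + v
  }
  r <- acc / n_reps
  r[any_na] <- NA_real_
  dimnames(r) <- list(j = 1:m, k = 1:n)
  out <- new_gpp_matrix(r, length(rr$intervals), paste0(rr$subject_id, "_sh"))
  out$n_reps <- n_reps
  out$child_seeds <- seeds
  out
}

#' Fit a generalized Poincare plot analysis to one RR series
#'
#' The central fitting function of the package. For one tachogram it
#' tabulates the r(j,k) correlation matrix over a j = 1..m, k = 1..n grid of
#' orders, averages `n_reshuffles` reshuffled-surrogate matrices, computes the
#' normalized asymmetry index of both (NAI and NAIsh) and the corrected index
#' NAIC = NAI - NAIsh, and detects the local maxima of the physiological
#' matrix.
#'
#' @param rr An [rr_series] or numeric vector of RR intervals in seconds.
#' @param m,n Grid bounds for preceding/following interval counts
#'   (default 100 each). NAI requires `m == n`.
#' @param n_reshuffles Number of surrogate reshufflings averaged (default 10).
#' @param seed Master seed controlling the reshufflings.
#' @param surrogate Set `FALSE` to skip the surrogate correction (NAIsh and
#'   NAIC are then `NA`); useful for quick exploration.
#' @return An object of class `gpp`: a list with elements
#'   \describe{
#'     \item{matrix}{the physiological [gpp_matrix]}
#'     \item{surrogate}{the averaged surrogate [gpp_matrix] (or `NULL`)}
#'     \item{r_bar}{mean absolute correlation of the physiological matrix}
#'     \item{nai, nai_sh, naic}{asymmetry indices; `naic = nai - nai_sh`}
#'     \item{maxima}{data frame of local maxima (`j`, `k`, `r`,
#'       `subject_id`, `group`)}
#'     \item{n_reshuffles, seed, child_seeds}{surrogate provenance}
#'   }
#' @examples
#' rr <- generate_validation_series(j_star = 3, k_star = 2,
#'                                  n_intervals = 400, seed = 7)
#' fit <- gpp(rr, m = 8, n = 8, seed = 7)
#' fit
#' coef(fit)
#' @seealso [nai()], [surrogate_matrix()], [find_local_maxima()],
#'   [plot.gpp()], [summary.gpp()]
#' @export
gpp <- function(rr, m = 100L, n = 100L, n_reshuffles = 10L, seed = 1L,
                surrogate = TRUE) {
  rr <- as_rr_series(rr)
  gm <- gpp_matrix(rr, m = m, n = n)
  r_bar <- if (any(gm$defined)) mean_abs_r(gm) else NA_real_
  nai_val <- NA_real_
  if (gm$m == gm$n && isTRUE(r_bar > 0)) nai_val <- nai(gm)
  sur <- NULL
  nai_sh <- NA_real_
  child_seeds <- integer(0)
  if (surrogate) {
    sur <- surrogate_matrix(rr, m = m, n = n, n_reps = n_reshuffles,
                            seed = seed)
    child_seeds <- sur$child_seeds
    if (sur$m == sur$n && any(sur$defined) && mean_abs_r(sur) > 0)
      nai_sh <- nai(sur)
  }
  maxima <- find_local_maxima(gm, subject_id = rr$subject_id,
                              group = rr$group)
  structure(
    list(subject_id = rr$subject_id, group = rr$group,
         n_intervals = length(rr$intervals),
         matrix = gm, surrogate = sur,
         r_bar = r_bar, nai = nai_val, nai_sh = nai_sh,
         naic = nai_val - nai_sh,
         maxima = maxima,
         n_reshuffles = if (surrogate) as.integer(n_reshuffles) else 0L,
         seed = as.integer(seed), child_seeds = child_seeds,
         call = match.call()),
    class = "gpp"
  )
}

#' @export
print.gpp <- function(x, digits = 4, ...) {
  cat(sprintf("Generalized Poincare plot analysis of '%s' (%s)\n",
              x$subject_id, x$group))
  cat(sprintf("  %d intervals, grid %d x %d, %d reshufflings\n",
              x$n_intervals, x$matrix$m, x$matrix$n, x$n_reshuffles))
  cat(sprintf("  mean |r| = %.*f\n", digits, x$r_bar))
  cat(sprintf("  NAI = %.*f   NAIsh = %.*f   NAIC = %.*f\n",
              digits, x$nai, digits, x$nai_sh, digits, x$naic))
  cat(sprintf("  %d local maxima detected\n", nrow(x$maxima)))
  invisible(x)
}

#' @export
coef.gpp <- function(object, ...) {
  c(r_bar = object$r_bar, nai = object$nai,
    nai_sh = object$nai_sh, naic = object$naic)
}

#' Summarize a fitted gPp analysis
#'
#' @param object A fitted [gpp] object.
#' @param top Number of strongest local maxima to display.
#' @param ... Unused.
#' @return Invisibly, a list with the coefficient vector and the maxima table.
#' @export
summary.gpp <- function(object, top = 5L, ...) {
  print(object)
  mx <- object$maxima
  if (nrow(mx)) {
    cat(sprintf("  top local maxima (of %d):\n", nrow(mx)))
    show <- utils::head(mx[, c("j", "k", "r")], top)
    print(show, row.names = FALSE, digits = 4)
  }
  invisible(list(coefficients = coef.gpp(object), maxima = mx))
}
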