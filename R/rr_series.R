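#' Construct an RR-interval series (tachogram)
#'
#' An `rr_series` holds one subject's ordered interbeat intervals in seconds
#' together with a subject identifier and a group label. It is the input type
#' of every analysis function in the package.
#'
#' @param intervals Numeric vector of RR intervals in seconds. All values must
#'   be finite and strictly positive, and at least 3 intervals are required
#'   (shorter series cannot produce a single generalized Poincare point).
#' @param subject_id Character scalar identifying the recording.
#' @param group Group label, one of `"healthy"`, `"AF"`, `"synthetic"`,
#'   `"unknown"`.
#' @return An object of class `rr_series`: a list with elements `intervals`,
#'   `subject_id` and `group`.
#' @examples
#' rr <- rr_series(c(0.8, 0.9, 1.0, 1.1), subject_id = "demo")
#' rr
#' @export
rr_series <- function(intervals, subject_id = "subject",
                      group = c("unknown", "healthy", "AF", "synthetic")) {
  group <- match.arg(group)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 3L)
    stop("an RR series needs at least 3 intervals, got ", length(intervals))
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad))
    stop("RR intervals must be finite and > 0; first offending position: ",
         bad[1L], " (value ", intervals[bad[1L]], ")")
  structure(
    list(intervals = intervals,
         subject_id = as.character(subject_id)[1L],
         group = group),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("RR series '%s' (%s): %d intervals, mean %.3f s, range [%.3f, %.3f] s\n",
              x$subject_id, x$group, n, mean(x$intervals),
              min(x$intervals), max(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

as_rr_series <- function(x, ...) {
  if (inherits(x, "rr_series")) return(x)
  rr_series(x, ...)
}

#' Randomly reshuffle an RR series
#'
#' Returns a uniformly random permutation of the intervals. Reshuffling
#' destroys all temporal structure while preserving the interval distribution
#' exactly; it is the surrogate used to separate genuine correlation structure
#' from artefacts of the interval histogram.
#'
#' @param rr An [rr_series] (or bare numeric vector of intervals in seconds).
#' @param seed Integer seed; the permutation is deterministic given `seed`.
#' @return A new `rr_series` with the same multiset of intervals in random
#'   order. The subject id is suffixed with `"_sh"`.
#' @examples
#' rr <- rr_series(c(0.8, 0.9, 1.0, 1.1, 0.95))
#' sort(reshuffle_rr(rr, seed = 1)$intervals) == sort(rr$intervals)
#' @export
reshuffle_rr <- function(rr, seed = 1L) {
  rr <- as_rr_series(rr)
  perm <- with_preserved_rng(seed, sample.int(length(rr$intervals)))
  structure(
    list(intervals = rr$intervals[perm],
         subject_id = paste0(rr$subject_id, "_sh"),
         group = rr$group),
    class = "rr_series"
  )
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

# Spawn `n` reproducible child seeds (< 2^31) from one master seed.
spawn_seeds <- function(seed, n) {
  with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}
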