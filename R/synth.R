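#' Synthetic validation tachogram with a planted correlation maximum
#'
#' Generates an RR series whose r(j,k) matrix attains its maximal correlation
#' at a chosen order (`j_star`, `k_star`), for validating the generalized
#' Poincare analysis end-to-end. All intervals live in the physiological
#' range `lo`..`hi` seconds (defaults 0.75-1.2 s); values that would escape
#' the range are clipped to it, the range limit overriding the planted
#' structure.
#'
#' The correlated structure is a moving-average template: a finite impulse
#' response, designed at run time by numerical optimization
#' so that the population correlation surface of summed windows peaks at the
#' planted order, is applied to i.i.d. Gaussian innovations. For any
#' covariance-stationary series the summed-window correlation surface is
#' provably transpose-symmetric — every interval pair at lag L enters r(j,k)
#' with weight min(j, k, L, j+k-L), symmetric in (j, k) — so a stationary
#' construction alone can only plant the unordered pair
#' \{(j*,k*), (k*,j*)\}. The generator therefore starts the series
#' uncorrelated (a white-noise floor of relative amplitude `noise`) and
#' ramps the coupling amplitude linearly from 0 to its full value across the
#' recording. This coupling onset is the sole source of direction: it favors
#' the planted cell over its transpose and tilts the asymmetry index NAI
#' negative when `j_star < k_star` (correlation mass above the identity
#' diagonal) and positive when `j_star > k_star`, the latter realized by
#' generating the transposed configuration and reversing the series (time
#' reversal exchanges preceding and following windows). The asymmetry is an
#' edge effect of order (j*+k*)/n, so its magnitude is small and the sign
#' law holds only statistically across seeds; see the package vignette.
#'
#' @param j_star,k_star Planted order: preceding/following interval counts.
#' @param lo,hi Interval range bounds in seconds (defaults 0.75 and 1.2).
#' @param n_intervals Series length (default 1200, roughly a 20-minute
#'   recording at ~1 s per beat).
#' @param mu,sigma Center and spread of the generated intervals; defaults
#'   `(lo + hi) / 2` and `(hi - lo) / 6` fill the range without piling up on
#'   the bounds.
#' @param noise White-noise floor as a fraction of the full coupling
#'   amplitude (default 0.05). The uncorrelated head of the series is this
#'   floor alone.
#' @param seed Integer seed; the series is deterministic given the seed.
#' @param grid_max Grid bound the template is designed against (default 30,
#'   automatically enlarged to cover the planted order).
#' @param subject_id Identifier attached to the series.
#' @return An [rr_series] with `group = "synthetic"`.
#' @examples
#' rr <- generate_validation_series(j_star = 5, k_star = 10,
#'                                  n_intervals = 600, seed = 1)
#' range(rr$intervals)
#' @export
generate_validation_series <- function(j_star, k_star, lo = 0.75, hi = 1.2,
                                       n_intervals = 1200L,
                                       mu = (lo + hi) / 2,
                                       sigma = (hi - lo) / 6,
                                       noise = 0.05, seed = 1L,
                                       grid_max = 30L,
                                       subject_id = sprintf("synth_j%d_k%d", j_star, k_star)) {
  j_star <- as.integer(j_star); k_star <- as.integer(k_star)
  n_intervals <- as.integer(n_intervals)
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  if (j_star < 1L || k_star < 1L) stop("j_star and k_star must be >= 1")
  if (n_intervals <= 4L * (j_star + k_star))
    stop("n_intervals must be at least 4 * (j_star + k_star)")
  if (noise < 0) stop("noise must be >= 0")
  grid_max <- max(as.integer(grid_max), j_star + 5L, k_star + 5L)
  # canonical ascending order; j_star > k_star is its time reversal
  h <- template_kernel(j_star, k_star, grid_max = grid_max)
  with_preserved_rng(seed, {
    n <- n_intervals
    q <- length(h)
    zeta <- stats::rnorm(n + q)
    z <- as.numeric(stats::filter(zeta, h, method = "convolution",
                                  sides = 1))[(q + 1L):(q + n)]
    z <- z / stats::sd(z)
    ramp <- seq(0, 1, length.out = n)       # coupling onset
    x <- ramp * z + noise * stats::rnorm(n)
    rr <- mu + sigma * x / stats::sd(x)
    rr <- pmin(pmax(rr, lo), hi)            # range limit overrides structure
    if (j_star > k_star) rr <- rev(rr)
    rr_series(rr, subject_id = subject_id, group = "synthetic")
  })
}

# truncated-normal draw by sequential re-draw (one value per accepted draw)
rtrunc_norm <- function(n, mu, sigma, lo, hi, max_tries = 10000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in seq_len(max_tries)) {
      v <- stats::rnorm(1L, mu, sigma)
      if (v >= lo && v <= hi) break
      v <- NA_real_
    }
    if (is.na(v))
      stop("truncated-normal rejection failed; bounds too far from mu/sigma")
    out[i] <- v
  }
  out
}

#' Uncorrelated (white-noise) tachogram
#'
#' I.i.d. truncated-normal RR intervals in `[lo, hi]` with no temporal
#' structure — the null fixture emulating the scattered, memoryless
#' short-range pattern of an atrial-fibrillation tachogram. Equivalent to
#' [generate_correlated_series()] with `phi = 0`.
#'
#' @param n Number of intervals (>= 3).
#' @inheritParams generate_validation_series
#' @return An [rr_series] with `group = "synthetic"`.
#' @export
generate_white_noise_series <- function(n, lo = 0.75, hi = 1.2,
                                        mu = (lo + hi) / 2,
                                        sigma = (hi - lo) / 6,
                                        seed = 1L,
                                        subject_id = "white_noise") {
  generate_correlated_series(n, phi = 0, lo = lo, hi = hi, mu = mu,
                             sigma = sigma, seed = seed,
                             subject_id = subject_id)
}

#' Autocorrelated tachogram (AR(1))
#'
#' Mean-reverting first-order autoregressive RR series mapped into
#' `[lo, hi]`: each interval reverts toward `mu` with persistence `phi`, with
#' innovations scaled so the marginal spread stays `sigma`; out-of-range
#' draws are rejected and re-drawn. A healthy-like fixture with slow beat-to-
#' beat modulation. `phi = 0` reduces to the white-noise generator.
#'
#' @param n Number of intervals (>= 3).
#' @param phi Lag-1 autoregression coefficient, |phi| < 1.
#' @inheritParams generate_validation_series
#' @return An [rr_series] with `group = "synthetic"`.
#' @export
generate_correlated_series <- function(n, phi, lo = 0.75, hi = 1.2,
                                       mu = (lo + hi) / 2,
                                       sigma = (hi - lo) / 6,
                                       seed = 1L,
                                       subject_id = sprintf("ar1_phi%g", phi)) {
  n <- as.integer(n)
  if (n < 3L) stop("need n >= 3 intervals")
  if (abs(phi) >= 1) stop("|phi| must be < 1 for a stationary series")
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  innov_sd <- sigma * sqrt(1 - phi^2)
  with_preserved_rng(seed, {
    rr <- numeric(n)
    rr[1L] <- rtrunc_norm(1L, mu, sigma, lo, hi)
    for (t in 2:n) {
      center <- mu + phi * (rr[t - 1L] - mu)
      rr[t] <- rtrunc_norm(1L, center, innov_sd, lo, hi)
    }
    rr_series(rr, subject_id = subject_id, group = "synthetic")
  })
}
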