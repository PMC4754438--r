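# Independent oracles used across the suite. Deliberately naive: direct
# double loops over the definitions, no shared code with the implementation.

# r(j,k) by explicit per-cell window summation and stats::cor
naive_gpp_matrix <- function(rr, m, n) {
  if (inherits(rr, "rr_series")) rr <- rr$intervals
  nn <- length(rr)
  out <- matrix(NA_real_, m, n)
  for (j in seq_len(m)) {
    for (k in seq_len(n)) {
      npts <- nn - j - k
      if (npts < 3) next
      xs <- ys <- numeric(npts)
      for (i in seq_len(npts)) {
        xs[i] <- sum(rr[i:(i + j - 1)])
        ys[i] <- sum(rr[(i + j):(i + j + k - 1)])
      }
      if (stats::sd(xs) > 0 && stats::sd(ys) > 0) out[j, k] <- stats::cor(xs, ys)
    }
  }
  out
}

# strict-8-neighborhood local maxima by exhaustive scan
brute_maxima <- function(r) {
  m <- nrow(r); n <- ncol(r)
  hits <- NULL
  for (j in seq_len(m)) {
    for (k in seq_len(n)) {
      if (is.na(r[j, k])) next
      ok <- TRUE
      for (dj in -1:1) for (dk in -1:1) {
        if (dj == 0 && dk == 0) next
        jj <- j + dj; kk <- k + dk
        if (jj < 1 || jj > m || kk < 1 || kk > n) next
        if (!is.na(r[jj, kk]) && r[j, k] <= r[jj, kk]) ok <- FALSE
      }
      if (ok) hits <- rbind(hits, c(j, k, r[j, k]))
    }
  }
  if (is.null(hits)) return(data.frame(j = integer(0), k = integer(0), r = numeric(0)))
  hits <- hits[order(-hits[, 3]), , drop = FALSE]
  data.frame(j = as.integer(hits[, 1]), k = as.integer(hits[, 2]), r = hits[, 3])
}

random_rr <- function(n, seed) {
  set.seed(seed)
  rr_series(runif(n, 0.6, 1.3), subject_id = paste0("rnd", seed))
}

# pooled maxima with the four-cluster cohort geometry: a low-order cluster,
# one with k >> j, one with j >> k, and a high-order cluster
four_cluster_blobs <- function(seed, per = 30) {
  set.seed(seed)
  mk <- function(cj, ck, cr, lab, sd = 4, sdr = 0.04)
    data.frame(j = rnorm(per, cj, sd), k = rnorm(per, ck, sd),
               r = rnorm(per, cr, sdr), subject_id = "s",
               group = "synthetic", lab = lab)
  rbind(mk(5, 5, 0.55, "low"), mk(15, 70, 0.30, "kgg"),
        mk(70, 15, 0.30, "jgg"), mk(75, 75, 0.20, "high"))
}
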