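#' Local maxima of an r(j,k) correlation matrix
#'
#' A cell is a local maximum when it is defined and strictly greater than
#' every defined cell in its 8-neighborhood. Border cells are eligible (the
#' comparison runs over the neighbors that exist) and plateaus yield no
#' maximum: a tie with any defined neighbor disqualifies the cell. Each
#' maximum of correlation is a candidate time scale at which a regulatory
#' mechanism couples preceding and following summed RR intervals.
#'
#' @param matrix A [gpp_matrix] (or plain numeric matrix with `NA` for
#'   undefined cells).
#' @param subject_id,group Provenance tags attached to each maximum.
#' @return Data frame with columns `j`, `k`, `r`, `subject_id`, `group`,
#'   sorted by descending `r`. Matrices smaller than 3 x 3 yield an empty
#'   frame with a message, not an error.
#' @examples
#' m <- matrix(0, 5, 5); m[2, 4] <- 0.8; m[4, 2] <- 0.5
#' find_local_maxima(m)[, c("j", "k", "r")]
#' @export
find_local_maxima <- function(matrix, subject_id = NULL, group = NULL) {
  gm <- as_gpp_matrix(matrix)
  if (is.null(subject_id)) subject_id <- gm$subject_id
  if (is.null(group)) group <- "unknown"
  empty <- data.frame(j = integer(0), k = integer(0), r = numeric(0),
                      subject_id = character(0), group = character(0),
                      stringsAsFactors = FALSE)
  if (gm$m < 3L || gm$n < 3L) {
    message("matrix smaller than 3 x 3; no local maxima reported")
    return(empty)
  }
  # Pad with NA so every cell has 8 addressable neighbors.
  pad <- matrix(NA_real_, gm$m + 2L, gm$n + 2L)
  pad[2:(gm$m + 1L), 2:(gm$n + 1L)] <- gm$r
  core_i <- 2:(gm$m + 1L)
  core_j <- 2:(gm$n + 1L)
  is_max <- gm$defined
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- pad[core_i + di, core_j + dj, drop = FALSE]
      # strict: value must exceed every DEFINED neighbor; NA neighbors pass
      is_max <- is_max & (is.na(nb) | (gm$r > nb))
    }
  }
  is_max[is.na(is_max)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(j = as.integer(idx[, 1L]), k = as.integer(idx[, 2L]),
                    r = gm$r[idx],
                    subject_id = as.character(subject_id),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool local maxima across subjects
#'
#' Concatenates per-subject maxima into one (j, k, r) point cloud for
#' cohort-level clustering, preserving each triple and its subject/group
#' provenance bit-exactly (no re-detection).
#'
#' @param per_subject A list whose elements are either maxima data frames
#'   (as returned by [find_local_maxima()]) or fitted [gpp] objects.
#' @return Object of class `gpp_maxima_set`: the pooled data frame with an
#'   attribute `group_counts` (maxima per group).
#' @export
pool_maxima <- function(per_subject) {
  if (!length(per_subject)) stop("need at least one subject")
  frames <- lapply(per_subject, function(x) {
    if (inherits(x, "gpp")) x$maxima else as.data.frame(x)
  })
  pooled <- do.call(rbind, frames)
  rownames(pooled) <- NULL
  structure(pooled,
            group_counts = if (nrow(pooled)) table(pooled$group) else table(character(0)),
            class = c("gpp_maxima_set", "data.frame"))
}

#' Cluster pooled correlation maxima with k-means
#'
#' Partitions pooled local maxima in the three raw coordinates (j, k, r) with
#' k-means (10 random restarts, best within-cluster sum of squares,
#' seed-controlled). By default the coordinates are NOT standardized: j and k
#' live on the grid scale (1..m) and r in \[-1, 1\], and clustering the raw
#' triples is what groups maxima by the time scale they occupy; an optional
#' `standardize` flag rescales each coordinate to unit variance.
#'
#' When `k = "auto"` the number of clusters is chosen by maximizing the mean
#' silhouette width over k = 2..8 (capped below the number of points).
#'
#' @param pooled A `gpp_maxima_set` from [pool_maxima()] (or any data frame
#'   with columns `j`, `k`, `r`).
#' @param k Number of clusters, or `"auto"` for silhouette-based selection.
#' @param seed Integer seed making the partition deterministic.
#' @param standardize Rescale the three coordinates to unit variance first.
#' @param k_range Candidate cluster counts tried under `"auto"`.
#' @param nstart Random restarts per k-means run.
#' @return Object of class `gpp_clusters`: list with `n_clusters`,
#'   `centroids` (data frame j, k, r on the original scale), `assignments`
#'   (integer vector), `selection` (k vs mean silhouette, when auto),
#'   `selection_score`, the `kmeans` fit and the input `data`.
#' @examples
#' set.seed(1)
#' pts <- data.frame(j = c(rnorm(20, 5), rnorm(20, 40)),
#'                   k = c(rnorm(20, 5), rnorm(20, 40)),
#'                   r = 0.5, subject_id = "s", group = "synthetic")
#' cluster_maxima(pts, k = 2, seed = 1)$centroids
#' @export
cluster_maxima <- function(pooled, k = "auto", seed = 1L,
                           standardize = FALSE, k_range = 2:8,
                           nstart = 10L) {
  pooled <- as.data.frame(pooled)
  need <- c("j", "k", "r")
  if (!all(need %in% names(pooled)))
    stop("pooled maxima need columns j, k, r")
  xyz <- as.matrix(pooled[, need])
  npts <- nrow(xyz)
  feat <- xyz
  if (standardize) feat <- scale(feat)
  selection <- NULL
  if (identical(k, "auto")) {
    ks <- k_range[k_range < npts & k_range >= 2L]
    if (!length(ks))
      stop("too few points (", npts, ") for automatic cluster-count selection")
    sil <- vapply(ks, function(kk) {
      fit <- with_preserved_rng(seed, stats::kmeans(feat, centers = kk,
                                                    nstart = nstart))
      mean(cluster::silhouette(fit$cluster, stats::dist(feat))[, "sil_width"])
    }, numeric(1))
    selection <- data.frame(k = ks, mean_silhouette = sil)
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (npts < k)
    stop("cannot form ", k, " clusters from ", npts, " pooled maxima")
  fit <- with_preserved_rng(seed, stats::kmeans(feat, centers = k,
                                                nstart = nstart))
  # centroids reported on the original (j, k, r) scale
  cent <- vapply(seq_len(k), function(cl)
    colMeans(xyz[fit$cluster == cl, , drop = FALSE]), numeric(3))
  centroids <- as.data.frame(t(cent))
  names(centroids) <- need
  score <- if (!is.null(selection)) max(selection$mean_silhouette) else NA_real_
  structure(
    list(n_clusters = k, centroids = centroids,
         assignments = fit$cluster, selection = selection,
         selection_score = score, kmeans = fit,
         standardize = standardize, seed = as.integer(seed),
         data = pooled),
    class = "gpp_clusters"
  )
}

#' @export
print.gpp_clusters <- function(x, ...) {
  cat(sprintf("k-means partition of %d pooled (j, k, r) maxima into %d clusters\n",
              nrow(x$data), x$n_clusters))
  if (!is.null(x$selection))
    cat(sprintf("  k selected by mean silhouette (%.3f)\n", x$selection_score))
  cat("  centroids:\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Per-cluster, per-group summary of correlation maxima
#'
#' For every cluster x group combination, reports the number of maxima, the
#' mean of their r values and its standard error (sd/sqrt(n)); the shape used
#' to compare cluster correlation strength between cohorts. Empty cells get
#' `n = 0` and `NA` statistics; single-member cells have an undefined SE.
#'
#' @param model A fitted [gpp_clusters] object.
#' @param pooled Optional pooled maxima (defaults to the data the model was
#'   fitted to).
#' @return Data frame with columns `cluster`, `group`, `n`, `mean_r`, `se_r`.
#' @export
summarize_clusters <- function(model, pooled = NULL) {
  stopifnot(inherits(model, "gpp_clusters"))
  if (is.null(pooled)) pooled <- model$data
  pooled <- as.data.frame(pooled)
  groups <- sort(unique(as.character(pooled$group)))
  out <- expand.grid(cluster = seq_len(model$n_clusters), group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_for <- function(cl, g) {
    v <- pooled$r[model$assignments == cl & pooled$group == g]
    n <- length(v)
    c(n = n,
      mean_r = if (n) mean(v) else NA_real_,
      se_r = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_)
  }
  st <- t(mapply(stats_for, out$cluster, out$group))
  out$n <- as.integer(st[, "n"])
  out$mean_r <- st[, "mean_r"]
  out$se_r <- st[, "se_r"]
  out[order(out$cluster, out$group), , drop = FALSE]
}

#' @export
summary.gpp_clusters <- function(object, ...) {
  print(object)
  tab <- summarize_clusters(object)
  cat("  per-cluster, per-group r summary:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the tie-corrected
#' normal approximation, reporting the U statistic, the signed standard
#' normal deviate Z and the p value. Z is positive when `a` tends to exceed
#' `b`. The p value comes from [stats::wilcox.test()] (normal approximation,
#' no continuity correction), matching `2 * pnorm(-|Z|)`.
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `Z`, `p.value`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(5, 6, 7), c(1, 2, 3))
#' @export
compare_groups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); nn <- n1 + n2
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  if (sigma2 <= 0)
    stop("degenerate samples: all pooled values tied, Z undefined")
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  p <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  list(U = u, Z = z, p.value = p, n_a = n1, n_b = n2)
}
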