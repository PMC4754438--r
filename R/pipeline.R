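#' Run the full cohort analysis pipeline
#'
#' For every subject listed in a manifest (columns `subject_id`, `group`,
#' `path`), reads the tachogram, fits the generalized Poincare analysis
#' ([gpp()]: r(j,k) matrix, surrogate correction, asymmetry indices, local
#' maxima), then pools the maxima across subjects, clusters them with
#' k-means and summarizes clusters per group. When the manifest holds exactly
#' two groups, asymmetry indices (NAIsh, NAIC) and per-cluster r values are
#' compared between groups with the Mann-Whitney U test.
#'
#' Outputs written to `output_dir`: `asymmetry.csv` (one row per subject),
#' `maxima.csv` (pooled maxima), `cluster_summary.csv` (per-cluster,
#' per-group N / mean r / SE, with Z and p when two groups are present),
#' `group_tests.csv`, optional per-subject matrix CSVs and PNG figures, and
#' `run.json` recording configuration and seeds.
#'
#' @param manifest Path to a manifest CSV, or an equivalent data frame.
#' @param output_dir Directory for results (created if needed).
#' @param m,n Grid bounds (default 100).
#' @param n_reshuffles Surrogate reshufflings per subject (default 10).
#' @param seed Master seed; per-subject seeds are spawned from it.
#' @param cluster_k Number of maxima clusters, or `"auto"` (silhouette).
#' @param units Tachogram units, `"s"` or `"ms"`.
#' @param write_matrices Also write each subject's r(j,k) matrix CSV.
#' @param plots Write PNG figures (matrix heat maps, cluster scatter).
#' @return Invisibly, a list with `fits`, `asymmetry` (data frame), `pooled`
#'   maxima, the `clusters` model, `cluster_summary` and `group_tests`.
#' @export
run_pipeline <- function(manifest, output_dir, m = 100L, n = 100L,
                         n_reshuffles = 10L, seed = 1L, cluster_k = "auto",
                         units = "s", write_matrices = FALSE, plots = TRUE) {
  man <- if (is.character(manifest)) utils::read.csv(manifest, stringsAsFactors = FALSE)
         else as.data.frame(manifest)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (!nrow(man)) stop("empty manifest")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  sub_seeds <- spawn_seeds(seed, nrow(man))
  fits <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rr <- read_rr(man$path[i], units = units,
                  subject_id = man$subject_id[i], group = man$group[i])
    fits[[i]] <- gpp(rr, m = m, n = n, n_reshuffles = n_reshuffles,
                     seed = sub_seeds[i])
    if (write_matrices)
      write_matrix_csv(fits[[i]]$matrix,
                       file.path(output_dir,
                                 paste0("matrix_", man$subject_id[i], ".csv")))
    if (plots)
      plot_matrix_file(fits[[i]]$matrix,
                       file.path(output_dir,
                                 paste0("matrix_", man$subject_id[i], ".png")))
  }
  asym <- write_asymmetry_csv(fits, file.path(output_dir, "asymmetry.csv"))
  pooled <- pool_maxima(fits)
  write_maxima_csv(pooled, file.path(output_dir, "maxima.csv"))

  clusters <- NULL
  cl_sum <- NULL
  if (nrow(pooled) >= 2L) {
    clusters <- tryCatch(
      cluster_maxima(pooled, k = cluster_k, seed = seed),
      error = function(e) {
        message("clustering skipped: ", conditionMessage(e)); NULL
      })
    if (!is.null(clusters)) cl_sum <- summarize_clusters(clusters, pooled)
  }

  groups <- unique(man$group)
  tests <- NULL
  if (length(groups) == 2L) {
    ga <- groups[1L]; gb <- groups[2L]
    cmp_row <- function(what, a, b) {
      ok <- length(a[!is.na(a)]) > 0 && length(b[!is.na(b)]) > 0
      res <- if (ok) tryCatch(compare_groups(a[!is.na(a)], b[!is.na(b)]),
                              error = function(e) NULL) else NULL
      data.frame(comparison = what, group_a = ga, group_b = gb,
                 Z = if (is.null(res)) NA_real_ else res$Z,
                 p = if (is.null(res)) NA_real_ else res$p.value,
                 stringsAsFactors = FALSE)
    }
    tests <- rbind(
      cmp_row("nai_sh", asym$nai_sh[asym$group == ga],
              asym$nai_sh[asym$group == gb]),
      cmp_row("naic", asym$naic[asym$group == ga],
              asym$naic[asym$group == gb]))
    if (!is.null(clusters) && !is.null(cl_sum)) {
      cl_sum$Z <- NA_real_; cl_sum$p <- NA_real_
      for (cl in seq_len(clusters$n_clusters)) {
        ra <- pooled$r[clusters$assignments == cl & pooled$group == ga]
        rb <- pooled$r[clusters$assignments == cl & pooled$group == gb]
        if (length(ra) && length(rb)) {
          res <- tryCatch(compare_groups(ra, rb), error = function(e) NULL)
          if (!is.null(res)) {
            cl_sum$Z[cl_sum$cluster == cl] <- res$Z
            cl_sum$p[cl_sum$cluster == cl] <- res$p.value
          }
        }
      }
    }
    utils::write.csv(tests, file.path(output_dir, "group_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cl_sum))
    utils::write.csv(cl_sum, file.path(output_dir, "cluster_summary.csv"),
                     row.names = FALSE)
  if (plots && !is.null(clusters)) {
    grDevices::png(file.path(output_dir, "clusters.png"),
                   width = 900, height = 900, res = 120)
    plot.gpp_clusters(clusters)
    grDevices::dev.off()
  }

  jsonlite::write_json(
    list(package = "gpoincare",
         version = as.character(utils::packageVersion("gpoincare")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         config = list(m = m, n = n, n_reshuffles = n_reshuffles,
                       seed = seed, cluster_k = cluster_k, units = units),
         subject_seeds = as.list(stats::setNames(sub_seeds, man$subject_id)),
         n_subjects = nrow(man), groups = as.list(table(man$group))),
    file.path(output_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fits = fits, asymmetry = asym, pooled = pooled,
                 clusters = clusters, cluster_summary = cl_sum,
                 group_tests = tests))
}
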