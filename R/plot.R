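#' Plot a generalized Poincare point set
#'
#' Scatter of summed preceding vs following window durations with the
#' identity line and the SD1/SD2 axes drawn through the centroid: SD2 along
#' the identity direction, SD1 perpendicular to it, each segment extending
#' one standard deviation either way.
#'
#' @param x A [gpp_points] object.
#' @param main Plot title; defaults to the order.
#' @param col Point color.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gpp_points <- function(x, main = NULL,
                            col = grDevices::adjustcolor("steelblue", 0.5),
                            ...) {
  if (is.null(main))
    main <- sprintf("gPp order (j = %d, k = %d), %d points",
                    x$j, x$k, x$n_points)
  graphics::plot(x$x, x$y, pch = 16, cex = 0.5, col = col, asp = 1,
                 xlab = sprintf("sum of %d preceding RR intervals (s)", x$j),
                 ylab = sprintf("sum of %d following RR intervals (s)", x$k),
                 main = main, ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  sd <- sd1_sd2(x)
  cx <- mean(x$x); cy <- mean(x$y)
  u <- sd[["sd2"]] / sqrt(2)   # along identity
  v <- sd[["sd1"]] / sqrt(2)   # across identity
  graphics::segments(cx - u, cy - u, cx + u, cy + u, lwd = 2)
  graphics::segments(cx + v, cy - v, cx - v, cy + v, lwd = 2)
  invisible(x)
}

#' Heat map of an r(j,k) matrix with local maxima overlaid
#'
#' Filled image of the correlation over the (j, k) grid — j on the abscissa
#' (preceding count), k on the ordinate (following count) — with detected
#' local maxima drawn as points. Undefined cells are left blank.
#'
#' @param x A [gpp_matrix].
#' @param maxima Optional maxima data frame ([find_local_maxima()]); computed
#'   from `x` when `TRUE` (default); `NULL`/`FALSE` to omit.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.gpp_matrix <- function(x, maxima = TRUE, main = "r(j,k)", ...) {
  pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
  lim <- max(abs(x$r), na.rm = TRUE)
  graphics::image(seq_len(x$m), seq_len(x$n), x$r,
                  col = pal, zlim = c(-lim, lim),
                  xlab = "j (preceding intervals)",
                  ylab = "k (following intervals)", main = main, ...)
  graphics::abline(0, 1, lty = 2)
  if (isTRUE(maxima)) maxima <- suppressMessages(find_local_maxima(x))
  if (is.data.frame(maxima) && nrow(maxima))
    graphics::points(maxima$j, maxima$k, pch = 21, bg = "black",
                     col = "white", cex = 0.9)
  invisible(x)
}

#' Plot a fitted gPp analysis
#'
#' Displays the physiological r(j,k) matrix with its local maxima and, when
#' a surrogate was fitted, the averaged reshuffled matrix beside it.
#'
#' @param x A fitted [gpp] object.
#' @param which `"matrix"`, `"surrogate"` or `"both"` (default `"both"` when
#'   a surrogate exists).
#' @param ... Passed to [plot.gpp_matrix()].
#' @return `x`, invisibly.
#' @export
plot.gpp <- function(x, which = c("auto", "matrix", "surrogate", "both"),
                     ...) {
  which <- match.arg(which)
  if (which == "auto") which <- if (is.null(x$surrogate)) "matrix" else "both"
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("matrix", "both"))
    plot.gpp_matrix(x$matrix, maxima = x$maxima,
                    main = sprintf("%s: r(j,k)", x$subject_id), ...)
  if (which %in% c("surrogate", "both") && !is.null(x$surrogate))
    plot.gpp_matrix(x$surrogate, maxima = FALSE,
                    main = sprintf("%s: reshuffled", x$subject_id), ...)
  invisible(x)
}

#' @export
plot.gpp_clusters <- function(x, ...) {
  pal <- grDevices::hcl.colors(max(x$n_clusters, 2L), "Dark 3")
  graphics::plot(x$data$j, x$data$k, col = pal[x$assignments], pch = 16,
                 xlab = "j (preceding intervals)",
                 ylab = "k (following intervals)",
                 main = sprintf("%d clusters of pooled (j, k, r) maxima",
                                x$n_clusters), ...)
  graphics::points(x$centroids$j, x$centroids$k, pch = 3, cex = 2, lwd = 2)
  invisible(x)
}

#' Save a gPp scatter or matrix figure to a file
#'
#' Thin wrappers writing the corresponding plot method to a PNG file, used by
#' the command-line interface.
#'
#' @param points A [gpp_points] object.
#' @param matrix A [gpp_matrix].
#' @param maxima Optional maxima overlay (see [plot.gpp_matrix()]).
#' @param file Output PNG path.
#' @param width,height,res Device geometry passed to [grDevices::png()].
#' @return `file`, invisibly.
#' @export
plot_gpp_file <- function(points, file, width = 900, height = 900, res = 120) {
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot.gpp_points(points)
  invisible(file)
}

#' @rdname plot_gpp_file
#' @export
plot_matrix_file <- function(matrix, file, maxima = TRUE,
                             width = 900, height = 900, res = 120) {
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot.gpp_matrix(as_gpp_matrix(matrix), maxima = maxima)
  invisible(file)
}
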