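#' Plot state / observation / estimate trajectories
#'
#' One panel per selected gene; Boolean series are drawn as step functions,
#' continuous series as lines. Several series (e.g. the true simulated
#' states and the filter's estimates) are overlaid with distinct line types
#' and colors — by default the first series solid black and the second
#' dashed red, the usual original-vs-estimate convention.
#'
#' @param series An n x d matrix with gene-named columns, a
#'   `pobds_trajectory` (its `X` is plotted), or a list of such matrices
#'   sharing n and gene names.
#' @param labels Optional legend labels, one per series.
#' @param genes Genes to plot (names or indices); default all.
#' @param file Optional path; when set, the figure is written there as PNG
#'   (`.png`) or SVG (`.svg`) instead of the current device.
#' @param main Overall title.
#' @return Invisibly `NULL`; called for its side effect.
#' @export
plot_trajectory <- function(series, labels = NULL, genes = NULL, file = NULL,
                            main = NULL) {
  if (inherits(series, "pobds_trajectory")) series <- series$X
  if (is.matrix(series) || is.data.frame(series)) series <- list(as.matrix(series))
  series <- lapply(series, function(s)
    if (inherits(s, "pobds_trajectory")) s$X else as.matrix(s))
  if (length(series) < 1L) stop("no series to plot")
  gn <- colnames(series[[1]])
  if (is.null(gn)) gn <- paste0("gene", seq_len(ncol(series[[1]])))
  n <- nrow(series[[1]])
  for (s in series)
    if (nrow(s) != n || ncol(s) != length(gn))
      stop("all series must share the same length and gene set")
  if (is.null(genes)) genes <- gn
  if (is.numeric(genes)) genes <- gn[genes]
  unknown <- setdiff(genes, gn)
  if (length(unknown))
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")))
  if (length(genes) < 1L) stop("'genes' must select at least one gene")
  if (is.null(labels)) labels <- paste0("series ", seq_along(series))

  if (!is.null(file)) {
    open_device(file)
    on.exit(grDevices.dev_off(), add = TRUE)
  }
  cols <- c("black", "red", "blue", "darkgreen", "orange")
  ltys <- c(1, 2, 3, 4, 5)
  op <- graphics::par(mfrow = c(length(genes), 1),
                      mar = c(2.5, 4, 1.5, 1), oma = c(0, 0, if (is.null(main)) 0 else 2, 0))
  on.exit(graphics::par(op), add = TRUE)
  for (g in genes) {
    vals <- lapply(series, function(s) s[, g])
    boolean <- all(unlist(vals) %in% c(0, 1))
    ylim <- range(unlist(vals))
    if (boolean) ylim <- c(-0.1, 1.1)
    graphics::plot(NULL, xlim = c(1, n), ylim = ylim, xlab = "", ylab = g,
                   yaxt = if (boolean) "n" else "s")
    if (boolean) graphics::axis(2, at = c(0, 1))
    for (i in seq_along(vals))
      graphics::lines(seq_len(n), vals[[i]],
                      type = if (all(vals[[i]] %in% c(0, 1))) "s" else "l",
                      col = cols[(i - 1) %% length(cols) + 1],
                      lty = ltys[(i - 1) %% length(ltys) + 1])
    if (g == genes[1] && length(series) > 1L)
      graphics::legend("topright", legend = labels, bty = "n", cex = 0.8,
                       col = cols[(seq_along(series) - 1) %% length(cols) + 1],
                       lty = ltys[(seq_along(series) - 1) %% length(ltys) + 1])
  }
  if (!is.null(main)) graphics::mtext(main, outer = TRUE, cex = 1.1)
  invisible(NULL)
}

open_device <- function(file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 700),
         svg = grDevices::svg(file, width = 9, height = 7),
         stop("'file' must end in .png or .svg"))
}

grDevices.dev_off <- function() grDevices::dev.off()

#' Plot the MMAE posterior of a model over time
#'
#' Posterior-probability curve of the selected (or any designated) candidate
#' model across the processed time steps, with the stopping threshold drawn
#' as a horizontal rule.
#'
#' @param result An `mmae_result`.
#' @param model Model index to plot; defaults to the selected model, or the
#'   final argmax when no model crossed the threshold.
#' @param file Optional `.png`/`.svg` output path.
#' @return Invisibly `NULL`.
#' @export
plot_mmae_posterior <- function(result, model = NULL, file = NULL) {
  stopifnot(inherits(result, "mmae_result"))
  h <- result$posterior_history
  if (is.null(h) || nrow(h) == 0L) stop("empty posterior history")
  if (is.null(model))
    model <- if (!is.na(result$selected_model)) result$selected_model else result$argmax_final
  if (model < 1 || model > ncol(h)) stop("model index out of range")
  if (!is.null(file)) {
    open_device(file)
    on.exit(grDevices.dev_off(), add = TRUE)
  }
  graphics::plot(seq_len(nrow(h)), h[, model], type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "time point",
                 ylab = "posterior model probability",
                 main = result$labels[model])
  graphics::abline(h = result$threshold, lty = 3)
  if (!is.na(result$stop_time) && result$stop_time <= nrow(h))
    graphics::abline(v = result$stop_time, lty = 3, col = "grey50")
  invisible(NULL)
}
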