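# Forest-plot rendering of a plan-results table: one row per analysis,
# point estimate with interval, reference line at PRR = 1.

#' Forest plot of disproportionality results
#'
#' Rows appear in plan order (top to bottom); the x axis is logarithmic with
#' a dashed reference line at 1.0. Unanalyzable rows are dropped with a
#' message.
#'
#' @param results output of [run_plan()].
#' @return a ggplot object.
#' @export
render_forest <- function(results) {
  df <- results[results$analyzable %in% TRUE, , drop = FALSE]
  if (nrow(df) == 0L) stop("no analyzable rows to render")
  if (nrow(df) < nrow(results))
    message(nrow(results) - nrow(df), " unanalyzable row(s) omitted")
  df$analysis <- factor(df$analysis, levels = rev(df$analysis))
  ggplot2::ggplot(df, ggplot2::aes(x = prr, y = analysis)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "proportional reporting ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Monospace text rendering of a forest plot
#'
#' A log-style rendering for console output: one line per analysis with the
#' interval drawn in characters and `|` marking the reference line at 1.0.
#'
#' @param results output of [run_plan()].
#' @param width character width of the plot band.
#' @return character vector of lines, invisibly; printed to the console.
#' @export
render_forest_text <- function(results, width = 40L) {
  df <- results[results$analyzable %in% TRUE, , drop = FALSE]
  if (nrow(df) == 0L) stop("no analyzable rows to render")
  lo <- min(df$ci_low, 1) * 0.8
  hi <- max(df$ci_high, 1) * 1.2
  pos <- function(x) {
    1L + as.integer(round((log(x) - log(lo)) / (log(hi) - log(lo)) *
                            (width - 1L)))
  }
  ref <- pos(1)
  lines <- character(nrow(df))
  name_w <- max(nchar(df$analysis))
  for (i in seq_len(nrow(df))) {
    band <- rep(" ", width)
    band[ref] <- "|"
    lo_i <- pos(df$ci_low[i]); hi_i <- pos(df$ci_high[i])
    band[seq(lo_i, hi_i)] <- "-"
    band[pos(df$prr[i])] <- "*"
    lines[i] <- sprintf("%-*s %s %5.2f (%4.2f-%4.2f)", name_w,
                        df$analysis[i], paste(band, collapse = ""),
                        df$prr[i], df$ci_low[i], df$ci_high[i])
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
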