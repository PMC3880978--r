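#' Bland-Altman plot of relative deviations
#'
#' One point per lesion: the mean of the original and coregistered value
#' on the x axis, the relative difference (coregistered minus original)
#' on the y axis. Solid line: mean difference; dashed lines: mean
#' +/- 2 SD; dotted lines: 95% limits of agreement (+/- 1.96 SD).
#'
#' @param records deviation-record data frame (see
#'   [relative_difference()]).
#' @param quantity one of `"suvmax"`, `"mtv"`, `"tlg"`.
#' @return A ggplot object, faceted by grid and mode.
#' @export
plot_bland_altman <- function(records, quantity = c("mtv", "suvmax", "tlg")) {
  quantity <- match.arg(quantity)
  cols <- switch(quantity,
    suvmax = c("or_suvmax", "cg_suvmax", "dsuvmax_pct"),
    mtv = c("or_mtv_ml", "cg_mtv_ml", "dmtv_pct"),
    tlg = c("or_tlg_ml", "cg_tlg_ml", "dtlg_pct")
  )
  df <- data.frame(
    grid = records$grid, mode = records$mode, method = records$method,
    mean_value = (records[[cols[1]]] + records[[cols[2]]]) / 2,
    diff_pct = records[[cols[3]]]
  )
  stats_df <- do.call(rbind, lapply(split(df, df[c("grid", "mode")],
                                          drop = TRUE), function(gr) {
    m <- mean(gr$diff_pct)
    s <- sd(gr$diff_pct)
    data.frame(grid = gr$grid[1], mode = gr$mode[1], mean = m,
               lo2 = m - 2 * s, hi2 = m + 2 * s,
               loa_lo = m - 1.96 * s, loa_hi = m + 1.96 * s)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = mean_value,
                                   y = diff_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = mean)) +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = lo2),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = hi2),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = loa_lo),
                        linetype = "dotted") +
    ggplot2::geom_hline(data = stats_df,
                        ggplot2::aes(yintercept = loa_hi),
                        linetype = "dotted") +
    ggplot2::facet_grid(grid ~ mode) +
    ggplot2::labs(x = sprintf("mean of original and coregistered %s",
                              toupper(quantity)),
                  y = "relative difference (%)")
}

#' Box plots of unsigned relative deviations
#'
#' @param records deviation-record data frame.
#' @return A ggplot object: unsigned relative differences per quantity,
#'   grouped by grid and mode.
#' @export
plot_deviation_boxplots <- function(records) {
  long <- do.call(rbind, lapply(
    c(SUVmax = "dsuvmax_pct", MTV = "dmtv_pct", TLG = "dtlg_pct"),
    function(col) data.frame(grid = records$grid, mode = records$mode,
                             quantity = col, value = abs(records[[col]]))
  ))
  long$quantity <- factor(long$quantity,
                          levels = c("dsuvmax_pct", "dmtv_pct", "dtlg_pct"),
                          labels = c("SUVmax", "MTV", "TLG"))
  ggplot2::ggplot(long, ggplot2::aes(x = mode, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(grid ~ quantity) +
    ggplot2::labs(x = NULL, y = "unsigned relative difference (%)")
}
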