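#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided test of symmetry about zero. Zero differences are dropped
#' (Wilcoxon's original treatment); tied absolute differences receive
#' average ranks. For `n <= exact_max_n` effective observations the
#' p-value is computed by exact enumeration over all `2^n` sign
#' patterns of the observed ranks; above that, a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max_n largest `n` for exact enumeration (default 12).
#' @param alpha significance level reported alongside (default 0.05).
#' @return List with `p_value`, `statistic` (W+, the positive-rank sum),
#'   `n_effective`, `method`, `all_zero`, `significant`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.0, 1.5, 0.3, 0.9))$p_value  # 2/64
wilcoxon_signed_rank <- function(d, exact_max_n = 12L, alpha = 0.05) {
  d <- as.numeric(d)
  if (length(d) < 1L || anyNA(d)) stopf("`d` must be non-empty and finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p_value = 1, statistic = 0, n_effective = 0L,
                method = "degenerate (all differences zero)",
                all_zero = TRUE, significant = FALSE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # all 2^n subset rank sums
    eps <- 1e-9
    p_ge <- mean(sums >= w - eps)
    p_le <- mean(sums <= w + eps)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w - mu
    cc <- sign(z) * 0.5
    z <- if (sigma2 > 0) (z - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(p_value = p, statistic = w, n_effective = n, method = method,
       all_zero = FALSE, significant = p < alpha)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `d = a - b`; the 95% limits of agreement are
#' `mean(d) +/- 1.96 sd(d)` (sample SD, n - 1). The `+/- 2 SD` lines
#' often drawn on agreement plots are reported separately.
#'
#' @param a,b paired numeric vectors (n >= 2).
#' @return An object of class `bland_altman`: `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `loa2_low`, `loa2_high`, plus the
#'   per-pair `differences` and `means` for plotting.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  if (length(a) < 2L) stopf("Bland-Altman needs at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stopf("missing values not allowed")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  structure(
    list(n = length(d), mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         loa2_low = m - 2 * s, loa2_high = m + 2 * s,
         differences = d, means = (a + b) / 2),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bland_altman: n = %d, mean diff %.4g, SD %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Group-wise summary of deviation records
#'
#' For each (grid, mode, method) group and each relative-difference
#' quantity, reports n, mean/median/IQR/range of the signed and unsigned
#' deviations, the two-sided Wilcoxon signed-rank p-value against zero,
#' and the Bland-Altman mean difference and 95% limits of agreement.
#' Quantiles use linear interpolation between order statistics (R type
#' 7).
#'
#' @param records data frame of deviation records (rows from
#'   [relative_difference()]).
#' @param quantities columns to summarize.
#' @param by grouping columns.
#' @return Tidy data frame, one row per group x quantity.
#' @export
summarize_deviations <- function(records,
                                 quantities = c("dsuvmax_pct", "dmtv_pct",
                                                "dtlg_pct"),
                                 by = c("grid", "mode", "method")) {
  if (nrow(records) == 0L) stopf("no records to summarize")
  by <- intersect(by, names(records))
  groups <- split(records, records[by], drop = TRUE)
  rows <- lapply(groups, function(gr) {
    do.call(rbind, lapply(quantities, function(q) {
      x <- gr[[q]]
      qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      qa <- quantile(abs(x), c(0.25, 0.75), type = 7, names = FALSE)
      wt <- wilcoxon_signed_rank(x)
      sd_x <- if (length(x) >= 2) sd(x) else NA_real_
      out <- gr[1, by, drop = FALSE]
      rownames(out) <- NULL
      cbind(out, data.frame(
        quantity = q, n = length(x),
        mean = mean(x), median = median(x), q1 = qs[1], q3 = qs[2],
        min = min(x), max = max(x),
        mean_abs = mean(abs(x)), median_abs = median(abs(x)),
        q1_abs = qa[1], q3_abs = qa[2],
        min_abs = min(abs(x)), max_abs = max(abs(x)),
        wilcoxon_p = wt$p_value,
        loa_low = if (is.na(sd_x)) NA_real_ else mean(x) - 1.96 * sd_x,
        loa_high = if (is.na(sd_x)) NA_real_ else mean(x) + 1.96 * sd_x
      ))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
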