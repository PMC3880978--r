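test_that("all-positive differences give the textbook exact p-value", {
  res <- wilcoxon_signed_rank(c(1.2, 0.8, 2.0, 1.5, 0.3, 0.9))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$n_effective, 6)
  expect_true(res$significant)
})

test_that("all-zero differences degenerate to p = 1 with a flag", {
  res <- wilcoxon_signed_rank(c(0, 0, 0, 0))
  expect_equal(res$p_value, 1)
  expect_true(res$all_zero)
  expect_false(res$significant)
})

test_that("exact p-values match full enumeration for n up to 12", {
  set.seed(17)
  for (n in 2:12) {
    d <- round(rnorm(n), 1)  # rounding creates occasional ties and zeros
    d[1] <- d[1] + (d[1] == 0)
    got <- wilcoxon_signed_rank(d)
    expect_lt(abs(got$p_value - wilcoxon_oracle(d)), 1e-12)
  }
})

test_that("tie-free exact p-values agree with the standard implementation", {
  set.seed(23)
  for (i in 1:5) {
    d <- rnorm(10)
    got <- wilcoxon_signed_rank(d)$p_value
    want <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("large samples use a continuity-corrected normal approximation", {
  set.seed(29)
  d <- rnorm(40, mean = 0.3)
  got <- wilcoxon_signed_rank(d)
  expect_match(got$method, "normal")
  want <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_value, want, tolerance = 1e-9)
})

test_that("the p-value is invariant under positive rescaling", {
  set.seed(31)
  d <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcoxon_signed_rank(1000 * d)$p_value)
  d2 <- rnorm(25)
  expect_equal(wilcoxon_signed_rank(d2)$p_value,
               wilcoxon_signed_rank(0.001 * d2)$p_value)
})

test_that("Bland-Altman reproduces hand-computed limits of agreement", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba <- bland_altman(c(0, 2, 4), c(1, 2, 3))  # d = {-1, 0, 1}
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$loa2_low, -2)
  expect_equal(ba$loa2_high, 2)
})

test_that("Bland-Altman is translation invariant and collapses for constant offsets", {
  set.seed(37)
  a <- rnorm(15)
  b <- rnorm(15)
  ba1 <- bland_altman(a, b)
  ba2 <- bland_altman(a + 100, b + 100)
  expect_equal(ba1$mean_diff, ba2$mean_diff)
  expect_equal(ba1$sd_diff, ba2$sd_diff)
  expect_equal(ba1$loa_low, ba2$loa_low)

  x <- rnorm(10)
  bac <- bland_altman(x + 3, x)
  expect_equal(bac$mean_diff, 3)
  expect_equal(bac$sd_diff, 0)
  expect_equal(c(bac$loa_low, bac$loa_high), c(3, 3))

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("group summaries reproduce quantile and degenerate-group behavior", {
  rec <- function(lesion, grid, mode, method, ds, dm, dt) {
    data.frame(lesion = lesion, grid = grid, mode = mode, method = method,
               dsuvmax_pct = ds, dmtv_pct = dm, dtlg_pct = dt)
  }
  single <- rec(1, "ct5", "truth", "AT", -3, 7, 2)
  s1 <- summarize_deviations(single)
  expect_equal(nrow(s1), 3)
  row <- s1[s1$quantity == "dmtv_pct", ]
  expect_equal(row$median, 7)
  expect_equal(row$mean, 7)
  expect_equal(row$q3 - row$q1, 0)

  x <- c(2, 9, 4, 7, 1, 6, 3)
  many <- do.call(rbind, lapply(seq_along(x), function(i)
    rec(i, "ct1", "rf", "T40", x[i], 2 * x[i], x[i])))
  s2 <- summarize_deviations(many)
  row2 <- s2[s2$quantity == "dsuvmax_pct", ]
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(row2$q1, qs[1])
  expect_equal(row2$q3, qs[2])
  expect_equal(row2$median, median(x))
  expect_equal(row2$max_abs, 9)
  # signed and unsigned columns are both present, as in the study tables
  expect_true(all(c("mean", "median", "q1", "q3", "min", "max",
                    "mean_abs", "median_abs", "q1_abs", "q3_abs",
                    "wilcoxon_p", "loa_low", "loa_high") %in% names(s2)))
})

test_that("plot builders return ggplot objects", {
  set.seed(41)
  recs <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(lesion = i, grid = "ct5", mode = "truth", method = "AT",
               or_suvmax = 8, cg_suvmax = 8 - 0.1 * i,
               or_mtv_ml = 3, cg_mtv_ml = 3 + 0.05 * i,
               or_tlg_ml = 12, cg_tlg_ml = 12 + 0.1 * i,
               dsuvmax_pct = -i, dmtv_pct = i, dtlg_pct = 0.5 * i)
  }))
  expect_s3_class(plot_bland_altman(recs, "mtv"), "ggplot")
  expect_s3_class(plot_deviation_boxplots(recs), "ggplot")
})
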