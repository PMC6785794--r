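test_that("relative platelet nadir is the ratio to baseline", {
  expect_equal(relative_platelet_nadir(241, 120.5), 0.5)
  expect_equal(relative_platelet_nadir(200, 200), 1)
  expect_error(relative_platelet_nadir(0, 10), "positive")
})

test_that("Spearman correlation reproduces the worked 5-point example", {
  sp <- spearman_correlation(1:5, c(3, 1, 2, 5, 4))
  expect_equal(sp$estimate, 1 - 6 * 8 / (5 * 24))  # sum d^2 = 8
  expect_true(sp$exact)
  expect_equal(sp$p_value, brute_spearman_p(1:5, c(3, 1, 2, 5, 4)))
  # perfect monotone association: only the two extreme orderings
  expect_equal(spearman_correlation(1:5, 2 * (1:5))$p_value, 2 / 120)
  expect_equal(spearman_correlation(1:5, 5:1)$estimate, -1)
  expect_error(spearman_correlation(1:5, rep(2, 5)), "zero rank variance")
})

test_that("exact Spearman p values match enumeration and cor.test", {
  set.seed(14)
  for (n in 4:6) for (r in 1:3) {
    x <- sample(50, n); y <- sample(50, n)
    expect_equal(spearman_correlation(x, y)$p_value, brute_spearman_p(x, y))
  }
  # tied data against the independent recursive oracle
  x <- c(1, 2, 2, 3, 4); y <- c(5, 5, 3, 2, 1)
  expect_equal(spearman_correlation(x, y)$p_value, brute_spearman_p(x, y))
  for (n in 7:9) for (r in 1:5) {
    x <- sample(500, n); y <- sample(500, n)  # no ties
    sp <- spearman_correlation(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = TRUE))
    expect_equal(sp$estimate, unname(ct$estimate))
    expect_equal(sp$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman is monotone-invariant and antisymmetric", {
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    base <- spearman_correlation(x, y)
    tr <- spearman_correlation(exp(x), y^3 + 5 * y)
    expect_equal(tr$estimate, base$estimate)
    expect_equal(tr$p_value, base$p_value)
    expect_equal(spearman_correlation(x, -y)$estimate, -base$estimate)
  }
})

test_that("Wilcoxon rank-sum reproduces worked and degenerate examples", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))
  expect_equal(w$statistic, 3)
  expect_equal(w$p_value, 0.2)  # 2 of the 10 assignments as extreme
  expect_true(w$exact)
  expect_equal(wilcoxon_rank_sum(7, 7)$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # hand-enumerated tied case: ranks 1, 2.5, 2.5, 4 -> p = 4/6
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(2, 3))$p_value, 4 / 6)
})

test_that("exact Wilcoxon p matches wilcox.test for all sizes up to 8", {
  set.seed(27)
  for (na in 1:4) for (nb in na:(8 - na)) for (r in 1:4) {
    a <- sample(1000, na); b <- sample(1000, nb)  # no ties
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample tie-corrected normal approximation
  a <- c(rnorm(10), rnorm(10)); b <- rnorm(15, 0.8)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("zero-noise monotone cohorts give perfect negative correlations", {
  coh <- simulate_cohort(zero_noise_cohort_spec(24), seed = 3)
  grid <- dose_response_grid(coh)
  expect_true(all(grid$n >= 3))
  expect_true(all(abs(grid$r_s + 1) < 1e-12))
  expect_true(all(grid$significant))
})

test_that("small groups are flagged instead of tested", {
  coh <- simulate_cohort(cohort_spec(n = 1, metastasis_prevalence = 0),
                         seed = 2)
  res <- dose_response_analysis(coh, "planar", 1, "all")
  expect_true(is.na(res$r_s))
  expect_false(res$significant)
})

test_that("group analyses partition the cohort", {
  coh <- simulate_cohort(cohort_spec(n = 20), seed = 5)
  g <- dose_response_grid(coh, methods = "V_SPECT", fractions = 1)
  n_all <- g$n[g$group == "all"]
  expect_equal(n_all, g$n[g$group == "with_mets"] +
                 g$n[g$group == "without_mets"])
})

test_that("group comparisons cover doses and the sex concentration contrast", {
  coh <- simulate_cohort(cohort_spec(n = 24), seed = 8)
  gc <- group_comparisons(coh)
  expect_true(all(c("dose_with_vs_without_mets",
                    "l1_l4_concentration_male_vs_female") %in%
                    gc$comparison))
  expect_true(all(gc$p_value > 0 & gc$p_value <= 1))
  # metastasis elevation raises the hybrid-method dose medians
  dm <- gc[gc$comparison == "dose_with_vs_without_mets" &
             gc$method == "V_SPECT", ]
  expect_gt(dm$median_1, dm$median_2)
})
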