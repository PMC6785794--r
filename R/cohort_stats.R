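#' Relative platelet nadir
#'
#' Ratio of the post-fraction platelet nadir to the pre-treatment baseline.
#' Larger marrow doses give smaller ratios, so dose-response correlations
#' are negative by convention.  Values above 1 (rebound) are allowed.
#'
#' @param baseline Baseline platelet count, 1e9/L (> 0).
#' @param nadir Lowest platelet count in the fraction's follow-up window,
#'   1e9/L (>= 0).
#' @return Unitless ratio `nadir / baseline`.
#' @export
relative_platelet_nadir <- function(baseline, nadir) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be positive", call. = FALSE)
  if (any(nadir < 0)) stop("nadir must be >= 0", call. = FALSE)
  nadir / baseline
}

# cache of permutation index matrices, one entry per n (n! rows)
.perm_cache <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  build <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      rest <- build(v[-i])
      out[[i]] <- cbind(v[i], rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  p <- build(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Spearman's r_s computed as the Pearson correlation of mid-ranks (ties
#' allowed).  The two-sided p value is exact for n <= 9, obtained by full
#' enumeration of all n! permutations of one rank vector (correct also
#' under ties); for larger n the usual t approximation
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `estimate` (r_s), `p_value`, `n` and `exact`
#'   (logical: was the permutation null used).
#' @examples
#' spearman_correlation(1:5, c(3, 1, 2, 5, 4))$estimate  # 0.6
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance", call. = FALSE)
  r_obs <- stats::cor(rx, ry)

  if (n <= 9L) {
    perms <- .all_permutations(n)
    # r for each permutation of ry against fixed rx; only the cross sum
    # changes, so correlate via the linear statistic
    cross <- perms_cross <- matrix(ry[perms], nrow(perms)) %*% rx
    mx <- mean(rx); my <- mean(ry)
    denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    r_all <- (cross - n * mx * my) / denom
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- r_obs * sqrt((n - 2) / max(1 - r_obs^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    exact <- FALSE
  }
  list(estimate = r_obs, p_value = min(p, 1), n = n, exact = exact)
}

#' Wilcoxon rank-sum test with exact small-sample p value
#'
#' Two-sample rank-sum test on mid-ranks.  The statistic is the rank sum of
#' the first group.  For combined sample sizes up to 12 the two-sided p
#' value is exact, computed by enumerating all `choose(n, n_a)` group
#' assignments of the observed (possibly tied) ranks and counting
#' assignments whose rank sum deviates from its null mean at least as far
#' as observed.  For larger samples a normal approximation with the
#' standard tie correction is used (no continuity correction).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List with `statistic` (rank sum of `a`), `p_value`, `n_a`,
#'   `n_b` and `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))$p_value  # exact 0.2
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2

  if (n <= 12L) {
    idx <- combn(n, na)
    w_all <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    exact <- TRUE
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = w_obs, p_value = 1,
                                 n_a = na, n_b = nb, exact = FALSE))
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = w_obs, p_value = min(p, 1), n_a = na, n_b = nb,
       exact = exact)
}

.GROUPS <- c("all", "with_mets", "without_mets")
.METHODS <- c("planar", "L4_SPECT", "V_SPECT", "L_SPECT", "T_SPECT")

# join doses and clinical records of one method/fraction/group; fraction 1
# pairs the fraction dose, fraction >= 2 the cumulative dose, with the
# platelet nadir ratio of that fraction's window
.pair_dose_response <- function(cohort, method, fraction, group,
                                use_cumulative = (fraction >= 2L)) {
  d <- cohort$doses
  d <- d[d$method == method & d$fraction == fraction, , drop = FALSE]
  rec <- cohort$records
  rec <- rec[rec$fraction == fraction, , drop = FALSE]
  m <- merge(d, rec, by = c("patient_id", "fraction"))
  if (group == "with_mets") m <- m[m$skeletal_metastases, , drop = FALSE]
  if (group == "without_mets") m <- m[!m$skeletal_metastases, , drop = FALSE]
  data.frame(
    patient_id = m$patient_id,
    dose = if (use_cumulative) m$cumulative_gy else m$dose_gy,
    response = relative_platelet_nadir(m$baseline_platelets,
                                       m$nadir_platelets)
  )
}

#' Dose-response analysis for one method, fraction and patient group
#'
#' Pairs each patient's bone-marrow absorbed dose (the fraction dose for
#' fraction 1, the cumulative dose for fraction 2 and later) with the
#' relative platelet nadir of that fraction's follow-up window and computes
#' the Spearman correlation.  Significance is declared at alpha = 0.05 on
#' the raw p value (no multiplicity adjustment).
#'
#' @param cohort A list with elements `records` (per patient-fraction
#'   clinical rows: `patient_id`, `fraction`, `sex`,
#'   `skeletal_metastases`, `baseline_platelets`, `nadir_platelets`) and
#'   `doses` (per patient-fraction-method rows: `patient_id`, `fraction`,
#'   `method`, `dose_gy`, `cumulative_gy`), e.g. from [simulate_cohort()].
#' @param method One of `"planar"`, `"L4_SPECT"`, `"V_SPECT"`,
#'   `"L_SPECT"`, `"T_SPECT"`.
#' @param fraction Treatment fraction (1 or 2).
#' @param group Patient group: `"all"`, `"with_mets"` or `"without_mets"`.
#' @param use_cumulative Pair the cumulative dose instead of the fraction
#'   dose; defaults to TRUE from fraction 2 on.
#' @return One-row data frame: `method`, `fraction`, `group`, `n`, `r_s`,
#'   `p_value`, `significant`.  If fewer than 3 patients remain after
#'   filtering, `r_s` and `p_value` are NA and the row is flagged
#'   non-significant.
#' @export
dose_response_analysis <- function(cohort, method, fraction,
                                   group = c("all", "with_mets",
                                             "without_mets"),
                                   use_cumulative = (fraction >= 2L)) {
  group <- match.arg(group)
  method <- match.arg(method, .METHODS)
  pairs <- .pair_dose_response(cohort, method, fraction, group,
                               use_cumulative)
  n <- nrow(pairs)
  if (n < 3L) {
    return(data.frame(method = method, fraction = fraction, group = group,
                      n = n, r_s = NA_real_, p_value = NA_real_,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  sp <- spearman_correlation(pairs$dose, pairs$response)
  data.frame(method = method, fraction = fraction, group = group, n = n,
             r_s = sp$estimate, p_value = sp$p_value,
             significant = is.finite(sp$p_value) && sp$p_value < 0.05,
             stringsAsFactors = FALSE)
}

#' Dose-response grid over all methods, fractions and groups
#'
#' Runs [dose_response_analysis()] for every combination of dosimetry
#' method, treatment fraction and patient group present in the cohort.
#'
#' @inheritParams dose_response_analysis
#' @param methods,fractions,groups Combinations to evaluate; defaults cover
#'   the full grid.
#' @return Data frame with one row per cell.
#' @export
dose_response_grid <- function(cohort, methods = .METHODS,
                               fractions = sort(unique(cohort$doses$fraction)),
                               groups = .GROUPS) {
  rows <- list()
  for (m in methods) for (f in fractions) for (g in groups)
    rows[[length(rows) + 1L]] <- dose_response_analysis(cohort, m, f, g)
  do.call(rbind, rows)
}

#' Cohort group comparisons
#'
#' The two Wilcoxon rank-sum comparisons reported alongside the
#' dose-response grid: per-method absorbed dose in patients with versus
#' without skeletal metastases (fraction-1 dose), and mean L1-L4 vertebral
#' activity concentration in men versus women.
#'
#' @inheritParams dose_response_analysis
#' @return Data frame with columns `comparison`, `method`, `n_1`, `n_2`,
#'   `median_1`, `median_2`, `statistic`, `p_value`.  The L1-L4 sex
#'   comparison row has method NA and requires a
#'   `l1_l4_mean_concentration` column in `cohort$records`.
#' @export
group_comparisons <- function(cohort) {
  rows <- list()
  d1 <- cohort$doses[cohort$doses$fraction == 1L, , drop = FALSE]
  rec1 <- cohort$records[cohort$records$fraction == 1L, , drop = FALSE]
  m <- merge(d1, rec1, by = c("patient_id", "fraction"))
  for (meth in unique(m$method)) {
    dm <- m[m$method == meth, , drop = FALSE]
    a <- dm$dose_gy[dm$skeletal_metastases]
    b <- dm$dose_gy[!dm$skeletal_metastases]
    if (length(a) > 0L && length(b) > 0L) {
      w <- wilcoxon_rank_sum(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "dose_with_vs_without_mets", method = meth,
        n_1 = length(a), n_2 = length(b),
        median_1 = median(a), median_2 = median(b),
        statistic = w$statistic, p_value = w$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if ("l1_l4_mean_concentration" %in% names(rec1)) {
    keep <- !rec1$skeletal_metastases &
      is.finite(rec1$l1_l4_mean_concentration)
    male <- rec1$l1_l4_mean_concentration[keep & rec1$sex == "male"]
    female <- rec1$l1_l4_mean_concentration[keep & rec1$sex == "female"]
    if (length(male) > 0L && length(female) > 0L) {
      w <- wilcoxon_rank_sum(male, female)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "l1_l4_concentration_male_vs_female",
        method = NA_character_, n_1 = length(male), n_2 = length(female),
        median_1 = median(male), median_2 = median(female),
        statistic = w$statistic, p_value = w$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
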