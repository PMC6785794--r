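# Independent oracles used across the test files.

# numerical quadrature of a fitted curve over [0, Inf): adaptive quadrature
# on [0, 2000 h] plus the analytic exponential remainder
quad_tia <- function(curve, t_split = 2000) {
  main <- stats::integrate(function(t) predict(curve, t), 0, t_split,
                           rel.tol = 1e-10, subdivisions = 2000L)$value
  rem <- if (inherits(curve, "tac_biexp")) {
    curve$a1 * exp(-curve$lambda1 * t_split) / curve$lambda1 +
      (if (curve$a2 > 0)
         curve$a2 * exp(-curve$lambda2 * t_split) / curve$lambda2 else 0)
  } else {
    curve$tail_value * exp(-curve$lambda_tail * (t_split - curve$t2)) /
      curve$lambda_tail
  }
  main + rem
}

# exhaustive Spearman permutation p value, written independently of the
# package's vectorised path: recursive permutation generation plus cor()
# per permutation
brute_spearman_p <- function(x, y) {
  perm_gen <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_gen(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  vals <- vapply(perm_gen(ry), function(p) stats::cor(rx, p), numeric(1L))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# calibration object with prescribed parameters, bypassing the fit
make_calibration <- function(sensitivity, mu_eff) {
  structure(list(sensitivity = sensitivity, mu_eff = mu_eff,
                 fit_residual = 0, n = 2L, camera_id = "test"),
            class = "camera_calibration")
}

# cohort specification with every source of between-patient variation
# switched off except the administered activity, so that every dosimetry
# method's dose is strictly proportional to one patient-level scalar
zero_noise_cohort_spec <- function(n = 24L) {
  cohort_spec(
    n = n, male_fraction = 1, metastasis_prevalence = 0.5,
    weight_sd_g = c(female = 0, male = 0),
    abdominal_thickness_sd_cm = 0, high_area_sd_cm2 = 0,
    kinetic_cv = 0, vertebral_cv = 0,
    visibility_prob = setNames(rep(1, 13),
                               vertebral_reference_profile()$label),
    metastasis_elevation = 1, max_hot_vertebrae = 0L,
    toxicity_noise_sd = 0
  )
}
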