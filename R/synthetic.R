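#' Specification of a synthetic planar phantom
#'
#' Describes a digital whole-body phantom with two activity compartments,
#' used to generate anterior/posterior planar count images whose geometry
#' satisfies the conjugate-view assumptions exactly: every source is a
#' uniform slab of known thickness centred in a uniform attenuating body of
#' known thickness.  The high-uptake compartment (liver, spleen, kidneys)
#' holds about an order of magnitude higher projected concentration than
#' the low-uptake background, as in clinical 177Lu-DOTATATE images.
#'
#' Default kinetics (fractions of injected activity): low compartment
#' biexponential with fast fraction 0.62 at 0.20/h and slow fraction 0.11
#' at 0.020/h (the remainder is excreted); high compartment rising linearly
#' from 85% of its 24-h peak at 2 h to a peak fraction 0.20 at 24 h, then
#' decaying at 0.012/h.  These values give whole-body retention, organ
#' contrast and marrow doses in the clinically reported range for
#' 7.4-GBq-fraction therapy.
#'
#' @param body_length_cm,body_width_cm Projected body ellipse axes.
#' @param abdominal_thickness_cm Body (attenuator) thickness, cm.
#' @param organ_thickness_cm Source slab thickness of the organs, cm
#'   (matches the 8 cm general organ thickness used in quantification).
#' @param background_thickness_cm Source slab thickness of the low-uptake
#'   background, cm.
#' @param organs Data frame of projected organ ellipses: `name`, `cx_cm`,
#'   `cy_cm` (centre relative to body centre), `rx_cm`, `ry_cm`,
#'   `share` (share of the high-compartment activity; must sum to 1).
#' @param low_f1,low_lambda1,low_f2,low_lambda2 Low-compartment
#'   biexponential parameters (fractions of injected activity; 1/h).
#' @param high_peak_frac High-compartment activity at its 24-h peak as a
#'   fraction of injected activity.
#' @param high_frac_at_t1 High-compartment activity at 2 h as a fraction of
#'   the peak.
#' @param high_lambda_tail Tail decay constant of the high compartment, 1/h.
#' @param mu_eff_per_cm Effective attenuation coefficient, 1/cm.
#' @param sensitivity_cps_per_mbq Camera sensitivity.
#' @param pixel_spacing_cm Pixel size of the planar grid, cm.
#' @param duration_s Effective acquisition duration per pixel, s.
#' @param injected_mbq Injected activity, MBq.
#' @param poisson_noise Apply Poisson counting noise to the images.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_length_cm = 70, body_width_cm = 30,
                         abdominal_thickness_cm = 20,
                         organ_thickness_cm = 8,
                         background_thickness_cm = 8,
                         organs = NULL,
                         low_f1 = 0.62, low_lambda1 = 0.20,
                         low_f2 = 0.11, low_lambda2 = 0.020,
                         high_peak_frac = 0.20, high_frac_at_t1 = 0.85,
                         high_lambda_tail = 0.012,
                         mu_eff_per_cm = 0.12,
                         sensitivity_cps_per_mbq = 10,
                         pixel_spacing_cm = 0.5, duration_s = 30,
                         injected_mbq = 7500, poisson_noise = FALSE) {
  if (is.null(organs)) {
    organs <- data.frame(
      name = c("liver", "spleen", "kidney_l", "kidney_r"),
      cx_cm = c(5, -8, -4, 4), cy_cm = c(-5, -6, 4, 4),
      rx_cm = c(5.5, 3, 2, 2), ry_cm = c(4.5, 2.5, 3, 3),
      share = c(0.60, 0.12, 0.14, 0.14),
      stringsAsFactors = FALSE
    )
  }
  if (abs(sum(organs$share) - 1) > 1e-9)
    stop("organ shares must sum to 1", call. = FALSE)
  if (!(abdominal_thickness_cm >= organ_thickness_cm &&
        abdominal_thickness_cm >= background_thickness_cm))
    stop("source slabs must fit inside the body thickness", call. = FALSE)
  if (injected_mbq < 0) stop("injected_mbq must be >= 0", call. = FALSE)
  structure(
    list(body_length_cm = body_length_cm, body_width_cm = body_width_cm,
         abdominal_thickness_cm = abdominal_thickness_cm,
         organ_thickness_cm = organ_thickness_cm,
         background_thickness_cm = background_thickness_cm,
         organs = organs,
         low_f1 = low_f1, low_lambda1 = low_lambda1,
         low_f2 = low_f2, low_lambda2 = low_lambda2,
         high_peak_frac = high_peak_frac,
         high_frac_at_t1 = high_frac_at_t1,
         high_lambda_tail = high_lambda_tail,
         mu_eff_per_cm = mu_eff_per_cm,
         sensitivity_cps_per_mbq = sensitivity_cps_per_mbq,
         pixel_spacing_cm = pixel_spacing_cm, duration_s = duration_s,
         injected_mbq = injected_mbq, poisson_noise = poisson_noise),
    class = "phantom_spec"
  )
}

# true compartment time-activity curves of a phantom/cohort parameter set,
# as fractions of 1 MBq injected
.truth_curves <- function(spec) {
  low <- tac_biexponential(spec$low_f1, spec$low_lambda1,
                           spec$low_f2, spec$low_lambda2)
  peak <- spec$high_peak_frac
  a_t1 <- spec$high_frac_at_t1 * peak
  high <- tac_piecewise(t1 = 2, a_t1 = a_t1, t2 = 24,
                        slope = (peak - a_t1) / 22,
                        tail_value = peak,
                        lambda_tail = spec$high_lambda_tail)
  list(low = low, high = high)
}

# count rate (cps) of a pixel holding activity a (MBq) as a uniform slab of
# thickness t centred in a body of thickness d, seen by either detector
.slab_rate <- function(a, sens, mu, d, t) {
  x <- mu * t / 2
  sinhc <- if (abs(x) < 1e-4) 1 + x^2 / 6 else sinh(x) / x
  sens * a * exp(-mu * d / 2) * sinhc
}

.ellipse_mask <- function(xc, yc, cx, cy, rx, ry) {
  outer(((xc - cx) / rx)^2, ((yc - cy) / ry)^2, `+`) <= 1
}

#' Simulate a planar study of the synthetic phantom
#'
#' Projects the phantom to paired anterior/posterior count images at one
#' time point.  Each compartment's activity at `time_h` is spread uniformly
#' over its projected region and attenuated as a centred slab source, so
#' the conjugate-view formula recovers the true activities exactly in the
#' noiseless case.  The posterior image is stored mirrored left-right, as
#' acquired by a posterior detector.
#'
#' @param spec A [phantom_spec()].
#' @param time_h Time after injection, hours.
#' @param seed Optional integer seed for the Poisson noise.
#' @return List with `study` (a [planar_study()]) and `truth`: the true
#'   compartment activities `a_high_mbq`, `a_low_mbq`, the projected
#'   `high_area_cm2`, and the generating curves.
#' @export
simulate_phantom_planar <- function(spec, time_h, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  px <- spec$pixel_spacing_cm
  nx <- ceiling(spec$body_width_cm / px) + 8L
  ny <- ceiling(spec$body_length_cm / px) + 8L
  xc <- ((seq_len(nx)) - (nx + 1) / 2) * px   # cm, body-centred
  yc <- ((seq_len(ny)) - (ny + 1) / 2) * px

  body <- .ellipse_mask(xc, yc, 0, 0, spec$body_width_cm / 2,
                        spec$body_length_cm / 2)
  organ_masks <- lapply(seq_len(nrow(spec$organs)), function(i) {
    o <- spec$organs[i, ]
    m <- .ellipse_mask(xc, yc, o$cx_cm, o$cy_cm, o$rx_cm, o$ry_cm)
    if (!all(body[m])) stop("invalid geometry: organ outside body",
                            call. = FALSE)
    m
  })
  overlap <- Reduce(`+`, organ_masks)
  if (any(overlap > 1)) stop("invalid geometry: overlapping organs",
                             call. = FALSE)
  high <- overlap > 0
  low <- body & !high

  curves <- .truth_curves(spec)
  a_high <- spec$injected_mbq * predict(curves$high, time_h)
  a_low <- spec$injected_mbq * predict(curves$low, time_h)

  rate <- matrix(0, nx, ny)
  mu <- spec$mu_eff_per_cm
  d <- spec$abdominal_thickness_cm
  for (i in seq_len(nrow(spec$organs))) {
    m <- organ_masks[[i]]
    a_px <- a_high * spec$organs$share[i] / sum(m)
    rate[m] <- .slab_rate(a_px, spec$sensitivity_cps_per_mbq, mu, d,
                          spec$organ_thickness_cm)
  }
  a_px_low <- if (sum(low) > 0) a_low / sum(low) else 0
  rate[low] <- .slab_rate(a_px_low, spec$sensitivity_cps_per_mbq, mu, d,
                          spec$background_thickness_cm)

  counts <- rate * spec$duration_s
  if (spec$poisson_noise) {
    ant <- matrix(rpois(length(counts), counts), nx, ny)
    post <- matrix(rpois(length(counts), counts), nx, ny)
  } else {
    ant <- counts
    post <- counts
  }
  post <- .mirror_lr(post)  # posterior detector sees the mirror image

  list(
    study = planar_study(ant, post, time_h, pixel_area_cm2 = px^2,
                         duration_s = spec$duration_s),
    truth = list(a_high_mbq = a_high, a_low_mbq = a_low,
                 high_area_cm2 = sum(high) * px^2,
                 low_area_cm2 = sum(low) * px^2,
                 curves = curves)
  )
}

#' Simulate a SPECT volume with spherical vertebral bodies
#'
#' Builds a calibrated activity-concentration volume containing one
#' spherical vertebral body per requested label, stacked along the axial
#' direction over a uniform soft-tissue background, together with the
#' ground-truth vertebra centre table the VOI analysis consumes.
#' Metastatic labels are multiplied by a hot factor and flagged.
#'
#' @param vertebra_concs Named numeric vector of base concentrations in
#'   kBq/mL; names are vertebra labels (subset of T1-T12, L1-L5).
#' @param metastases Character vector of labels to make metastatic.
#' @param background Background concentration, kBq/mL.
#' @param hot_factor Multiplier applied to metastatic vertebrae.
#' @param noise_sd Relative (multiplicative Gaussian) voxel noise; 0
#'   disables.
#' @param seed Optional seed for the noise.
#' @param spacing_mm Isotropic voxel spacing.
#' @param vertebra_radius_mm Radius of the spherical vertebral bodies.
#' @param center_spacing_mm Axial distance between vertebra centres.
#' @return List with `volume` (a [spect_volume()]) and `vertebrae` (data
#'   frame: `label`, `x_mm`, `y_mm`, `z_mm`, `metastasis`, `visible`,
#'   `true_concentration_kbq_ml`).
#' @export
simulate_spect_volume <- function(vertebra_concs, metastases = character(),
                                  background = 5, hot_factor = 3,
                                  noise_sd = 0, seed = NULL,
                                  spacing_mm = 3, vertebra_radius_mm = 12,
                                  center_spacing_mm = 26) {
  labels <- names(vertebra_concs)
  .check_labels(labels)
  if (any(vertebra_concs < 0)) stop("concentrations must be >= 0",
                                    call. = FALSE)
  bad <- setdiff(metastases, labels)
  if (length(bad) > 0L)
    stop("metastatic labels not in vertebra_concs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (center_spacing_mm < 2 * vertebra_radius_mm)
    stop("overlapping vertebra placements", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # order cranial -> caudal along z
  labels <- labels[order(match(labels, .VERTEBRA_LABELS))]
  n <- length(labels)
  margin <- vertebra_radius_mm + 3 * spacing_mm
  extent_z <- 2 * margin + (n - 1) * center_spacing_mm
  nxy <- ceiling((4 * vertebra_radius_mm + 2 * margin) / spacing_mm)
  nz <- ceiling(extent_z / spacing_mm)
  cx <- nxy * spacing_mm / 2
  z0 <- margin

  vol <- array(background, c(nxy, nxy, nz))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    met <- lab %in% metastases
    conc <- vertebra_concs[[lab]] * if (met) hot_factor else 1
    center <- c(cx, cx, z0 + (i - 1) * center_spacing_mm)
    m <- sphere_voi_mask(c(nxy, nxy, nz), spacing_mm, center,
                         volume_cm3 = 4 / 3 * pi * (vertebra_radius_mm / 10)^3)
    vol[m] <- conc
    rows[[i]] <- data.frame(
      label = lab, x_mm = center[1L], y_mm = center[2L], z_mm = center[3L],
      metastasis = met, visible = TRUE,
      true_concentration_kbq_ml = conc, stringsAsFactors = FALSE)
  }
  if (noise_sd > 0)
    vol <- pmax(vol * (1 + rnorm(length(vol), 0, noise_sd)), 0)

  list(volume = spect_volume(vol, spacing_mm),
       vertebrae = do.call(rbind, rows))
}

#' Specification of a synthetic patient cohort
#'
#' Distributional parameters of the cohort generator, defaulting to the
#' study conditions of the clinical cohort the package models: 46 patients,
#' 52% male, 52% skeletal-metastasis prevalence, administered activity
#' uniform on 6.8-8.0 GBq per fraction (mean 7.5), two fractions, baseline
#' platelets lognormal around 241e9/L, and a vertebral axial concentration
#' profile following [vertebral_reference_profile()] (peak between T10 and
#' L1) with per-patient lognormal scatter, per-label visibility
#' probabilities from the reference cohort's field-of-view counts, and an
#' L1-L4 male/female concentration ratio of 1.13.
#'
#' The marrow dose that drives platelet toxicity is the generator's own
#' ground truth (computed from the generating kinetic parameters and the
#' patient's median vertebral concentration through the hybrid dose
#' equation); the relative platelet nadir after fraction f is
#' `clamp(1 - toxicity_slope * cumulative_true_dose + N(0, noise), 0.05,
#' 1.2)`.
#'
#' @param n Number of patients (>= 1).
#' @param male_fraction Probability a patient is male.
#' @param metastasis_prevalence Probability of skeletal metastases.
#' @param n_fractions Treatment fractions per patient.
#' @param administered_gbq_range Per-fraction administered activity range
#'   (uniform), GBq.
#' @param weight_mean_g,weight_sd_g Named by sex: mean/sd body weight, g.
#' @param abdominal_thickness_mean_cm,abdominal_thickness_sd_cm Abdominal
#'   thickness distribution, cm.
#' @param high_area_mean_cm2,high_area_sd_cm2 Projected high-compartment
#'   area distribution, cm^2.
#' @param low_f1,low_lambda1,low_f2,low_lambda2,high_peak_frac,high_frac_at_t1,high_lambda_tail
#'   Median kinetic parameters, as in [phantom_spec()].
#' @param kinetic_cv Lognormal coefficient of variation applied to each
#'   kinetic parameter per patient.
#' @param vertebral_profile Named vector of base vertebral concentrations
#'   (kBq/mL at 7.5 GBq administered).
#' @param vertebral_cv Lognormal patient-effect CV on the vertebral profile.
#' @param visibility_prob Named per-label probability that a vertebra is in
#'   the SPECT field of view.
#' @param male_l1l4_ratio Multiplier on L1-L4 concentrations in men.
#' @param metastasis_elevation Multiplier on all vertebral concentrations
#'   in patients with skeletal metastases (diffuse involvement).
#' @param hot_factor Extra multiplier on individually metastatic vertebrae.
#' @param max_hot_vertebrae Maximum number of flagged hot vertebrae per
#'   metastatic patient.
#' @param toxicity_slope Platelet-ratio decrease per Gy of true cumulative
#'   marrow dose.
#' @param toxicity_noise_sd SD of the Gaussian noise on the platelet ratio.
#' @param baseline_platelets_meanlog,baseline_platelets_sdlog Lognormal
#'   baseline platelet distribution (1e9/L).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 46L,
                        male_fraction = 24 / 46,
                        metastasis_prevalence = 24 / 46,
                        n_fractions = 2L,
                        administered_gbq_range = c(6.8, 8.0),
                        weight_mean_g = c(female = 68000, male = 82000),
                        weight_sd_g = c(female = 9000, male = 10000),
                        abdominal_thickness_mean_cm = 22,
                        abdominal_thickness_sd_cm = 2.5,
                        high_area_mean_cm2 = 350, high_area_sd_cm2 = 50,
                        low_f1 = 0.62, low_lambda1 = 0.20,
                        low_f2 = 0.11, low_lambda2 = 0.020,
                        high_peak_frac = 0.20, high_frac_at_t1 = 0.85,
                        high_lambda_tail = 0.012,
                        kinetic_cv = 0.15,
                        vertebral_profile = NULL,
                        vertebral_cv = 0.25,
                        visibility_prob = NULL,
                        male_l1l4_ratio = 1.13,
                        metastasis_elevation = 1.3,
                        hot_factor = 2.5,
                        max_hot_vertebrae = 3L,
                        toxicity_slope = 0.7,
                        toxicity_noise_sd = 0.12,
                        baseline_platelets_meanlog = log(241),
                        baseline_platelets_sdlog = 0.25) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  probs <- c(male_fraction, metastasis_prevalence)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  ref <- vertebral_reference_profile()
  if (is.null(vertebral_profile))
    vertebral_profile <- setNames(ref$concentration_kbq_ml, ref$label)
  if (is.null(visibility_prob))
    visibility_prob <- setNames(ref$n_patients / 22, ref$label)
  .check_labels(names(vertebral_profile))
  structure(
    list(n = as.integer(n), male_fraction = male_fraction,
         metastasis_prevalence = metastasis_prevalence,
         n_fractions = as.integer(n_fractions),
         administered_gbq_range = administered_gbq_range,
         weight_mean_g = weight_mean_g, weight_sd_g = weight_sd_g,
         abdominal_thickness_mean_cm = abdominal_thickness_mean_cm,
         abdominal_thickness_sd_cm = abdominal_thickness_sd_cm,
         high_area_mean_cm2 = high_area_mean_cm2,
         high_area_sd_cm2 = high_area_sd_cm2,
         low_f1 = low_f1, low_lambda1 = low_lambda1,
         low_f2 = low_f2, low_lambda2 = low_lambda2,
         high_peak_frac = high_peak_frac,
         high_frac_at_t1 = high_frac_at_t1,
         high_lambda_tail = high_lambda_tail,
         kinetic_cv = kinetic_cv,
         vertebral_profile = vertebral_profile,
         vertebral_cv = vertebral_cv,
         visibility_prob = visibility_prob,
         male_l1l4_ratio = male_l1l4_ratio,
         metastasis_elevation = metastasis_elevation,
         hot_factor = hot_factor,
         max_hot_vertebrae = as.integer(max_hot_vertebrae),
         toxicity_slope = toxicity_slope,
         toxicity_noise_sd = toxicity_noise_sd,
         baseline_platelets_meanlog = baseline_platelets_meanlog,
         baseline_platelets_sdlog = baseline_platelets_sdlog),
    class = "cohort_spec"
  )
}

# mean-1 lognormal jitter
.jitter_ln <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  rlnorm(n, meanlog = -log(1 + cv^2) / 2, sdlog = sqrt(log(1 + cv^2)))
}

#' Simulate a patient cohort with known ground-truth doses
#'
#' Draws per-patient anatomy, kinetics and vertebral concentration
#' profiles from a [cohort_spec()], computes per-fraction bone-marrow doses
#' for the planar method and all four hybrid methods through the package's
#' own dose equations, generates platelet nadirs from the ground-truth
#' cumulative dose, and returns the tables the cohort statistics consume.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return List of class `synthetic_cohort` with data frames `records`
#'   (per patient-fraction clinical rows), `doses` (per
#'   patient-fraction-method dose rows), `truth` (per patient-fraction
#'   ground-truth dose and scale factor) and `vertebrae` (per
#'   patient-vertebra concentrations at 7.5-GBq scale).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  s_by_sex <- list(female = default_s_factors("female"),
                   male = default_s_factors("male"))
  labels <- names(spec$vertebral_profile)
  lumbar14 <- intersect(labels, paste0("L", 1:4))

  records <- list(); doses <- list(); truth <- list(); verts <- list()
  for (p in seq_len(spec$n)) {
    pid <- sprintf("P%03d", p)
    sex <- if (runif(1) < spec$male_fraction) "male" else "female"
    weight <- max(rnorm(1, spec$weight_mean_g[[sex]],
                        spec$weight_sd_g[[sex]]), 45000)
    abd <- min(max(rnorm(1, spec$abdominal_thickness_mean_cm,
                         spec$abdominal_thickness_sd_cm), 16), 30)
    mets <- runif(1) < spec$metastasis_prevalence
    high_area <- max(rnorm(1, spec$high_area_mean_cm2,
                           spec$high_area_sd_cm2), 100)
    baseline <- rlnorm(1, spec$baseline_platelets_meanlog,
                       spec$baseline_platelets_sdlog)

    # patient kinetic parameters
    j <- .jitter_ln(7L, spec$kinetic_cv)
    pk <- list(low_f1 = spec$low_f1 * j[1L],
               low_lambda1 = spec$low_lambda1 * j[2L],
               low_f2 = spec$low_f2 * j[3L],
               low_lambda2 = spec$low_lambda2 * j[4L],
               high_peak_frac = spec$high_peak_frac * j[5L],
               high_frac_at_t1 = min(spec$high_frac_at_t1 * j[6L], 0.99),
               high_lambda_tail = spec$high_lambda_tail * j[7L])
    curves <- .truth_curves(pk)

    # vertebral base concentrations (kBq/mL at 7.5 GBq administered)
    conc <- spec$vertebral_profile * .jitter_ln(1L, spec$vertebral_cv)
    if (sex == "male")
      conc[lumbar14] <- conc[lumbar14] * spec$male_l1l4_ratio
    if (mets) conc <- conc * spec$metastasis_elevation
    visible <- runif(length(labels)) < spec$visibility_prob[labels]
    met_flags <- setNames(rep(FALSE, length(labels)), labels)
    if (mets && spec$max_hot_vertebrae > 0L) {
      n_hot <- sample.int(spec$max_hot_vertebrae, 1L)
      hot <- sample(labels, n_hot)
      conc[hot] <- conc[hot] * spec$hot_factor
      met_flags[hot] <- TRUE
    }
    verts[[p]] <- data.frame(
      patient_id = pid, label = labels,
      concentration_kbq_ml = unname(conc),
      metastasis = unname(met_flags), visible = visible,
      stringsAsFactors = FALSE)

    masses <- compartment_masses(weight, high_area, abd)
    s <- s_by_sex[[sex]]
    cum_by_method <- setNames(numeric(length(.METHODS)), .METHODS)
    cum_true <- 0

    for (f in seq_len(spec$n_fractions)) {
      a0_gbq <- runif(1, spec$administered_gbq_range[1L],
                      spec$administered_gbq_range[2L])
      a0_mbq <- a0_gbq * 1000
      a_tilde_low <- a0_mbq * integrate_curve(curves$low)
      a_tilde_high <- a0_mbq * integrate_curve(curves$high)
      c_tilde_low <- a_tilde_low / masses$m_low
      # low-compartment concentration at 24 h, kBq/mL
      c_low24 <- a0_mbq * predict(curves$low, 24) / masses$m_low * 1000

      inp <- dose_inputs(c_tilde_low, a_tilde_low, a_tilde_high, s,
                         administered_gbq = a0_gbq)
      scale_f <- a0_mbq / 7500  # vertebral conc scales with administered
      meas <- data.frame(label = labels,
                         concentration_kbq_ml = unname(conc) * scale_f,
                         metastasis = unname(met_flags),
                         visible = visible, stringsAsFactors = FALSE)

      for (m in .METHODS) {
        dr <- if (m == "planar") {
          bone_marrow_dose_planar(inp, fraction = f)
        } else {
          ref_c <- try(select_reference_concentration(meas, m),
                       silent = TRUE)
          if (inherits(ref_c, "try-error")) next
          k <- ref_c / c_low24
          bone_marrow_dose_hybrid(inp, k, method = m, fraction = f)
        }
        cum_by_method[m] <- cum_by_method[m] + dr$dose_gy
        doses[[length(doses) + 1L]] <- data.frame(
          patient_id = pid, fraction = f, method = m,
          dose_gy = dr$dose_gy,
          dose_gy_per_7p4gbq = dr$dose_gy_per_7p4gbq,
          cumulative_gy = cum_by_method[m], stringsAsFactors = FALSE)
      }

      # ground truth: marrow concentration from the patient's full true
      # vertebral profile (median over all vertebrae, visible or not)
      k_true <- median(unname(conc) * scale_f) / c_low24
      true_dose <- bone_marrow_dose_hybrid(inp, k_true, "V_SPECT",
                                           fraction = f)$dose_gy
      cum_true <- cum_true + true_dose
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, fraction = f, true_dose_gy = true_dose,
        cumulative_true_gy = cum_true, k_true = k_true,
        stringsAsFactors = FALSE)

      ratio <- 1 - spec$toxicity_slope * cum_true +
        rnorm(1, 0, spec$toxicity_noise_sd)
      ratio <- min(max(ratio, 0.05), 1.2)
      records[[length(records) + 1L]] <- data.frame(
        patient_id = pid, fraction = f, sex = sex, weight_g = weight,
        abdominal_thickness_cm = abd, skeletal_metastases = mets,
        administered_gbq = a0_gbq, baseline_platelets = baseline,
        nadir_platelets = baseline * ratio,
        l1_l4_mean_concentration =
          if (length(lumbar14) > 0L) mean(conc[lumbar14]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(records = do.call(rbind, records),
         doses = do.call(rbind, doses),
         truth = do.call(rbind, truth),
         vertebrae = do.call(rbind, verts),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(unique(x$records$patient_id))
  cat(sprintf(
    "Synthetic cohort: %d patients, %d fractions, %d dose rows\n",
    n, max(x$records$fraction), nrow(x$doses)))
  cat(sprintf("  skeletal metastases: %d/%d patients\n",
              sum(x$records$skeletal_metastases[x$records$fraction == 1L]),
              n))
  invisible(x)
}
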