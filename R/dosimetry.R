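#' Cross-dose S-factor set for bone marrow
#'
#' Holds the two cross-dose S factors used by the marrow dose equations:
#' dose to bone marrow per unit time-integrated activity in the low- and
#' high-uptake compartments, in Gy/(MBq*h), for one sex.
#'
#' @param s_bm_from_low,s_bm_from_high Non-negative S factors in
#'   Gy/(MBq*h).
#' @param sex `"female"` or `"male"`.
#' @param provenance Free-text description of where the values come from.
#' @return Object of class `s_factor_set`.
#' @export
s_factor_set <- function(s_bm_from_low, s_bm_from_high,
                         sex = c("female", "male"),
                         provenance = "user supplied") {
  sex <- match.arg(sex)
  if (s_bm_from_low < 0 || s_bm_from_high < 0)
    stop("S factors must be >= 0", call. = FALSE)
  structure(
    list(s_bm_from_low = s_bm_from_low, s_bm_from_high = s_bm_from_high,
         sex = sex, provenance = provenance),
    class = "s_factor_set"
  )
}

#' @export
print.s_factor_set <- function(x, ...) {
  cat(sprintf("Bone marrow cross-dose S factors (%s):\n", x$sex))
  cat(sprintf("  S(BM <- low)  = %.4g Gy/(MBq*h)\n", x$s_bm_from_low))
  cat(sprintf("  S(BM <- high) = %.4g Gy/(MBq*h)\n", x$s_bm_from_high))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Mass-weighted compartment S factor
#'
#' Combines per-organ marrow S factors into one compartment-level value by
#' organ-mass weighting: `sum(m_o * S_o) / sum(m_o)`.  Per-organ values are
#' computed offline from specific absorbed fractions over the 177Lu photon
#' spectrum and shipped as a sex-specific table (see [default_s_factors()]);
#' this function performs only the weighting.
#'
#' @param per_organ_s Data frame with columns `organ`, `mass_g` (> 0) and
#'   `s_bm_gy_per_mbq_h` (>= 0).
#' @return Weighted S factor in Gy/(MBq*h).
#' @examples
#' weighted_s_factor(data.frame(
#'   organ = c("a", "b"), mass_g = c(1000, 3000),
#'   s_bm_gy_per_mbq_h = c(1.153e-8, 2.307e-8)
#' ))  # 2.019e-8
#' @export
weighted_s_factor <- function(per_organ_s) {
  need <- c("organ", "mass_g", "s_bm_gy_per_mbq_h")
  if (!is.data.frame(per_organ_s) || !all(need %in% names(per_organ_s)) ||
      nrow(per_organ_s) == 0L)
    stop("need a non-empty data frame with organ, mass_g, s_bm_gy_per_mbq_h",
         call. = FALSE)
  m <- per_organ_s$mass_g
  s <- per_organ_s$s_bm_gy_per_mbq_h
  if (any(!is.finite(m)) || any(m <= 0))
    stop("organ masses must be positive", call. = FALSE)
  if (any(s < 0)) stop("S factors must be >= 0", call. = FALSE)
  sum(m * s) / sum(m)
}

#' Default bone-marrow S factors by sex
#'
#' Loads the package's shipped per-organ table
#' (`inst/extdata/s_factors_synthetic.csv`) and mass-weights it into an
#' [s_factor_set()] for the requested sex.  The table is a synthetic
#' approximation: organ masses are standard adult reference values and the
#' per-organ photon S factors are order-of-magnitude estimates built from
#' the 177Lu photon yield (about 33 keV emitted photon energy per decay)
#' and body-scale specific absorbed fractions, not a published SAF
#' compilation.  Replace it with a site-validated table for clinical use.
#'
#' @param sex `"female"` or `"male"`.
#' @param path Optional path to an alternative CSV with the same columns
#'   (`sex`, `compartment`, `organ`, `mass_g`, `s_bm_gy_per_mbq_h`).
#' @return An [s_factor_set()].
#' @export
default_s_factors <- function(sex = c("female", "male"), path = NULL) {
  sex <- match.arg(sex)
  if (is.null(path))
    path <- system.file("extdata", "s_factors_synthetic.csv",
                        package = "marrowdose", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, , drop = FALSE]
  s_factor_set(
    s_bm_from_low = weighted_s_factor(tab[tab$compartment == "low", ]),
    s_bm_from_high = weighted_s_factor(tab[tab$compartment == "high", ]),
    sex = sex,
    provenance = paste0("synthetic approximation, organ-mass weighted (",
                        basename(path), ")")
  )
}

#' Inputs for the bone-marrow dose equations
#'
#' Collects the quantities entering the planar and hybrid marrow dose
#' equations: the time-integrated activity concentration of the low-uptake
#' compartment (the marrow surrogate), the time-integrated activities of
#' both compartments, the cross-dose S factors, and the physical constants
#' of the self-dose term.
#'
#' @param c_tilde_low Time-integrated low-compartment concentration in
#'   MBq*h/g.
#' @param a_tilde_low,a_tilde_high Time-integrated activities in MBq*h.
#' @param s An [s_factor_set()].
#' @param ratio_bm_low Fixed marrow-to-low-compartment activity
#'   concentration ratio used by the planar method; default 1.8.
#' @param delta_kev Mean locally absorbed (electron) energy per decay of
#'   177Lu in keV; default 147.
#' @param phi_self Absorbed fraction for marrow self-irradiation, in
#'   (0, 1]; default 1.
#' @param administered_gbq Administered activity of the fraction in GBq,
#'   used for the per-7.4-GBq normalisation.
#' @return Object of class `dose_inputs`.
#' @export
dose_inputs <- function(c_tilde_low, a_tilde_low, a_tilde_high, s,
                        ratio_bm_low = 1.8, delta_kev = 147, phi_self = 1,
                        administered_gbq = 7.4) {
  stopifnot(inherits(s, "s_factor_set"))
  vals <- c(c_tilde_low = c_tilde_low, a_tilde_low = a_tilde_low,
            a_tilde_high = a_tilde_high)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("time-integrated quantities must be finite and >= 0", call. = FALSE)
  if (!(ratio_bm_low > 0)) stop("ratio_bm_low must be > 0", call. = FALSE)
  if (!(delta_kev > 0)) stop("delta_kev must be > 0", call. = FALSE)
  if (!(phi_self > 0 && phi_self <= 1))
    stop("phi_self must be in (0, 1]", call. = FALSE)
  if (!(administered_gbq > 0))
    stop("administered_gbq must be > 0", call. = FALSE)
  structure(
    list(c_tilde_low = c_tilde_low, a_tilde_low = a_tilde_low,
         a_tilde_high = a_tilde_high, s = s, ratio_bm_low = ratio_bm_low,
         delta_kev = delta_kev, phi_self = phi_self,
         administered_gbq = administered_gbq),
    class = "dose_inputs"
  )
}

#' Self-dose coefficient of the marrow dose equations
#'
#' Absorbed dose in Gy delivered per unit time-integrated activity
#' concentration (1 MBq*h/g) when the locally absorbed energy per decay is
#' `delta_kev`:
#' `3.6e9 decays/(MBq*h) * delta_kev * 1.602177e-16 J/keV * 1000 g/kg`.
#' For 177Lu (147 keV) this is 0.08478 Gy per MBq*h/g.
#'
#' @param delta_kev Locally absorbed energy per decay in keV.
#' @return Gy per (MBq*h/g).
#' @export
self_dose_coefficient <- function(delta_kev = 147) {
  if (!(delta_kev > 0)) stop("delta_kev must be > 0", call. = FALSE)
  delta_kev * .GY_PER_MBQ_H_PER_G_PER_KEV
}

# shared core of the planar and hybrid dose equations: marrow concentration
# scale factor k is the fixed 1.8 ratio (planar) or the SPECT-derived
# patient-specific factor (hybrid)
.marrow_dose <- function(inputs, k, method, fraction) {
  if (!is.finite(k) || k < 0) stop("scale factor must be >= 0", call. = FALSE)
  self_term <- inputs$c_tilde_low * k * inputs$phi_self *
    self_dose_coefficient(inputs$delta_kev)
  cross <- inputs$a_tilde_low * inputs$s$s_bm_from_low +
    inputs$a_tilde_high * inputs$s$s_bm_from_high
  dose <- self_term + cross
  structure(
    list(method = method, dose_gy = dose,
         dose_gy_per_7p4gbq = dose * 7.4 / inputs$administered_gbq,
         self_dose_gy = self_term, cross_dose_gy = cross,
         fraction = as.integer(fraction), cumulative_gy = dose,
         administered_gbq = inputs$administered_gbq,
         s_provenance = inputs$s$provenance),
    class = "dose_result"
  )
}

#' Bone-marrow absorbed dose, planar two-compartment method
#'
#' Marrow dose as self-dose plus compartment cross-doses:
#' `D = C_low * 1.8 * phi * Delta + A_low * S(BM<-low) + A_high * S(BM<-high)`
#' where `C_low` is the time-integrated activity concentration of the
#' low-uptake compartment, the fixed factor 1.8 converts it to a marrow
#' concentration, and the unit handling of the self term is described in
#' [self_dose_coefficient()].
#'
#' @param inputs A [dose_inputs()] object.
#' @param fraction Treatment fraction index (>= 1).
#' @return A `dose_result` with `dose_gy`, `dose_gy_per_7p4gbq`, the self
#'   and cross components, and the fraction index.
#' @export
bone_marrow_dose_planar <- function(inputs, fraction = 1L) {
  stopifnot(inherits(inputs, "dose_inputs"))
  .marrow_dose(inputs, inputs$ratio_bm_low, "planar", fraction)
}

#' Hybrid scale factor from a vertebral SPECT measurement
#'
#' Ratio of the reference vertebral activity concentration at 24 h to the
#' fitted low-compartment concentration curve evaluated at 24 h.  This
#' patient-specific factor replaces the planar method's fixed 1.8 in the
#' hybrid dose equation.  With unit density, kBq/g and kBq/mL are
#' interchangeable.
#'
#' @param c_vert_24h_kbq_ml Reference vertebral concentration at 24 h in
#'   kBq/mL (from [select_reference_concentration()]).
#' @param low_conc_curve A `conc_curve` (see [to_concentration()]) for the
#'   low-uptake compartment, in MBq/g.
#' @param t_h Evaluation time, default 24 h.
#' @return Unitless scale factor `k >= 0`.
#' @export
hybrid_scale_factor <- function(c_vert_24h_kbq_ml, low_conc_curve,
                                t_h = 24) {
  stopifnot(inherits(low_conc_curve, "conc_curve"))
  if (c_vert_24h_kbq_ml < 0)
    stop("vertebral concentration must be >= 0", call. = FALSE)
  c_low <- predict(low_conc_curve, t_h) * 1000  # MBq/g -> kBq/g == kBq/mL
  if (!is.finite(c_low) || c_low <= 0)
    stop("low-compartment concentration curve must be positive at ", t_h,
         " h", call. = FALSE)
  c_vert_24h_kbq_ml / c_low
}

#' Bone-marrow absorbed dose, hybrid planar/SPECT methods
#'
#' Identical to [bone_marrow_dose_planar()] except that the fixed
#' marrow-to-low ratio 1.8 is replaced by the patient-specific SPECT-derived
#' scale factor `k` (see [hybrid_scale_factor()]); at `k = 1.8` the two
#' equations coincide exactly.
#'
#' @param inputs A [dose_inputs()] object.
#' @param k Hybrid scale factor (>= 0).
#' @param method Which reference scheme produced `k`: one of
#'   `"L4_SPECT"`, `"V_SPECT"`, `"L_SPECT"`, `"T_SPECT"`.
#' @param fraction Treatment fraction index (>= 1).
#' @return A `dose_result`.
#' @export
bone_marrow_dose_hybrid <- function(inputs, k,
                                    method = c("L4_SPECT", "V_SPECT",
                                               "L_SPECT", "T_SPECT"),
                                    fraction = 1L) {
  stopifnot(inherits(inputs, "dose_inputs"))
  method <- match.arg(method)
  .marrow_dose(inputs, k, method, fraction)
}

#' Accumulate per-fraction doses
#'
#' Sums the absorbed doses of successive treatment fractions estimated with
#' the same method.  The cumulative dose after fraction 2 is what the
#' fraction-2 dose-response analysis uses.
#'
#' @param per_fraction List of `dose_result` objects, same method, distinct
#'   fraction indices.
#' @return A `dose_result` whose `cumulative_gy` is the summed dose and
#'   whose `fraction` is the largest fraction index; `dose_gy` is the last
#'   fraction's own dose.
#' @export
accumulate_doses <- function(per_fraction) {
  if (length(per_fraction) == 0L) stop("empty dose list", call. = FALSE)
  stopifnot(all(vapply(per_fraction, inherits, logical(1L), "dose_result")))
  methods <- vapply(per_fraction, `[[`, character(1L), "method")
  if (length(unique(methods)) != 1L)
    stop("cannot accumulate doses across different methods", call. = FALSE)
  fracs <- vapply(per_fraction, `[[`, integer(1L), "fraction")
  if (anyDuplicated(fracs)) stop("duplicate fraction indices", call. = FALSE)
  ord <- order(fracs)
  last <- per_fraction[[ord[length(ord)]]]
  out <- last
  out$cumulative_gy <- sum(vapply(per_fraction, `[[`, numeric(1L), "dose_gy"))
  out
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("Bone marrow dose (%s), fraction %d:\n", x$method, x$fraction))
  cat(sprintf("  dose: %.4g Gy (self %.4g + cross %.4g)\n",
              x$dose_gy, x$self_dose_gy, x$cross_dose_gy))
  cat(sprintf("  normalised: %.4g Gy/7.4 GBq (administered %.3g GBq)\n",
              x$dose_gy_per_7p4gbq, x$administered_gbq))
  if (x$cumulative_gy != x$dose_gy)
    cat(sprintf("  cumulative: %.4g Gy\n", x$cumulative_gy))
  invisible(x)
}
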