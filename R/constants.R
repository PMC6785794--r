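# Physical constants and anatomical reference data used throughout the
# dosimetry chain.  Units are stated next to each value; dose arithmetic is
# done in Gy, activity in MBq, time in hours, mass in grams (density 1
# g/cm^3 is assumed for soft tissue so kBq/g and kBq/mL are interchangeable).

# 1 keV in joule
.KEV_TO_J <- 1.602177e-16

# decays per MBq-hour: 1e6 decays/s/MBq * 3600 s/h
.DECAYS_PER_MBQ_H <- 3.6e9

# Gy per (MBq*h/g) per keV of locally absorbed energy per decay:
# decays/(MBq h) * J/keV * 1000 g/kg
.GY_PER_MBQ_H_PER_G_PER_KEV <- .DECAYS_PER_MBQ_H * .KEV_TO_J * 1000

#' Physical decay constant of 177Lu
#'
#' The physical half-life of 177Lu is 6.647 d (159.53 h), giving a decay
#' constant of 0.004345 per hour.  Whole-body clearance fitted from serial
#' images cannot be slower than physical decay, so fitted slow-phase rate
#' constants below this value are flagged.
#'
#' @format A single numeric value in 1/h.
#' @export
lu177_lambda_phys <- log(2) / 159.53

# Ordered vertebral labels, cranial to caudal, thoracic then lumbar.
.VERTEBRA_LABELS <- c(paste0("T", 1:12), paste0("L", 1:5))

.THORACIC_LABELS <- paste0("T", 1:12)
.LUMBAR_LABELS <- paste0("L", 1:5)

# Fallback order for the single-vertebra (L4-SPECT) reference.
.L4_FALLBACK <- c("L4", "L5", "L3", "L2")

#' Reference vertebral activity concentration profile
#'
#' Median 177Lu-DOTATATE activity concentrations (kBq/mL) measured at 24 h
#' after injection in 0.7 cm^3 vertebral-body sphere VOIs, per vertebra, in
#' a published reference cohort of 22 patients without skeletal metastases,
#' together with the number of patients in whom each vertebra was inside
#' the SPECT field of view.  The axial profile peaks between T10 and L1 and
#' falls off towards T5-T7 and L4-L5.  Used as the default axial gradient
#' of the synthetic cohort generator and as a worked fixture for the
#' reference-vertebra selection schemes.
#'
#' @return A data frame with columns `label`, `concentration_kbq_ml`
#'   (median concentration) and `n_patients` (visibility count out of 22).
#' @examples
#' vertebral_reference_profile()
#' @export
vertebral_reference_profile <- function() {
  data.frame(
    label = c("T5", "T6", "T7", "T8", "T9", "T10", "T11", "T12",
              "L1", "L2", "L3", "L4", "L5"),
    concentration_kbq_ml = c(14.4, 20.2, 21.3, 25.8, 28.1, 37.1, 47.8, 41.0,
                             38.4, 35.6, 28.2, 23.9, 24.2),
    n_patients = c(1L, 3L, 5L, 9L, 15L, 21L, 22L, 22L,
                   22L, 22L, 22L, 22L, 21L),
    stringsAsFactors = FALSE
  )
}

# internal: validate a vertebra label vector
.check_labels <- function(labels) {
  bad <- setdiff(labels, .VERTEBRA_LABELS)
  if (length(bad) > 0L)
    stop("unknown vertebra label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(labels)
}
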