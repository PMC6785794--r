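#' Construct a planar scintigraphy study
#'
#' Pairs an anterior and a posterior whole-body count image acquired at one
#' time point after injection.  Both images must share the same pixel grid;
#' the posterior image is stored as acquired (it is mirrored left-right only
#' when combined with the anterior view, since the two detectors face in
#' opposite directions).
#'
#' @param anterior,posterior Numeric matrices of counts per pixel
#'   (non-negative, same dimensions).
#' @param time_h Time after injection in hours (the protocol images at
#'   roughly 2, 24, 48 and 168 h).
#' @param pixel_area_cm2 Pixel area in cm^2.
#' @param duration_s Effective acquisition duration per pixel in seconds
#'   (from the scan speed), used to convert counts to count rates.
#' @param camera_id Camera identifier linking the study to its calibration.
#' @return An object of class `planar_study`.
#' @export
planar_study <- function(anterior, posterior, time_h, pixel_area_cm2,
                         duration_s, camera_id = "camera") {
  if (!is.matrix(anterior) || !is.matrix(posterior))
    stop("anterior and posterior must be matrices", call. = FALSE)
  if (!identical(dim(anterior), dim(posterior)))
    stop("anterior and posterior images must have identical shape",
         call. = FALSE)
  if (any(anterior < 0) || any(posterior < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (!is.finite(time_h) || time_h < 0) stop("time_h must be >= 0", call. = FALSE)
  if (!is.finite(pixel_area_cm2) || pixel_area_cm2 <= 0)
    stop("pixel_area_cm2 must be positive", call. = FALSE)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  structure(
    list(anterior = anterior, posterior = posterior, time_h = time_h,
         pixel_area_cm2 = pixel_area_cm2, duration_s = duration_s,
         camera_id = camera_id),
    class = "planar_study"
  )
}

#' @export
print.planar_study <- function(x, ...) {
  cat(sprintf(
    "Planar study at %g h: %d x %d px (%.3g cm^2/px), %g s/px, camera %s\n",
    x$time_h, nrow(x$anterior), ncol(x$anterior), x$pixel_area_cm2,
    x$duration_s, x$camera_id))
  cat(sprintf("  total counts: anterior %.4g, posterior %.4g\n",
              sum(x$anterior), sum(x$posterior)))
  invisible(x)
}

# mirror an image about the vertical axis (left-right flip). Rows index the
# patient's left-right direction in this package's convention.
.mirror_lr <- function(img) img[rev(seq_len(nrow(img))), , drop = FALSE]

#' Geometric mean of the conjugate planar views
#'
#' Mirrors the posterior image left-right into the anterior frame (the two
#' detectors face each other) and returns the pixelwise geometric mean
#' `sqrt(anterior * posterior_mirrored)`.  Pixels where either view is zero
#' are zero.
#'
#' @param study A [planar_study()].
#' @return A numeric matrix, same shape as the input images.
#' @export
geometric_mean_image <- function(study) {
  stopifnot(inherits(study, "planar_study"))
  sqrt(study$anterior * .mirror_lr(study$posterior))
}

#' Segment a geometric-mean image into high- and low-uptake compartments
#'
#' Threshold-based two-compartment segmentation of a whole-body geometric
#' mean image.  The whole-body outline is found on a Gaussian-smoothed copy
#' (pixels at or above `wb_threshold_frac` of the smoothed maximum, largest
#' connected component, morphologically closed and hole-filled).  The
#' high/low split is then applied to the *unfiltered* image inside that
#' outline: pixels at or above `split_threshold_frac` of the within-body
#' maximum form the high-uptake compartment (liver, spleen, kidneys,
#' tumours); the remainder of the body is the low-uptake compartment.  The
#' two compartments exactly partition the whole-body mask.
#'
#' @param gm Numeric matrix, a geometric-mean count image.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels for the
#'   whole-body outline (0 disables smoothing).
#' @param wb_threshold_frac Whole-body threshold as a fraction of the
#'   smoothed maximum, in (0, `split_threshold_frac`).
#' @param split_threshold_frac High-uptake threshold as a fraction of the
#'   within-body maximum of the unsmoothed image, in
#'   (`wb_threshold_frac`, 1]. The default 0.35 is a configurable placeholder
#'   tuned on synthetic phantoms; the optimal clinical value depends on the
#'   camera and should be set per site.
#' @return A list of class `compartment_masks` with logical matrices
#'   `whole_body`, `high` and `low`.
#' @export
segment_two_compartments <- function(gm, smoothing_sigma = 2,
                                     wb_threshold_frac = 0.02,
                                     split_threshold_frac = 0.35) {
  if (!is.matrix(gm)) stop("gm must be a matrix", call. = FALSE)
  if (all(gm == 0)) stop("empty image", call. = FALSE)
  if (!(wb_threshold_frac > 0 && wb_threshold_frac < split_threshold_frac &&
        split_threshold_frac <= 1))
    stop("need 0 < wb_threshold_frac < split_threshold_frac <= 1",
         call. = FALSE)

  sm <- if (smoothing_sigma > 0) EBImage::gblur(gm, sigma = smoothing_sigma) else gm
  wb <- sm >= wb_threshold_frac * max(sm)

  # largest connected component
  lab <- EBImage::bwlabel(wb)
  if (max(lab) < 1) stop("empty image", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  wb <- lab == which.max(sizes)

  # close small gaps and fill interior holes
  wb <- EBImage::closing(wb, EBImage::makeBrush(3, shape = "box")) > 0
  wb <- EBImage::fillHull(wb) > 0

  inside <- gm[wb]
  high <- wb & (gm >= split_threshold_frac * max(inside))
  low <- wb & !high

  structure(list(whole_body = wb, high = high, low = low),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf(
    "Compartment masks: whole body %d px, high %d px, low %d px\n",
    sum(x$whole_body), sum(x$high), sum(x$low)))
  invisible(x)
}

# source self-attenuation factor f = x / sinh(x) with x = mu*t/2, series
# expansion near 0 (f -> 1 as mu -> 0)
.self_attenuation_factor <- function(mu_eff, source_thickness) {
  x <- mu_eff * source_thickness / 2
  if (abs(x) < 1e-4) 1 - x^2 / 6 else x / sinh(x)
}

#' Quantify activity from conjugate planar views
#'
#' Conjugate-view formula for the activity of a source region seen in paired
#' anterior/posterior images:
#' `A = sqrt(R_ant * R_post) / sensitivity * exp(mu_eff * d / 2) * f`,
#' where `R` are count rates (counts/duration), `d` is the patient body
#' thickness over the abdomen, and `f = (mu*t/2)/sinh(mu*t/2)` corrects for
#' self-attenuation of a source of thickness `t` (a general organ thickness
#' of 8 cm is the clinical default).  The formula is exact for a uniform
#' source slab of thickness `t` centred in a uniform attenuator of
#' thickness `d`.
#'
#' @param ant_counts,post_counts Total counts of the region in the anterior
#'   and (mirrored) posterior view.
#' @param duration_s Acquisition duration in seconds common to both views.
#' @param calib A [camera_calibration][fit_attenuation_sensitivity] object.
#' @param body_thickness_cm Patient body thickness over the abdomen in cm.
#' @param source_thickness_cm Source (organ) thickness in cm; default 8.
#' @return Activity in MBq.
#' @examples
#' cal <- fit_attenuation_sensitivity(c(0, 10), c(1000, 1000 * exp(-1.2)), 100)
#' conjugate_view_activity(1000 * 60, 800 * 60, 60, cal,
#'                         body_thickness_cm = 20)
#' @export
conjugate_view_activity <- function(ant_counts, post_counts, duration_s,
                                    calib, body_thickness_cm,
                                    source_thickness_cm = 8) {
  stopifnot(inherits(calib, "camera_calibration"))
  if (calib$sensitivity <= 0) stop("sensitivity must be positive", call. = FALSE)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  if (ant_counts < 0 || post_counts < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (!(body_thickness_cm >= source_thickness_cm && source_thickness_cm > 0))
    stop("need body_thickness_cm >= source_thickness_cm > 0", call. = FALSE)

  r_ant <- ant_counts / duration_s
  r_post <- post_counts / duration_s
  gm_rate <- sqrt(r_ant * r_post)
  f <- .self_attenuation_factor(calib$mu_eff, source_thickness_cm)
  gm_rate / calib$sensitivity * exp(calib$mu_eff * body_thickness_cm / 2) * f
}

#' Masses of the two planar compartments
#'
#' The high-uptake compartment mass is its projected area times the
#' abdominal thickness at unit density; the low-uptake compartment is the
#' rest of the body.
#'
#' @param body_weight_g Patient weight in grams.
#' @param high_area_cm2 Projected area of the high-uptake compartment in
#'   cm^2.
#' @param abdominal_thickness_cm Body thickness over the abdomen in cm.
#' @return Named list with `m_high` and `m_low` in grams.
#' @examples
#' compartment_masses(70000, 300, 20)  # m_high 6000 g, m_low 64000 g
#' @export
compartment_masses <- function(body_weight_g, high_area_cm2,
                               abdominal_thickness_cm) {
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be positive", call. = FALSE)
  if (high_area_cm2 < 0) stop("high_area_cm2 must be >= 0", call. = FALSE)
  if (!is.finite(abdominal_thickness_cm) || abdominal_thickness_cm <= 0)
    stop("abdominal_thickness_cm must be positive", call. = FALSE)
  m_high <- high_area_cm2 * abdominal_thickness_cm  # density 1 g/cm^3
  if (m_high >= body_weight_g)
    stop("high compartment exceeds body mass", call. = FALSE)
  list(m_high = m_high, m_low = body_weight_g - m_high)
}

#' Quantify both compartment activities of one planar study
#'
#' Convenience wrapper: computes the geometric-mean image, sums anterior and
#' mirrored-posterior counts over each compartment mask, and applies the
#' conjugate-view formula to each compartment.
#'
#' @param study A [planar_study()].
#' @param masks A `compartment_masks` object from
#'   [segment_two_compartments()].
#' @param calib A camera calibration.
#' @param body_thickness_cm Abdominal body thickness in cm.
#' @param source_thickness_cm Organ thickness for self-attenuation; default
#'   8 cm for both compartments.
#' @return Data frame with one row per compartment (`high`, `low`):
#'   `time_h`, `compartment`, `activity_mbq`, `area_cm2`.
#' @export
compartment_activities <- function(study, masks, calib, body_thickness_cm,
                                   source_thickness_cm = 8) {
  stopifnot(inherits(study, "planar_study"),
            inherits(masks, "compartment_masks"))
  post_m <- .mirror_lr(study$posterior)
  quant <- function(mask) {
    conjugate_view_activity(sum(study$anterior[mask]), sum(post_m[mask]),
                            study$duration_s, calib, body_thickness_cm,
                            source_thickness_cm)
  }
  data.frame(
    time_h = study$time_h,
    compartment = c("high", "low"),
    activity_mbq = c(quant(masks$high), quant(masks$low)),
    area_cm2 = c(sum(masks$high), sum(masks$low)) * study$pixel_area_cm2,
    stringsAsFactors = FALSE
  )
}
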