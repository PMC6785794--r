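#' Construct a calibrated SPECT (or CT) volume
#'
#' A 3-D numeric array with isotropic or anisotropic voxel spacing in mm.
#' Voxel `(i, j, k)` is centred at physical coordinate
#' `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)` mm, with the origin at
#' the corner of the grid.  SPECT volumes are assumed already reconstructed
#' and calibrated to kBq/mL and resampled to the CT grid by the provider;
#' this package performs no registration.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm Numeric length-3 voxel spacing in mm.
#' @return Object of class `spect_volume` (a list with `data`, `spacing_mm`).
#' @export
spect_volume <- function(data, spacing_mm) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values", call. = FALSE)
  structure(list(data = data, spacing_mm = spacing_mm),
            class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "SPECT volume %d x %d x %d voxels, spacing %g x %g x %g mm\n",
    d[1L], d[2L], d[3L], x$spacing_mm[1L], x$spacing_mm[2L], x$spacing_mm[3L]))
  cat(sprintf("  value range: %.4g to %.4g\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Spherical volume-of-interest mask
#'
#' Builds the logical mask of voxels whose centres lie within a sphere of
#' the requested volume (default 0.7 cm^3, radius about 5.51 mm) centred at
#' a physical coordinate.  Sphere VOIs of this size are placed centrally in
#' vertebral bodies: smaller than the vertebra to limit partial-volume
#' effects and cross-contamination from adjacent high-uptake organs.
#' Membership is by voxel centre, with no partial-volume weighting, so the
#' mask volume converges to the nominal volume as the grid is refined.
#'
#' @param dim_vox Integer length-3 grid dimensions (voxels).
#' @param spacing_mm Voxel spacing in mm (scalar or length 3).
#' @param center_mm Physical sphere centre in mm (length 3).
#' @param volume_cm3 Sphere volume in cm^3 (> 0); default 0.7.
#' @return Logical 3-D array of the grid dimensions.
#' @examples
#' m <- sphere_voi_mask(c(20, 20, 20), 1, c(10, 10, 10))
#' sum(m)  # about 700 voxels at 1 mm resolution
#' @export
sphere_voi_mask <- function(dim_vox, spacing_mm, center_mm,
                            volume_cm3 = 0.7) {
  if (!is.finite(volume_cm3) || volume_cm3 <= 0)
    stop("volume_cm3 must be positive", call. = FALSE)
  dim_vox <- as.integer(dim_vox)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(dim_vox) == 3L, length(spacing_mm) == 3L,
            length(center_mm) == 3L)

  r_mm <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)  # cm^3 -> mm^3
  extent <- dim_vox * spacing_mm
  if (any(center_mm - r_mm < 0) || any(center_mm + r_mm > extent))
    stop("VOI out of bounds", call. = FALSE)

  cx <- (seq_len(dim_vox[1L]) - 0.5) * spacing_mm[1L]
  cy <- (seq_len(dim_vox[2L]) - 0.5) * spacing_mm[2L]
  cz <- (seq_len(dim_vox[3L]) - 0.5) * spacing_mm[3L]
  dx2 <- (cx - center_mm[1L])^2
  dy2 <- (cy - center_mm[2L])^2
  dz2 <- (cz - center_mm[3L])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= r_mm^2
}

#' Mean activity concentration within a VOI
#'
#' @param spect A [spect_volume()] calibrated in kBq/mL.
#' @param mask Logical array of the same dimensions (from
#'   [sphere_voi_mask()]).
#' @return Mean voxel value within the mask, kBq/mL.
#' @export
voi_concentration <- function(spect, mask) {
  stopifnot(inherits(spect, "spect_volume"))
  if (!identical(dim(spect$data), dim(mask)))
    stop("mask and volume dimensions differ", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("empty mask", call. = FALSE)
  mean(spect$data[mask])
}

#' Extract vertebral-body concentrations from a SPECT volume
#'
#' Places one sphere VOI per vertebra listed in the table and returns the
#' per-vertebra mean concentrations.
#'
#' @param spect A [spect_volume()] in kBq/mL.
#' @param vertebra_table Data frame with columns `label`, `x_mm`, `y_mm`,
#'   `z_mm`, `metastasis` (logical) and optionally `visible` (logical,
#'   default TRUE).
#' @param volume_cm3 Sphere volume, default 0.7 cm^3.
#' @return The input table with a `concentration_kbq_ml` column added.
#' @export
measure_vertebrae <- function(spect, vertebra_table, volume_cm3 = 0.7) {
  stopifnot(inherits(spect, "spect_volume"))
  need <- c("label", "x_mm", "y_mm", "z_mm", "metastasis")
  if (!all(need %in% names(vertebra_table)))
    stop("vertebra_table needs columns label, x_mm, y_mm, z_mm, metastasis",
         call. = FALSE)
  .check_labels(vertebra_table$label)
  if (anyDuplicated(vertebra_table$label))
    stop("duplicate vertebra labels", call. = FALSE)
  if (is.null(vertebra_table$visible)) vertebra_table$visible <- TRUE
  conc <- vapply(seq_len(nrow(vertebra_table)), function(i) {
    m <- sphere_voi_mask(dim(spect$data), spect$spacing_mm,
                         c(vertebra_table$x_mm[i], vertebra_table$y_mm[i],
                           vertebra_table$z_mm[i]), volume_cm3)
    voi_concentration(spect, m)
  }, numeric(1L))
  vertebra_table$concentration_kbq_ml <- conc
  vertebra_table
}

# median with even-count semantics = mean of the central pair (stats::median
# already does this for numeric input; kept explicit for clarity)
.mid_median <- function(x) median(x)

#' Select the reference vertebral concentration for a hybrid method
#'
#' Four reference schemes are supported.  `L4_SPECT` uses a single
#' vertebra: L4, falling back to L5, then L3, then L2 when the preferred
#' vertebra is metastatic or outside the field of view.  `V_SPECT`,
#' `L_SPECT` and `T_SPECT` use the median concentration over all visible
#' vertebrae, the visible lumbar vertebrae (L1-L5) and the visible thoracic
#' vertebrae (T1-T12), respectively.  Metastatic vertebrae are *included*
#' in the medians — the median itself damps their influence — and excluded
#' only from the single-vertebra fallback chain.
#'
#' @param measurements Data frame with columns `label`,
#'   `concentration_kbq_ml`, `metastasis` and optionally `visible`
#'   (default TRUE).
#' @param method One of `"L4_SPECT"`, `"V_SPECT"`, `"L_SPECT"`,
#'   `"T_SPECT"`.
#' @return Reference concentration in kBq/mL.
#' @examples
#' tab <- data.frame(
#'   label = paste0("L", 1:5),
#'   concentration_kbq_ml = c(38.4, 35.6, 28.2, 23.9, 24.2),
#'   metastasis = FALSE
#' )
#' select_reference_concentration(tab, "L_SPECT")  # 28.2
#' @export
select_reference_concentration <- function(measurements,
                                           method = c("L4_SPECT", "V_SPECT",
                                                      "L_SPECT", "T_SPECT")) {
  method <- match.arg(method)
  need <- c("label", "concentration_kbq_ml", "metastasis")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns label, concentration_kbq_ml, metastasis",
         call. = FALSE)
  .check_labels(measurements$label)
  if (anyDuplicated(measurements$label))
    stop("duplicate vertebra labels", call. = FALSE)
  if (is.null(measurements$visible)) measurements$visible <- TRUE
  if (any(measurements$concentration_kbq_ml < 0))
    stop("concentrations must be >= 0", call. = FALSE)

  vis <- measurements[measurements$visible, , drop = FALSE]

  if (method == "L4_SPECT") {
    for (lab in .L4_FALLBACK) {
      row <- vis[vis$label == lab & !vis$metastasis, , drop = FALSE]
      if (nrow(row) == 1L) return(row$concentration_kbq_ml)
    }
    stop("no eligible lumbar vertebra", call. = FALSE)
  }

  subset_labels <- switch(method,
    V_SPECT = .VERTEBRA_LABELS,
    L_SPECT = .LUMBAR_LABELS,
    T_SPECT = .THORACIC_LABELS
  )
  vals <- vis$concentration_kbq_ml[vis$label %in% subset_labels]
  if (length(vals) == 0L)
    stop("no visible vertebrae for method ", method, call. = FALSE)
  .mid_median(vals)
}
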