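#' Absorbed-dose grid
#'
#' A 3D array of absorbed dose in Gy on the same regular-grid contract as
#' [structure_set()] (spacing mm, origin mm, voxel-center convention). Dose
#' and mask grids must be co-registered; no resampling is performed anywhere
#' in the package — a geometry mismatch is an error, never an interpolation.
#'
#' @param array 3D numeric array of dose in Gy, all values >= 0.
#' @param spacing Voxel spacing (mm), length 3, > 0.
#' @param origin Grid origin (mm), length 3.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(array, spacing, origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3L) stop("dose must be a 3D array")
  if (any(array < 0)) stop("dose values must be >= 0 Gy")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(array = array, spacing = spacing, origin = origin),
            class = "dose_grid")
}

check_grid_match <- function(dose, ss) {
  if (!identical(dim(dose$array), grid_dim(ss)) ||
      !isTRUE(all.equal(dose$spacing, ss$spacing)) ||
      !isTRUE(all.equal(dose$origin, ss$origin)))
    stop("dose grid and structure set are not co-registered (shape/spacing/origin mismatch)")
  invisible(TRUE)
}

#' Cumulative dose-volume histogram of an ROI
#'
#' Collects the dose values of all voxels inside the mask; the cumulative DVH
#' at dose `d` is the percentage of ROI volume receiving >= `d` Gy. The curve
#' is monotone non-increasing, 100% at 0 Gy and 0% above the maximum voxel
#' dose.
#'
#' @param dose A [dose_grid()].
#' @param ss A [structure_set()] co-registered with `dose`.
#' @param roi ROI name in `ss` (non-empty mask).
#' @return Object of class `dvh`: sorted voxel doses, ROI volume, voxel count.
#' @export
compute_dvh <- function(dose, ss, roi) {
  check_grid_match(dose, ss)
  if (!roi %in% names(ss$masks)) stop("ROI not in structure set: ", roi)
  mask <- ss$masks[[roi]]
  if (!any(mask)) stop("ROI '", roi, "' is empty; DVH undefined")
  d <- sort(dose$array[mask])
  structure(list(roi = roi, dose_sorted = d, n = length(d),
                 volume_mm3 = length(d) * prod(ss$spacing)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("DVH of '%s': %d voxels, %.2f cm^3, dose %.2f-%.2f Gy (mean %.2f)\n",
              x$roi, x$n, x$volume_mm3 / 1000, min(x$dose_sorted),
              max(x$dose_sorted), mean(x$dose_sorted)))
  invisible(x)
}

#' Volume receiving at least a given dose (Vx)
#'
#' @param dvh A [compute_dvh()] result.
#' @param dose_gy Dose threshold in Gy (>= 0).
#' @return Percentage of ROI volume with voxel dose >= `dose_gy`.
#' @export
volume_at_dose <- function(dvh, dose_gy) {
  stopifnot(inherits(dvh, "dvh"))
  if (any(dose_gy < 0)) stop("dose threshold must be >= 0 Gy")
  vapply(dose_gy, function(x) 100 * sum(dvh$dose_sorted >= x) / dvh$n, numeric(1))
}

#' Dose covering at least a given volume fraction (Dp)
#'
#' `Dp` is the largest dose `d` such that at least `p`% of the ROI volume
#' receives >= `d` Gy. With voxel doses sorted in descending order
#' `s_1 >= ... >= s_n`, the empirical curve passes through the points
#' `(100 k / n, s_k)` and is linearly interpolated between adjacent sorted
#' doses; `p` below `100/n` returns the maximum voxel dose, `p = 100` the
#' minimum. The interpolation is linear in dose, so `Dp` scales exactly with
#' a global dose rescaling (which makes [normalize_to_coverage()] exact).
#'
#' @param dvh A [compute_dvh()] result.
#' @param volume_pct Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_pct) {
  stopifnot(inherits(dvh, "dvh"))
  if (any(volume_pct <= 0 | volume_pct > 100))
    stop("volume percentage must be in (0, 100]")
  s <- rev(dvh$dose_sorted)            # descending
  f <- 100 * seq_len(dvh$n) / dvh$n    # cumulative volume % at s_k
  vapply(volume_pct, function(p) {
    if (p <= f[1]) return(s[1])
    stats::approx(f, s, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' ICRU-83 homogeneity index of a target DVH
#'
#' `HI = (D2% - D98%) / D50%`: the near-maximum minus near-minimum dose,
#' relative to the median dose. 0 for a perfectly uniform dose; invariant
#' under global dose rescaling.
#'
#' @param dvh PTV DVH from [compute_dvh()].
#' @return HI (unitless, >= 0 up to interpolation).
#' @export
homogeneity_index <- function(dvh) {
  d50 <- dose_at_volume(dvh, 50)
  if (d50 <= 0) stop("D50% is zero; homogeneity index undefined")
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / d50
}

#' Paddick conformity index
#'
#' `CI = TV_PIV^2 / (TV x PIV)` where `TV` is the target volume, `PIV` the
#' prescription isodose volume (all voxels with dose >= prescription), and
#' `TV_PIV` their intersection. 1 means the prescription isodose coincides
#' with the target; values fall towards 0 for under-coverage or spill.
#'
#' @param dose A [dose_grid()].
#' @param ss A co-registered [structure_set()].
#' @param prescription_gy Prescription dose level in Gy (> 0).
#' @param roi Target ROI name (default `"ptv"`).
#' @return CI in `[0, 1]`; 0 with a warning when no voxel reaches the
#'   prescription dose.
#' @export
paddick_ci <- function(dose, ss, prescription_gy, roi = "ptv") {
  check_grid_match(dose, ss)
  if (prescription_gy <= 0) stop("prescription must be > 0 Gy")
  stop_if_missing_roi(ss, roi)
  iso <- dose$array >= prescription_gy
  piv <- sum(iso)
  if (piv == 0) {
    warning("prescription isodose volume is empty; CI = 0")
    return(0)
  }
  tv <- sum(ss$masks[[roi]])
  tv_piv <- sum(iso & ss$masks[[roi]])
  tv_piv^2 / (tv * piv)
}

#' Rescale a dose grid so that a coverage criterion is met exactly
#'
#' Multiplies the whole grid by the single scalar that makes
#' `D(coverage)%` of the target equal the prescription — the plan
#' normalization "prescription dose covers 95% of the PTV". Exactly
#' idempotent because [dose_at_volume()] is homogeneous in dose.
#'
#' @inheritParams paddick_ci
#' @param coverage_pct Coverage percentage (default 95).
#' @return The rescaled [dose_grid()]; the applied scale factor is attached
#'   as attribute `"scale"`.
#' @export
normalize_to_coverage <- function(dose, ss, prescription_gy, coverage_pct = 95,
                                  roi = "ptv") {
  dvh <- compute_dvh(dose, ss, roi)
  dcov <- dose_at_volume(dvh, coverage_pct)
  if (dcov <= 0) stop("D", coverage_pct, "% of '", roi,
                      "' is zero; cannot normalize")
  s <- prescription_gy / dcov
  out <- dose_grid(dose$array * s, dose$spacing, dose$origin)
  attr(out, "scale") <- s
  out
}

#' Evaluate a dose grid against a structure set
#'
#' Computes every plan-quality index used for SBRT plan review: PTV minimum /
#' maximum / mean dose (true voxel extrema), homogeneity index, Paddick
#' conformity index; maximum dose for the serial organs at risk (bronchus,
#' esophagus, spinal cord, rib, heart); mean dose, V10 and V20 for the lung.
#' Missing optional OARs yield `NA` metrics (absent, not failing). When a
#' plan template is supplied, each metric is also checked against its
#' clinical constraint via [check_plan_against_spec()].
#'
#' @param dose A [dose_grid()].
#' @param ss A co-registered [structure_set()] with non-empty `ptv` and `lung`.
#' @param prescription_gy Prescription dose (Gy) for the conformity index.
#' @param total_mu Optional total monitor units (pass-through metadata).
#' @return Object of class `plan_metrics`: a named list of indices
#'   (`ptv_dmin_gy`, `ptv_dmax_gy`, `ptv_dmean_gy`, `ptv_hi`, `ptv_ci`,
#'   `<oar>_dmax_gy`, `lung_dmean_gy`, `lung_v10_pct`, `lung_v20_pct`,
#'   `total_mu`).
#' @export
evaluate_plan <- function(dose, ss, prescription_gy = 50, total_mu = NA_real_) {
  check_grid_match(dose, ss)
  stop_if_missing_roi(ss, c("ptv", "lung"))
  dvh_ptv <- compute_dvh(dose, ss, "ptv")
  dvh_lung <- compute_dvh(dose, ss, "lung")
  oar_dmax <- function(roi) {
    if (!roi %in% names(ss$masks) || !any(ss$masks[[roi]])) return(NA_real_)
    max(dose$array[ss$masks[[roi]]])
  }
  m <- list(
    ptv_dmin_gy = min(dvh_ptv$dose_sorted),
    ptv_dmax_gy = max(dvh_ptv$dose_sorted),
    ptv_dmean_gy = mean(dvh_ptv$dose_sorted),
    ptv_hi = homogeneity_index(dvh_ptv),
    ptv_ci = paddick_ci(dose, ss, prescription_gy),
    bronchus_dmax_gy = oar_dmax("bronchus"),
    esophagus_dmax_gy = oar_dmax("esophagus"),
    spinal_cord_dmax_gy = oar_dmax("spinal_cord"),
    rib_dmax_gy = oar_dmax("rib"),
    heart_dmax_gy = oar_dmax("heart"),
    lung_dmean_gy = mean(dvh_lung$dose_sorted),
    lung_v10_pct = volume_at_dose(dvh_lung, 10),
    lung_v20_pct = volume_at_dose(dvh_lung, 20),
    total_mu = total_mu
  )
  structure(m, class = "plan_metrics", case_id = ss$case_id,
            prescription_gy = prescription_gy)
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat("plan metrics",
      if (!is.null(attr(x, "case_id"))) paste0("(", attr(x, "case_id"), ")"),
      "\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm,
                                   ifelse(is.na(x[[nm]]), "-", sprintf("%.3f", x[[nm]]))))
  invisible(x)
}

#' Bind per-case plan metrics into a cohort table
#'
#' @param metrics List of `plan_metrics` (from [evaluate_plan()]).
#' @return `data.frame` with `case_id` plus one column per index.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "plan_metrics")) metrics <- list(metrics)
  ids <- vapply(seq_along(metrics), function(i) {
    id <- attr(metrics[[i]], "case_id")
    if (is.null(id)) sprintf("case%03d", i) else as.character(id)
  }, character(1))
  cbind(data.frame(case_id = ids, stringsAsFactors = FALSE),
        do.call(rbind, lapply(metrics, function(m) as.data.frame(unclass(m)))))
}
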