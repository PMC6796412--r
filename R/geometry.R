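#' Names of the anatomical geometry features
#'
#' The 11 scalar features extracted from a thoracic structure set:
#' `V_PTV`, `V_Lung`, `V_Heart` (volumes, mm^3); `D_PL`, `D_PH` (3D Euclidean
#' distances between the PTV mass center and the lung / heart mass centers,
#' mm); `OVZ_PL`, `OVZ_PH` (overlap length of the PTV and the lung / heart
#' along the z axis, mm); and `X_PL`, `Y_PL`, `X_PH`, `Y_PH` (signed per-axis
#' offsets of the PTV mass center from the lung / heart mass centers, mm).
#'
#' @return Character vector of length 11.
#' @export
kbp_feature_names <- function() {
  c("V_PTV", "V_Lung", "V_Heart", "D_PL", "D_PH",
    "OVZ_PL", "OVZ_PH", "X_PL", "Y_PL", "X_PH", "Y_PH")
}

#' Volume of a binary mask
#'
#' @param mask 3D logical array.
#' @param spacing Voxel spacing (mm), length 3, all > 0.
#' @param roi Optional ROI name; an empty `ptv`/`lung`/`heart` mask triggers a
#'   warning (these are required non-empty for feature extraction).
#' @return Volume in mm^3 (set-voxel count times voxel volume).
#' @export
compute_volume <- function(mask, spacing, roi = NULL) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  n <- sum(mask)
  if (n == 0 && !is.null(roi) && roi %in% c("ptv", "lung", "heart"))
    warning("ROI '", roi, "' is empty; volume is 0")
  n * prod(spacing)
}

#' Mass center of a binary mask
#'
#' Unweighted centroid of the set voxels' center coordinates in patient space
#' (no CT density weighting).
#'
#' @inheritParams compute_volume
#' @param origin Grid origin (mm), length 3.
#' @return Numeric `(x, y, z)` in mm.
#' @export
compute_mass_center <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI: mass center undefined")
  ctr <- origin + (colMeans(idx) - 0.5) * spacing
  names(ctr) <- c("x", "y", "z")
  ctr
}

z_extent <- function(mask, spacing, origin) {
  nz <- dim(mask)[3]
  per_slice <- colSums(matrix(mask, ncol = nz)) > 0
  k <- which(per_slice)
  if (!length(k)) stop("empty ROI: z extent undefined")
  # occupied-slice interval including half-voxel margins at both ends
  c(origin[3] + (min(k) - 1) * spacing[3],
    origin[3] + max(k) * spacing[3])
}

#' Overlap length of two ROIs along the z (superior-inferior) axis
#'
#' Each ROI's z extent is the interval from its lowest to its highest occupied
#' slice, widened by half a voxel at each end so that a single-slice ROI has
#' extent `dz`. The overlap is the length of the intersection of the two
#' intervals, 0 if disjoint.
#'
#' @param mask_a,mask_b 3D logical arrays on the same grid, both non-empty.
#' @inheritParams compute_mass_center
#' @return Overlap length in mm (>= 0).
#' @export
compute_axis_overlap_z <- function(mask_a, mask_b, spacing, origin = c(0, 0, 0)) {
  ea <- z_extent(mask_a, spacing, origin)
  eb <- z_extent(mask_b, spacing, origin)
  max(0, min(ea[2], eb[2]) - max(ea[1], eb[1]))
}

#' Extract the 11 anatomical geometry features from a structure set
#'
#' Requires non-empty `ptv`, `lung` and `heart` masks. Distances are 3D
#' Euclidean distances between binary-mask mass centers; per-axis offsets are
#' signed (PTV center minus organ center), so mirrored anatomies produce
#' mirrored features. All features are invariant under rigid translation of
#' the whole grid.
#'
#' @param ss A [structure_set()].
#' @return Object of class `geometry_features`: a named numeric vector with
#'   the [kbp_feature_names()] entries (volumes mm^3, lengths mm) and the
#'   case id as an attribute.
#' @export
compute_features <- function(ss) {
  stopifnot(inherits(ss, "structure_set"))
  stop_if_missing_roi(ss, c("ptv", "lung", "heart"))
  sp <- ss$spacing; or <- ss$origin
  c_ptv <- compute_mass_center(ss$masks$ptv, sp, or)
  c_lung <- compute_mass_center(ss$masks$lung, sp, or)
  c_heart <- compute_mass_center(ss$masks$heart, sp, or)
  f <- c(
    V_PTV = compute_volume(ss$masks$ptv, sp, "ptv"),
    V_Lung = compute_volume(ss$masks$lung, sp, "lung"),
    V_Heart = compute_volume(ss$masks$heart, sp, "heart"),
    D_PL = sqrt(sum((c_ptv - c_lung)^2)),
    D_PH = sqrt(sum((c_ptv - c_heart)^2)),
    OVZ_PL = compute_axis_overlap_z(ss$masks$ptv, ss$masks$lung, sp, or),
    OVZ_PH = compute_axis_overlap_z(ss$masks$ptv, ss$masks$heart, sp, or),
    X_PL = unname(c_ptv["x"] - c_lung["x"]),
    Y_PL = unname(c_ptv["y"] - c_lung["y"]),
    X_PH = unname(c_ptv["x"] - c_heart["x"]),
    Y_PH = unname(c_ptv["y"] - c_heart["y"])
  )
  structure(f, class = "geometry_features", case_id = ss$case_id)
}

#' Bind per-case geometry features into a feature table
#'
#' @param features List of `geometry_features` (from [compute_features()]).
#' @param case_ids Optional ids; defaults to the ids carried by the features.
#' @return `data.frame` with `case_id` plus the 11 feature columns.
#' @export
feature_table <- function(features, case_ids = NULL) {
  if (inherits(features, "geometry_features")) features <- list(features)
  if (is.null(case_ids))
    case_ids <- vapply(seq_along(features), function(i) {
      id <- attr(features[[i]], "case_id")
      if (is.null(id)) sprintf("case%03d", i) else as.character(id)
    }, character(1))
  mat <- do.call(rbind, lapply(features, function(f) unclass(f)[kbp_feature_names()]))
  cbind(data.frame(case_id = case_ids, stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Write a feature table to CSV
#'
#' Columns: `case_id` plus the 11 feature symbols from [kbp_feature_names()].
#'
#' @param tab Feature table (from [feature_table()] or [generate_cohort()]).
#' @param path Output CSV path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
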