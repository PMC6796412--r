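#' Voxelized structure set
#'
#' A `structure_set` bundles named binary voxel masks (regions of interest,
#' ROIs) that share one regular grid: voxel spacing in mm, grid origin in
#' patient coordinates (mm), and a fixed axis convention
#' (x = patient left-right, y = anterior-posterior, z = superior-inferior).
#' Arrays are indexed `[i, j, k]` along (x, y, z); the world coordinate of the
#' center of voxel `i` (1-based) along an axis is
#' `origin + (i - 0.5) * spacing`.
#'
#' ROI names are lower-case by convention; `ptv`, `lung` and `heart` are
#' required for geometry feature extraction, while serial organs
#' (`bronchus`, `esophagus`, `spinal_cord`, `rib`) are optional and only used
#' for plan evaluation.
#'
#' @param masks Named list of 3D `logical` (or 0/1) arrays, all the same shape.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all > 0.
#' @param origin Numeric length-3, patient-space coordinate (mm) of the grid
#'   corner (voxel centers are offset half a voxel inwards).
#' @param axes Axis convention label; only `"LPS-like"` (x left-right,
#'   y ant-post, z sup-inf) is recognized.
#' @param case_id Optional case identifier carried through tables and reports.
#'
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0),
                          axes = "LPS-like", case_id = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("`masks` must be a named list of 3D arrays")
  masks <- lapply(masks, function(m) {
    if (length(dim(m)) != 3L) stop("each mask must be a 3D array")
    storage.mode(m) <- "logical"
    m
  })
  dims <- lapply(masks, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all masks must share the same grid shape")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  if (!identical(axes, "LPS-like"))
    stop("unsupported axis convention: ", axes,
         " (expected \"LPS-like\": x left-right, y ant-post, z sup-inf)")
  ss <- structure(
    list(masks = masks, spacing = spacing, origin = origin,
         axes = axes, case_id = case_id),
    class = "structure_set"
  )
  # plausibility screen only: clinical SBRT target volumes are small
  if ("ptv" %in% names(masks)) {
    v_cm3 <- compute_volume(masks$ptv, spacing) / 1000
    if (v_cm3 > 0 && (v_cm3 < 3.19 || v_cm3 > 357.20))
      warning(sprintf("PTV volume %.2f cm^3 outside plausible SBRT range [3.19, 357.20] cm^3", v_cm3))
  }
  ss
}

#' @export
print.structure_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat("structure_set:", if (is.null(x$case_id)) "<unnamed>" else x$case_id, "\n")
  cat(sprintf("  grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$axes))
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %8d voxels (%.2f cm^3)\n", nm, sum(x$masks[[nm]]),
                compute_volume(x$masks[[nm]], x$spacing) / 1000))
  invisible(x)
}

grid_dim <- function(ss) dim(ss$masks[[1]])

stop_if_missing_roi <- function(ss, rois) {
  missing <- setdiff(rois, names(ss$masks))
  if (length(missing))
    stop("structure set is missing required ROI(s): ",
         paste(missing, collapse = ", "))
  empty <- rois[vapply(ss$masks[rois], function(m) !any(m), logical(1))]
  if (length(empty))
    stop("required ROI(s) empty: ", paste(empty, collapse = ", "))
  invisible(TRUE)
}

#' Read a structure set from NIfTI volumes listed in a YAML manifest
#'
#' The manifest maps ROI names to single-channel NIfTI files, one file per
#' ROI, with optional `origin` and `case_id` entries:
#' ```yaml
#' case_id: case001
#' origin: [0, 0, 0]
#' rois:
#'   ptv: ptv.nii.gz
#'   lung: lung.nii.gz
#'   heart: heart.nii.gz
#' ```
#' Voxel spacing is taken from the NIfTI headers (pixdim), which must agree
#' across ROIs; paths are resolved relative to the manifest. Voxels > 0 are
#' treated as inside the ROI.
#'
#' @param manifest_path Path to the YAML manifest.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(manifest_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI structure sets requires the RNifti package")
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$rois) || !length(man$rois))
    stop("manifest has no `rois` entry")
  base <- dirname(normalizePath(manifest_path))
  vols <- lapply(man$rois, function(p) {
    p <- if (file.exists(p)) p else file.path(base, p)
    RNifti::readNifti(p)
  })
  spacings <- lapply(vols, function(v) round(RNifti::pixdim(v), 9))
  if (length(unique(spacings)) != 1L)
    stop("ROI volumes disagree on voxel spacing")
  masks <- lapply(vols, function(v) array(as.vector(v) > 0, dim = dim(v)))
  origin <- if (is.null(man$origin)) c(0, 0, 0) else as.numeric(man$origin)
  structure_set(masks, spacing = as.numeric(spacings[[1]]), origin = origin,
                case_id = man$case_id)
}

#' Write a structure set as per-ROI NIfTI volumes plus a YAML manifest
#'
#' Inverse of [read_structure_set()]; mainly used to exchange synthetic
#' cohorts with external tools.
#'
#' @param ss A [structure_set()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_structure_set <- function(ss, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI structure sets requires the RNifti package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(ss$masks)) {
    img <- RNifti::asNifti(array(as.integer(ss$masks[[nm]]), dim = grid_dim(ss)),
                           pixdim = ss$spacing)
    f <- paste0(nm, ".nii.gz")
    RNifti::writeNifti(img, file.path(dir, f))
    files[[nm]] <- f
  }
  man <- list(case_id = ss$case_id, origin = as.list(ss$origin), rois = files)
  path <- file.path(dir, "structures.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
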