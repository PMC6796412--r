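#' Configuration of a synthetic thoracic cohort
#'
#' Describes the virtual patient population used for end-to-end testing and
#' parameter-recovery experiments: grid geometry, organ size ranges, the PTV
#' volume range (defaults to the clinical SBRT range 3.19-357.20 cm^3), the
#' geometry-to-parameter mapping and the per-target noise levels emulating
#' planner-to-planner variability. Cohort sizes default to the study design
#' of 125 training and 30 test cases.
#'
#' All randomness derives from `seed` and the case index, so a cohort is
#' reproducible case-by-case.
#'
#' @param n_train,n_test Cohort sizes.
#' @param grid_shape Grid dimensions (voxels along x, y, z).
#' @param spacing Voxel spacing (mm).
#' @param ptv_volume_range_cm3 PTV volume range (cm^3); volumes are drawn
#'   log-uniformly, truncated per-case to what fits inside the hosting lung.
#' @param sigma Named per-target noise SDs (deg, deg, Gy, %, %).
#' @param noise_cor_v Correlation between the V10 and V20 noise draws (a hot
#'   plan tends to be hot at both dose levels).
#' @param mapping Geometry-to-parameter mapping, see [default_target_mapping()].
#' @param include_oars Also rasterize placeholder serial organs
#'   (spinal cord, esophagus, bronchus, rib) for plan-evaluation plumbing.
#' @param seed Master seed (mandatory).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_train = 125L, n_test = 30L,
                          grid_shape = c(96L, 96L, 80L),
                          spacing = c(3, 3, 3),
                          ptv_volume_range_cm3 = c(3.19, 357.20),
                          sigma = c(start_deg = 15, stop_deg = 10,
                                    mld_gy = 0.8, v10_pct = 3.0,
                                    v20_pct = 1.71),
                          noise_cor_v = 0.8,
                          mapping = default_target_mapping(),
                          include_oars = TRUE,
                          seed) {
  if (missing(seed)) stop("a master seed is mandatory")
  stopifnot(all(grid_shape > 0), all(spacing > 0),
            all(ptv_volume_range_cm3 > 0),
            all(sigma >= 0),
            all(kbp_target_names() %in% names(sigma)))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 ptv_volume_range_cm3 = as.numeric(ptv_volume_range_cm3),
                 sigma = sigma[kbp_target_names()],
                 noise_cor_v = noise_cor_v,
                 mapping = mapping, include_oars = isTRUE(include_oars),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic per-case seed below 2^31
derive_seed <- function(master, case_index, salt = 0L) {
  as.integer((as.double(master) * 48271 + case_index * 1009 + salt * 7919) %%
               2147483647)
}

ellipsoid_mask <- function(xs, ys, zs, center, axes) {
  qx <- ((xs - center[1]) / axes[1])^2
  qy <- ((ys - center[2]) / axes[2])^2
  qz <- ((zs - center[3]) / axes[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

sphere_mask_at <- function(xs, ys, zs, center, r) {
  qx <- (xs - center[1])^2
  qy <- (ys - center[2])^2
  qz <- (zs - center[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= r^2
}

#' Generate one synthetic thoracic anatomy
#'
#' Rasterizes a stylized thorax on the configured grid: two lung ellipsoids
#' (the heart volume is carved out of the lung), a heart ellipsoid between
#' them, and a spherical PTV placed at a random eccentric position strictly
#' inside one randomly chosen lung. Placement uses the erosion property of
#' ellipsoids (a sphere of radius r centred inside the concentric ellipsoid
#' with semi-axes reduced by r is contained in the ellipsoid), plus a bounded
#' retry loop to avoid the heart carve-out. Optional placeholder serial
#' organs support plan-evaluation plumbing: a spinal-cord cylinder, an
#' esophagus cylinder, a short bronchus cylinder and a lateral rib slab on
#' the PTV side.
#'
#' Fully deterministic given `(config$seed, case_index)`.
#'
#' @param config A [cohort_config()].
#' @param case_index Positive integer case index within the cohort.
#' @return A [structure_set()] with `case_id = "case<index>"`.
#' @export
generate_anatomy <- function(config, case_index) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, case_index, salt = 1L))
  shape <- config$grid_shape; sp <- config$spacing
  xs <- (seq_len(shape[1]) - 0.5) * sp[1]
  ys <- (seq_len(shape[2]) - 0.5) * sp[2]
  zs <- (seq_len(shape[3]) - 0.5) * sp[3]
  ctr <- shape * sp / 2

  # lungs: one ellipsoid per side, mirrored centres, independently jittered
  lung_axes <- list(
    left = c(stats::runif(1, 50, 62), stats::runif(1, 65, 85),
             stats::runif(1, 85, 105)),
    right = c(stats::runif(1, 50, 62), stats::runif(1, 65, 85),
              stats::runif(1, 85, 105))
  )
  lung_ctr <- list(
    left = ctr + c(70, stats::runif(1, -5, 5), stats::runif(1, -5, 5)),
    right = ctr + c(-70, stats::runif(1, -5, 5), stats::runif(1, -5, 5))
  )
  m_left <- ellipsoid_mask(xs, ys, zs, lung_ctr$left, lung_axes$left)
  m_right <- ellipsoid_mask(xs, ys, zs, lung_ctr$right, lung_axes$right)

  # PTV: log-uniform volume truncated to what fits in the hosting lung
  side <- sample(c("left", "right"), 1)
  ax <- lung_axes[[side]]; lc <- lung_ctr[[side]]
  margin <- max(sp)
  r_max <- min(ax) - margin - 1
  vr <- config$ptv_volume_range_cm3 * 1000
  v_hi <- min(vr[2], 4 / 3 * pi * r_max^3)
  v <- exp(stats::runif(1, log(vr[1]), log(v_hi)))
  r <- (3 * v / (4 * pi))^(1 / 3)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
  p <- lc + u * (ax - r - margin)

  # Heart: ellipsoid between the lungs. Its anterior-posterior centre is
  # anchored to the tumour's y position with an independent jitter, so the
  # tumour-heart offset Y_PH is pure jitter, statistically independent of the
  # tumour-lung offset Y_PL — emulating the clinical observation that Y_PL
  # carries beam-angle information while Y_PH does not.
  heart_s <- stats::runif(1, 0.93, 1.07)
  heart_axes <- c(42, 48, 55) * heart_s
  place_heart <- function(p) {
    c(ctr[1] + stats::runif(1, 0, 20),
      p[2] + stats::runif(1, -35, 5),
      ctr[3] + stats::runif(1, -35, -15))
  }

  # PTV containment in the hosting lung ellipsoid is guaranteed analytically
  # (erosion bound); disjointness from the heart is verified per voxel, with
  # placement and heart re-drawn on collision and the radius shrunk every 12
  # failed attempts so the loop is bounded
  m_side <- if (side == "left") m_left else m_right
  m_ptv <- NULL
  for (attempt in seq_len(60)) {
    heart_ctr <- place_heart(p)
    m_heart <- ellipsoid_mask(xs, ys, zs, heart_ctr, heart_axes)
    cand <- sphere_mask_at(xs, ys, zs, p, r)
    if (any(cand) && all(m_side[cand]) && !any(cand & m_heart)) {
      m_ptv <- cand; break
    }
    if (attempt %% 12 == 0) r <- 0.85 * r
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    p <- lc + u * (ax - r - margin)
  }
  if (is.null(m_ptv))
    stop("could not place PTV inside the lung after 60 attempts (case ",
         case_index, ")")
  m_lung <- (m_left | m_right) & !m_heart

  masks <- list(ptv = m_ptv, lung = m_lung, heart = m_heart)
  if (config$include_oars) {
    cyl <- function(cx, cy, rad, zlo, zhi) {
      qx <- (xs - cx)^2; qy <- (ys - cy)^2
      disc <- outer(qx, qy, `+`) <= rad^2
      zin <- zs >= zlo & zs <= zhi
      outer(disc, zin, `&`)
    }
    zl <- range(zs)
    masks$spinal_cord <- cyl(ctr[1], ctr[2] + 105, 6, zl[1], zl[2])
    masks$esophagus <- cyl(ctr[1] - 8, ctr[2] + 35, 5, zl[1] + 20, zl[2] - 20)
    masks$bronchus <- cyl(ctr[1], ctr[2], 8, ctr[3], ctr[3] + 60)
    sgn <- if (side == "left") 1 else -1
    rib_x <- lc[1] + sgn * (ax[1] + 6)
    rib <- abs(xs - rib_x) <= 5
    yin <- abs(ys - lc[2]) <= ax[2]
    zin <- abs(zs - lc[3]) <= ax[3]
    masks$rib <- outer(outer(rib, yin, `&`), zin, `&`)
  }
  suppressWarnings(
    structure_set(masks, spacing = sp, origin = c(0, 0, 0),
                  case_id = sprintf("case%03d", case_index))
  )
}

#' Default geometry-to-parameter mapping of the synthetic cohort
#'
#' The closed-form smooth mapping from anatomical features to noiseless plan
#' parameters. Each feature is normalized with a fixed reference center and
#' scale (constants of the mapping, not data statistics) and passed through
#' `tanh`, so the mapping is bounded and low-order yet nonlinear. The signs
#' encode the clinically observed monotone structure: lung dose burden
#' (MLD, V10, V20) grows with PTV volume and PTV-lung z overlap and falls
#' with lung volume and the PTV-lung / PTV-heart distances; the arc angles
#' grow with the lateral/vertical PTV offsets (X_PL, Y_PL, X_PH) and fall
#' with the PTV-heart distance. Heart volume and Y_PH are deliberately
#' unused. Angle ground truth stays inside a wraparound-free band
#' (start well below stop, both in (0, 360)) so plain scalar regression is
#' well posed; a wraparound stress shift is available for circular-error
#' tests.
#'
#' @return Object of class `target_mapping`: per-target intercepts and
#'   per-feature coefficients, plus reference centers/scales and output
#'   floors/ceilings.
#' @export
default_target_mapping <- function() {
  structure(list(
    reference = list(
      center = c(logV_PTV = 10.5, V_Lung = 3.15e6, D_PL = 84, D_PH = 90,
                 OVZ_PL = 45, OVZ_PH = 32, X_PL = 0, Y_PL = 0, X_PH = 0),
      scale = c(logV_PTV = 1.4, V_Lung = 2.6e5, D_PL = 15, D_PH = 15,
                OVZ_PL = 20, OVZ_PH = 20, X_PL = 60, Y_PL = 25, X_PH = 60)
    ),
    intercept = c(start_deg = 70, stop_deg = 300, mld_gy = 3.4,
                  v10_pct = 9.7, v20_pct = 4.6),
    coef = list(
      start_deg = c(X_PL = 16, Y_PL = 12, X_PH = 5, D_PH = -6),
      stop_deg = c(X_PL = 13, Y_PL = 10, X_PH = 4, D_PH = -5),
      mld_gy = c(logV_PTV = 1.0, OVZ_PL = 0.8, V_Lung = -0.7, D_PL = -0.8,
                 D_PH = -0.45, OVZ_PH = 0.25),
      v10_pct = c(logV_PTV = 3.2, OVZ_PL = 2.4, V_Lung = -1.9, D_PL = -2.4,
                  D_PH = -1.1, OVZ_PH = 0.7),
      v20_pct = c(logV_PTV = 1.7, OVZ_PL = 1.3, V_Lung = -0.95, D_PL = -1.3,
                  D_PH = -0.6, OVZ_PH = 0.35)
    ),
    bounds = list(start_deg = c(5, 175), stop_deg = c(195, 355),
                  mld_gy = c(0.3, Inf), v10_pct = c(1, 100),
                  v20_pct = c(0.5, 100))
  ), class = "target_mapping")
}

map_targets_noiseless <- function(features, mapping) {
  f <- unclass(features)
  ref <- mapping$reference
  zval <- function(nm) {
    raw <- if (nm == "logV_PTV") log(f[["V_PTV"]]) else f[[nm]]
    tanh((raw - ref$center[[nm]]) / ref$scale[[nm]])
  }
  out <- numeric(0)
  for (tg in names(mapping$coef)) {
    co <- mapping$coef[[tg]]
    y <- mapping$intercept[[tg]] +
      sum(vapply(names(co), function(nm) co[[nm]] * zval(nm), numeric(1)))
    b <- mapping$bounds[[tg]]
    out[tg] <- min(max(y, b[1]), b[2])
  }
  out
}

#' Generate ground-truth plan parameters for one case
#'
#' Applies the deterministic geometry-to-parameter mapping to the case's
#' features and adds Gaussian noise emulating planner-to-planner variation
#' (SDs from the config). The V10 and V20 noise draws are correlated
#' (`noise_cor_v`), and physical consistency is restored afterwards:
#' v20 <= v10, doses and volumes within range, angles within the mapping's
#' band. With all-zero noise the output is a pure function of the features.
#'
#' @param features `geometry_features` (or named vector) for the case.
#' @param config A [cohort_config()] (carries mapping and noise SDs).
#' @param case_index Case index; randomness derives from
#'   `(config$seed, case_index)`.
#' @param noiseless Skip the noise injection.
#' @return Named numeric vector over [kbp_target_names()].
#' @export
generate_ground_truth <- function(features, config, case_index,
                                  noiseless = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  mu <- map_targets_noiseless(features, config$mapping)
  if (noiseless) return(mu)
  set.seed(derive_seed(config$seed, case_index, salt = 2L))
  s <- config$sigma
  z <- stats::rnorm(4) # start, stop, mld, shared-v
  z_extra <- stats::rnorm(1)
  rho <- config$noise_cor_v
  n <- c(start_deg = s[["start_deg"]] * z[1],
         stop_deg = s[["stop_deg"]] * z[2],
         mld_gy = s[["mld_gy"]] * z[3],
         v10_pct = s[["v10_pct"]] * z[4],
         v20_pct = s[["v20_pct"]] * (rho * z[4] + sqrt(1 - rho^2) * z_extra))
  y <- mu + n[names(mu)]
  b <- config$mapping$bounds
  for (tg in names(y)) y[tg] <- min(max(y[tg], b[[tg]][1]), b[[tg]][2])
  y["v20_pct"] <- min(y["v20_pct"], y["v10_pct"])
  y
}

#' Generate a complete synthetic cohort table
#'
#' Runs [generate_anatomy()], [compute_features()] and
#' [generate_ground_truth()] for each case index and binds the results into
#' the training-table CSV dialect ([read_training_table()]). Case indices
#' 1..n_train are the training cohort; `n_train + 1 .. n_train + n_test`
#' the external test cohort.
#'
#' @param config A [cohort_config()].
#' @param case_indices Which cases to generate (default: full train + test).
#' @param keep_structures Also return the structure sets (memory-heavy).
#' @return `list(table = data.frame, structures = list or NULL)`; the table
#'   has `case_id`, a `cohort` column (`"train"`/`"test"`), the 11 feature
#'   and 5 target columns.
#' @export
generate_cohort <- function(config,
                            case_indices = seq_len(config$n_train + config$n_test),
                            keep_structures = FALSE) {
  feats <- vector("list", length(case_indices))
  truths <- vector("list", length(case_indices))
  structs <- if (keep_structures) vector("list", length(case_indices)) else NULL
  for (i in seq_along(case_indices)) {
    ci <- case_indices[i]
    ss <- generate_anatomy(config, ci)
    feats[[i]] <- compute_features(ss)
    truths[[i]] <- generate_ground_truth(feats[[i]], config, ci)
    if (keep_structures) structs[[i]] <- ss
  }
  tab <- feature_table(feats)
  tab$cohort <- ifelse(case_indices <= config$n_train, "train", "test")
  tt <- do.call(rbind, truths)
  tab <- cbind(tab, as.data.frame(tt))
  rownames(tab) <- NULL
  list(table = tab, structures = structs)
}

#' Generate a synthetic falloff dose grid for one case
#'
#' Analytic stand-in for a treatment planning system's optimized dose: a
#' prescription-level plateau inside the PTV with a mild parabolic boost
#' towards the PTV centre (so the target DVH is inhomogeneous like a real
#' SBRT plan), and an exponential radial falloff outside the PTV surface
#' that irradiates the surrounding lung and, more distantly, the other
#' organs. Optional multiplicative log-normal voxel noise adds DVH texture.
#' The grid is normalized so that the prescription dose covers exactly
#' `coverage_pct` of the PTV ([normalize_to_coverage()]).
#'
#' @param ss A [structure_set()] with a non-empty `ptv`.
#' @param case_seed Seed for the voxel noise.
#' @param prescription_gy,coverage_pct Normalization protocol (50 Gy at 95%).
#' @param falloff_mm Exponential falloff length of the out-of-target dose.
#' @param boost Fractional central boost inside the PTV (0.25 puts the
#'   noiseless maximum at 125% of the plateau, inside the 150% cap).
#' @param noise_sd SD of the log-normal voxel noise (0 = noiseless).
#' @param normalize Apply the coverage normalization (default `TRUE`).
#' @return A [dose_grid()].
#' @export
generate_dose_grid <- function(ss, case_seed = 1L, prescription_gy = 50,
                               coverage_pct = 95, falloff_mm = 12,
                               boost = 0.25, noise_sd = 0.02,
                               normalize = TRUE) {
  stopifnot(inherits(ss, "structure_set"))
  stop_if_missing_roi(ss, "ptv")
  sp <- ss$spacing; shape <- grid_dim(ss)
  ctr <- compute_mass_center(ss$masks$ptv, sp, ss$origin)
  r_eq <- (3 * compute_volume(ss$masks$ptv, sp) / (4 * pi))^(1 / 3)
  xs <- ss$origin[1] + (seq_len(shape[1]) - 0.5) * sp[1]
  ys <- ss$origin[2] + (seq_len(shape[2]) - 0.5) * sp[2]
  zs <- ss$origin[3] + (seq_len(shape[3]) - 0.5) * sp[3]
  rho <- sqrt(outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
                    (zs - ctr[3])^2, `+`))
  inside <- ss$masks$ptv
  dose <- prescription_gy * exp(-pmax(rho - r_eq, 0) / falloff_mm)
  dose[inside] <- prescription_gy *
    (1 + boost * pmax(1 - (rho[inside] / r_eq)^2, 0))
  if (noise_sd > 0) {
    set.seed(as.integer(case_seed))
    dose <- dose * exp(stats::rnorm(length(dose), 0, noise_sd))
  }
  out <- dose_grid(dose, sp, ss$origin)
  if (normalize)
    out <- normalize_to_coverage(out, ss, prescription_gy, coverage_pct)
  out
}
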