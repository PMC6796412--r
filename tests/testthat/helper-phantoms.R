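# Shared in-code fixtures: small digital phantoms and cohort configs.

# random blob mask: union of a few random boxes, guaranteed non-empty
random_mask <- function(dim3, n_boxes = 3) {
  m <- array(FALSE, dim3)
  for (b in seq_len(n_boxes)) {
    lo <- pmax(1, floor(runif(3, 1, dim3 * 0.8)))
    hi <- pmin(dim3, lo + floor(runif(3, 0, dim3 * 0.4)))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}

# digitized sphere mask on a grid (voxel-centre rule)
sphere_mask <- function(dim3, spacing, center, radius) {
  xs <- (seq_len(dim3[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dim3[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dim3[3]) - 0.5) * spacing[3]
  outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
        (zs - center[3])^2, `+`) <= radius^2
}

# tiny three-organ structure set: PTV sphere inside a lung box, heart box aside
tiny_structure_set <- function(spacing = c(2, 2, 2)) {
  dim3 <- c(30L, 30L, 24L)
  lung <- array(FALSE, dim3); lung[4:27, 4:27, 3:22] <- TRUE
  heart <- array(FALSE, dim3); heart[12:18, 20:26, 4:12] <- TRUE
  lung <- lung & !heart
  ptv <- sphere_mask(dim3, spacing, c(18, 18, 24), 8)
  stopifnot(all(lung[ptv]))
  suppressWarnings(structure_set(list(ptv = ptv, lung = lung, heart = heart),
                                 spacing = spacing, case_id = "tiny"))
}

# coarse-grid cohort config used throughout the suite (4x cheaper than the
# default 3 mm grid; same organ geometry in mm)
coarse_config <- function(seed, ...) {
  cohort_config(grid_shape = c(64L, 64L, 54L), spacing = c(4.5, 4.5, 4.5),
                seed = seed, ...)
}

# independent sort-based oracle for Vx (fraction of voxels >= threshold)
oracle_vx <- function(doses, x) 100 * mean(doses >= x)

# independent step-function oracle for Dp: largest sampled dose with
# coverage >= p (no interpolation; implementations may differ by at most the
# gap between adjacent order statistics)
oracle_dp_step <- function(doses, p) {
  s <- sort(doses, decreasing = TRUE)
  f <- 100 * seq_along(s) / length(s)
  s[min(which(f >= p))]
}

expect_rows_named <- function(df, cols) {
  expect_true(all(cols %in% names(df)))
}
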