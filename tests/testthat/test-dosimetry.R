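make_dose_ss <- function(doses_in_roi, dim3 = c(6L, 6L, 6L)) {
  # structure set with one cubic ROI holding the given voxel doses
  n <- length(doses_in_roi)
  stopifnot(n <= prod(dim3))
  mask <- array(FALSE, dim3); mask[seq_len(n)] <- TRUE
  arr <- array(0, dim3); arr[seq_len(n)] <- doses_in_roi
  lung <- array(TRUE, dim3)
  heart <- array(FALSE, dim3); heart[prod(dim3)] <- TRUE
  ss <- suppressWarnings(structure_set(list(ptv = mask, lung = lung, heart = heart),
                                       c(1, 1, 1)))
  list(ss = ss, dose = dose_grid(arr, c(1, 1, 1)))
}

test_that("cumulative DVH matches the voxel-counting oracle", {
  set.seed(10)
  doses <- runif(200, 0, 60)
  fx <- make_dose_ss(doses, c(8L, 8L, 8L))
  dvh <- compute_dvh(fx$dose, fx$ss, "ptv")
  for (q in seq(0, 65, length.out = 100))
    expect_equal(volume_at_dose(dvh, q), oracle_vx(doses, q))
  # endpoints and monotonicity
  expect_equal(volume_at_dose(dvh, 0), 100)
  expect_equal(volume_at_dose(dvh, max(doses) + 1e-9), 0)
  vs <- volume_at_dose(dvh, seq(0, 70, by = 0.5))
  expect_true(all(diff(vs) <= 0))
})

test_that("uniform and bimodal dose produce textbook DVHs", {
  fx <- make_dose_ss(rep(10, 50))
  dvh <- compute_dvh(fx$dose, fx$ss, "ptv")
  expect_equal(volume_at_dose(dvh, 10), 100)     # >= convention at boundary
  expect_equal(volume_at_dose(dvh, 10.01), 0)
  expect_equal(dose_at_volume(dvh, 95), 10)

  fx2 <- make_dose_ss(c(rep(0, 25), rep(20, 25)))
  dvh2 <- compute_dvh(fx2$dose, fx2$ss, "ptv")
  for (q in c(0.5, 5, 19.99, 20)) expect_equal(volume_at_dose(dvh2, q), 50)
})

test_that("Dp and Vx agree with sort-based oracles and round-trip", {
  set.seed(11)
  doses <- sort(runif(120, 5, 55))  # ramp over equal-volume voxels
  fx <- make_dose_ss(doses, c(5L, 5L, 5L))
  dvh <- compute_dvh(fx$dose, fx$ss, "ptv")
  gap <- max(diff(sort(doses)))
  for (p in c(2, 25, 50, 75, 95, 98)) {
    expect_lt(abs(dose_at_volume(dvh, p) - oracle_dp_step(doses, p)), gap + 1e-12)
    # round trip: coverage at Dp is at least p (within one voxel fraction)
    expect_gte(volume_at_dose(dvh, dose_at_volume(dvh, p)),
               p - 100 / length(doses) - 1e-9)
  }
  # exact at the sampled coverage fractions
  s <- sort(doses, decreasing = TRUE)
  k <- c(10, 60, 110)
  expect_equal(dose_at_volume(dvh, 100 * k / 120), s[k])
  # Dp non-increasing in p
  dps <- dose_at_volume(dvh, seq(1, 100, by = 1))
  expect_true(all(diff(dps) <= 1e-12))
  expect_error(dose_at_volume(dvh, 0), "percentage")
  expect_error(volume_at_dose(dvh, -1), ">= 0")
})

test_that("homogeneity index is 0 for uniform dose, scale-free, and matches percentiles", {
  fx <- make_dose_ss(rep(42, 64), c(4L, 4L, 4L))
  expect_equal(homogeneity_index(compute_dvh(fx$dose, fx$ss, "ptv")), 0)

  set.seed(12)
  doses <- runif(150, 30, 70)
  fx2 <- make_dose_ss(doses, c(6L, 6L, 6L))
  dvh <- compute_dvh(fx2$dose, fx2$ss, "ptv")
  hi <- homogeneity_index(dvh)
  manual <- (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) /
    dose_at_volume(dvh, 50)
  expect_equal(hi, manual)
  expect_gt(hi, 0)
  # scale invariance of the ratio
  fx3 <- make_dose_ss(doses * 3.7, c(6L, 6L, 6L))
  expect_equal(homogeneity_index(compute_dvh(fx3$dose, fx3$ss, "ptv")), hi,
               tolerance = 1e-12)
})

test_that("Paddick CI spans its limit cases and matches voxel counting", {
  dim3 <- c(24L, 24L, 24L); sp <- c(1, 1, 1)
  ptv <- sphere_mask(dim3, sp, c(12, 12, 12), 6)
  lung <- array(TRUE, dim3)
  heart <- array(FALSE, dim3); heart[1, 1, 1] <- TRUE
  ss <- suppressWarnings(structure_set(list(ptv = ptv, lung = lung, heart = heart), sp))

  # isodose exactly the PTV -> CI = 1
  arr <- array(0, dim3); arr[ptv] <- 50
  expect_equal(paddick_ci(dose_grid(arr, sp), ss, 50), 1)

  # isodose disjoint from the PTV -> CI = 0
  arr2 <- array(0, dim3); arr2[1:3, 1:3, 1:3] <- 60
  expect_equal(paddick_ci(dose_grid(arr2, sp), ss, 50), 0)

  # nested digitized spheres: TV fully inside PIV -> CI = TV / PIV
  piv_mask <- sphere_mask(dim3, sp, c(12, 12, 12), 9)
  arr3 <- array(0, dim3); arr3[piv_mask] <- 55
  expect_equal(paddick_ci(dose_grid(arr3, sp), ss, 50),
               sum(ptv) / sum(piv_mask))
  expect_warning(ci0 <- paddick_ci(dose_grid(array(0, dim3), sp), ss, 50),
                 "empty")
  expect_equal(ci0, 0)
})

test_that("CI and HI are invariant under voxel-order permutation", {
  set.seed(13)
  doses <- runif(100, 20, 80)
  fx <- make_dose_ss(doses, c(5L, 5L, 5L))
  dvh <- compute_dvh(fx$dose, fx$ss, "ptv")
  fxp <- make_dose_ss(sample(doses), c(5L, 5L, 5L))
  dvhp <- compute_dvh(fxp$dose, fxp$ss, "ptv")
  expect_equal(homogeneity_index(dvh), homogeneity_index(dvhp))
  expect_equal(paddick_ci(fx$dose, fx$ss, 50), paddick_ci(fxp$dose, fxp$ss, 50))
})

test_that("coverage normalization scales exactly and is idempotent", {
  set.seed(14)
  fx <- make_dose_ss(runif(180, 10, 40), c(6L, 6L, 6L))
  # uniform 25 in PTV: D95 = 25, scale to 50 must be exactly 2
  fu <- make_dose_ss(rep(25, 100), c(5L, 5L, 5L))
  nu <- normalize_to_coverage(fu$dose, fu$ss, 50)
  expect_equal(attr(nu, "scale"), 2)

  n1 <- normalize_to_coverage(fx$dose, fx$ss, 50)
  dvh1 <- compute_dvh(n1, fx$ss, "ptv")
  expect_equal(dose_at_volume(dvh1, 95), 50, tolerance = 1e-9)
  n2 <- normalize_to_coverage(n1, fx$ss, 50)
  expect_equal(attr(n2, "scale"), 1, tolerance = 1e-9)
  expect_error(normalize_to_coverage(
    dose_grid(array(0, c(6, 6, 6)), c(1, 1, 1)), fx$ss, 50), "zero")
})

test_that("plan evaluation reproduces every index from first principles", {
  ss <- tiny_structure_set()
  dose <- generate_dose_grid(ss, case_seed = 5, noise_sd = 0.05)
  m <- evaluate_plan(dose, ss, prescription_gy = 50)

  ptv_d <- dose$array[ss$masks$ptv]; lung_d <- dose$array[ss$masks$lung]
  expect_equal(m$ptv_dmin_gy, min(ptv_d))
  expect_equal(m$ptv_dmax_gy, max(ptv_d))
  expect_equal(m$ptv_dmean_gy, mean(ptv_d))
  expect_equal(m$lung_dmean_gy, mean(lung_d))
  expect_equal(m$lung_v10_pct, oracle_vx(lung_d, 10))
  expect_equal(m$lung_v20_pct, oracle_vx(lung_d, 20))
  expect_equal(m$heart_dmax_gy, max(dose$array[ss$masks$heart]))
  # absent optional OARs are NA, not errors
  expect_true(is.na(m$rib_dmax_gy))
  expect_true(m$ptv_dmin_gy <= m$ptv_dmean_gy && m$ptv_dmean_gy <= m$ptv_dmax_gy)
  expect_true(m$ptv_ci >= 0 && m$ptv_ci <= 1)
})

test_that("uniform in-target dose passes constraints and scaling breaks Dmax", {
  dim3 <- c(16L, 16L, 16L); sp <- c(2, 2, 2)
  ptv <- sphere_mask(dim3, sp, c(16, 16, 16), 7)
  lung <- array(TRUE, dim3)
  heart <- array(FALSE, dim3); heart[1, 1, 1] <- TRUE
  ss <- suppressWarnings(structure_set(list(ptv = ptv, lung = lung, heart = heart), sp))
  arr <- array(0, dim3); arr[ptv] <- 50
  m <- evaluate_plan(dose_grid(arr, sp), ss)
  expect_equal(m$ptv_dmin_gy, 50)
  expect_equal(m$ptv_dmax_gy, 50)
  expect_equal(m$heart_dmax_gy, 0)
  chk <- check_plan_against_spec(m, default_plan_template())
  expect_true(attr(chk, "acceptable"))

  m80 <- evaluate_plan(dose_grid(arr * 1.6, sp), ss)  # 80 Gy plateau
  chk80 <- check_plan_against_spec(m80, default_plan_template())
  expect_false(chk80$pass[chk80$index == "ptv_dmax_gy"])
  expect_false(attr(chk80, "acceptable"))
})

test_that("mismatched grids are rejected rather than resampled", {
  ss <- tiny_structure_set()
  wrong <- dose_grid(array(1, c(10, 10, 10)), ss$spacing)
  expect_error(compute_dvh(wrong, ss, "ptv"), "co-registered")
  wrong2 <- dose_grid(array(1, dim(ss$masks$ptv)), ss$spacing * 2)
  expect_error(evaluate_plan(wrong2, ss), "co-registered")
})
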