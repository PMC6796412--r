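fake_tables <- function(n = 30, seed = 1) {
  set.seed(seed)
  f <- as.data.frame(matrix(rnorm(n * 11), n,
                            dimnames = list(NULL, kbp_feature_names())))
  t <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, kbp_target_names())))
  list(f = f, t = t)
}

test_that("Spearman rho matches the ranked-Pearson oracle and honors monotone transforms", {
  set.seed(21)
  x <- rnorm(20)
  tabs <- data.frame(x = x)
  # monotone transform invariance: y = exp(x) -> rho = 1; y = -x -> rho = -1
  r1 <- spearman_correlations(tabs, data.frame(y = exp(x)))
  expect_equal(unname(r1$rho["x", "y"]), 1)
  r2 <- spearman_correlations(tabs, data.frame(y = -x))
  expect_equal(unname(r2$rho["x", "y"]), -1)

  # ties: mid-rank Pearson oracle to 1e-12
  for (k in 1:5) {
    xs <- sample(1:6, 40, replace = TRUE)
    ys <- sample(1:5, 40, replace = TRUE) + 0.3 * xs
    rep <- spearman_correlations(data.frame(x = xs), data.frame(y = ys))
    rx <- rank(xs); ry <- rank(ys)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(unname(rep$rho["x", "y"]), oracle, tolerance = 1e-12)
  }
})

test_that("permutation P agrees with the large-sample t approximation", {
  set.seed(22)
  x <- rnorm(40); y <- 0.45 * x + rnorm(40)
  pt <- spearman_correlations(data.frame(x = x), data.frame(y = y))
  set.seed(23)
  pp <- spearman_correlations(data.frame(x = x), data.frame(y = y),
                              p_method = "permutation", n_perm = 1e5)
  expect_equal(unname(pp$p["x", "y"]), unname(pt$p["x", "y"]), tolerance = 0.01)
})

test_that("constant columns are flagged, not fatal", {
  tabs <- fake_tables()
  tabs$f$V_Heart <- 5
  expect_warning(rep <- spearman_correlations(tabs$f, tabs$t), "constant")
  expect_true(all(is.na(rep$rho["V_Heart", ])))
  expect_true(all(!rep$significant["V_Heart", ]))
})

test_that("the published clinical screen reproduces the reported feature selection", {
  path <- system.file("extdata", "clinical_correlation_screen.csv",
                      package = "kbplan")
  rep <- read_correlation_report(path, alpha = 0.05, n = 125L)
  expect_setequal(select_features(rep, "angle"),
                  c("D_PL", "D_PH", "X_PL", "Y_PL", "X_PH"))
  expect_setequal(select_features(rep, "dose"),
                  c("V_PTV", "V_Lung", "D_PL", "D_PH", "OVZ_PL", "OVZ_PH"))
  expect_setequal(excluded_features(rep), c("V_Heart", "Y_PH"))
})

test_that("selection handles degenerate screens and is monotone in alpha", {
  tabs <- fake_tables()
  rep <- spearman_correlations(tabs$f, tabs$t)
  rep$p[] <- 1
  expect_error(select_features(rep, "angle"), "no feature")
  rep$p[] <- 0; rep$significant[] <- TRUE
  expect_setequal(select_features(rep, "dose"), kbp_feature_names())

  # lowering alpha never adds features
  rep2 <- spearman_correlations(tabs$f, tabs$t)
  rep2$p[] <- matrix(runif(55), 11)
  for (a_hi in c(0.5, 0.2)) {
    hi <- tryCatch(select_features(rep2, "angle", alpha = a_hi),
                   error = function(e) character(0))
    lo <- tryCatch(select_features(rep2, "angle", alpha = a_hi / 4),
                   error = function(e) character(0))
    expect_true(all(lo %in% hi))
  }
})

test_that("standardization uses population variance and round-trips", {
  fit <- standardize_fit(data.frame(a = c(1, 2, 3)))
  out <- standardize_apply(fit, matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(out), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  set.seed(24)
  x <- matrix(rnorm(60), 20, dimnames = list(NULL, c("a", "b", "c")))
  fit2 <- standardize_fit(x)
  z <- standardize_apply(fit2, x)
  # idempotence on already-standardized data
  fit3 <- standardize_fit(z)
  expect_equal(unname(fit3$center), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(fit3$scale), rep(1, 3), tolerance = 1e-12)
  # inverse transform round trip
  expect_equal(standardize_apply(fit2, z, inverse = TRUE), x, tolerance = 1e-12)
  expect_error(standardize_fit(data.frame(a = 1:3, b = rep(2, 3))), "b")
})

test_that("SVR grid search recovers realizable functions and degenerate targets", {
  set.seed(25)
  X <- data.frame(x1 = runif(30, -2, 2), x2 = rnorm(30))
  y <- 2 * X$x1 + 1
  m <- fit_svr_grid_loo(X, y, target = "lin", grid = svr_grid(), seed = 2)
  expect_lte(m$loo_rmse, m$epsilon + 0.15)
  expect_equal(predict(m, X), y, tolerance = m$epsilon + 0.15)

  expect_warning(mc <- fit_svr_grid_loo(X, rep(5, 30), target = "const",
                                        grid = svr_grid_compact(), seed = 2),
                 "constant")
  expect_equal(predict(mc, X), rep(5, 30))
})

test_that("batch prediction equals case-by-case prediction and errors on missing features", {
  set.seed(26)
  X <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  y <- X$x1 - X$x2^2 + rnorm(25, 0, 0.05)
  m <- fit_svr_grid_loo(X, y, grid = svr_grid_compact(), seed = 4)
  batch <- predict(m, X)
  single <- vapply(seq_len(25), function(i) predict(m, X[i, ]), numeric(1))
  expect_equal(batch, single)
  expect_error(predict(m, data.frame(x1 = 1)), "x2")
})

test_that("LOO folds are isolated from the held-out case's target", {
  set.seed(27)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  y <- X$x1 + rnorm(20, 0, 0.1)
  scaler <- standardize_fit(X)
  xs <- standardize_apply(scaler, as.matrix(X))
  loo1 <- kbplan:::loo_predictions(xs, y, "radial", 10, 0.1, 0.5)
  y2 <- y; y2[7] <- y[7] + 100   # corrupt case 7's target only
  loo2 <- kbplan:::loo_predictions(xs, y2, "radial", 10, 0.1, 0.5)
  expect_equal(loo1[7], loo2[7])       # its own fold never sees it
  expect_false(isTRUE(all.equal(loo1[-7], loo2[-7])))  # other folds do
})

test_that("training is deterministic: identical inputs give byte-identical model JSON", {
  set.seed(28)
  X <- data.frame(x1 = rnorm(20), x2 = runif(20))
  y <- sin(X$x1) + rnorm(20, 0, 0.1)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_models(fit_svr_grid_loo(X, y, grid = svr_grid_compact(), seed = 9), f1)
  write_models(fit_svr_grid_loo(X, y, grid = svr_grid_compact(), seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("model JSON round-trips bit-exactly and restored models predict identically", {
  set.seed(29)
  X <- data.frame(x1 = rnorm(22), x2 = rnorm(22))
  y <- X$x1 * X$x2 + rnorm(22, 0, 0.1)
  m <- fit_svr_grid_loo(X, y, target = "t", grid = svr_grid_compact(), seed = 5)
  bundle <- structure(list(t = m), class = "kbp_models",
                      selection = list(angle = "x1", dose = "x2"), seed = 5L)
  f1 <- tempfile(fileext = ".json")
  write_models(bundle, f1)
  back <- read_models(f1)
  expect_identical(predict(back$t, X), predict(m, X))
  f2 <- tempfile(fileext = ".json")
  write_models(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("RMSE handles wraparound and matches the direct formula", {
  expect_equal(rmse(350, 10, circular = TRUE), 20)
  expect_equal(rmse(10, 350, circular = TRUE), 20)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(30)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(rmse(a, b), sqrt(mean((a - b)^2)))
  # circular error never exceeds 180
  ang1 <- runif(50, 0, 360); ang2 <- runif(50, 0, 360)
  expect_lte(rmse(ang1, ang2, circular = TRUE), 180)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("prediction post-processing enforces physical ranges", {
  tabs <- fake_tables(n = 20, seed = 31)
  tabs$t$v10_pct <- tabs$f$V_PTV * 2 + 3          # learnable
  tabs$t$v20_pct <- tabs$f$V_PTV * 2 + 2.8        # nearly v10 -> clampable
  tr <- cbind(case_id = sprintf("c%02d", 1:20), tabs$f, tabs$t)
  sel <- list(angle = c("X_PL", "Y_PL"), dose = c("V_PTV", "V_Lung"))
  mods <- fit_plan_models(tr, sel, grid = svr_grid_compact(), seed = 6)
  newf <- structure(rnorm(11), names = kbp_feature_names(),
                    class = "geometry_features")
  p <- suppressMessages(predict_plan_parameters(mods, newf))
  expect_true(all(p[c("start_deg", "stop_deg")] >= 0 &
                    p[c("start_deg", "stop_deg")] < 360))
  expect_gte(p["mld_gy"], 0)
  expect_lte(p["v20_pct"], p["v10_pct"])
})

test_that("external validation reports per-target RMSE and refuses leakage", {
  cc <- coarse_config(seed = 3, n_train = 20L, n_test = 8L)
  coh <- generate_cohort(cc)
  tab <- coh$table
  train <- tab[tab$cohort == "train", ]; test <- tab[tab$cohort == "test", ]
  sel <- list(angle = c("X_PL", "Y_PL", "X_PH", "D_PH"),
              dose = c("V_PTV", "V_Lung", "D_PL", "OVZ_PL"))
  mods <- fit_plan_models(train, sel, grid = svr_grid_compact(), seed = 3)
  val <- run_validation(mods, test)
  expect_identical(val$summary$target, kbp_target_names())
  expect_true(all(val$summary$rmse >= 0))
  expect_true(all(!is.na(val$summary$rmse_circular[1:2])))
  expect_error(run_validation(mods, train), "leakage")
})
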