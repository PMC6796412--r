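#' Names of the plan-parameter targets
#'
#' Five per-plan targets are learned from historical plans: the arc start and
#' stop gantry angles (degrees, `[0, 360)`), the mean lung dose (Gy) and the
#' lung V10 and V20 (% of lung volume). The angle group (`start_deg`,
#' `stop_deg`) and the dose group (`mld_gy`, `v10_pct`, `v20_pct`) use
#' separately selected feature sets.
#'
#' @param group `"all"`, `"angle"` or `"dose"`.
#' @return Character vector of target names.
#' @export
kbp_target_names <- function(group = c("all", "angle", "dose")) {
  group <- match.arg(group)
  switch(group,
         all = c("start_deg", "stop_deg", "mld_gy", "v10_pct", "v20_pct"),
         angle = c("start_deg", "stop_deg"),
         dose = c("mld_gy", "v10_pct", "v20_pct"))
}

# ---- Spearman screen -------------------------------------------------------

#' Spearman rank-correlation screen of features against targets
#'
#' For every (feature, target) pair computes Spearman's rho (average-rank
#' convention, i.e. Pearson correlation of mid-ranks) and a two-sided P
#' value. P uses the large-sample t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n-2` degrees of freedom by default,
#' or a permutation null when `p_method = "permutation"` (preferable for
#' small cohorts). A constant column has undefined rho; it is reported as
#' `NA` / non-significant with a warning.
#'
#' @param features `data.frame` of anatomical features (columns named as in
#'   [kbp_feature_names()]; a `case_id` column is ignored).
#' @param targets `data.frame` of plan parameters (columns named as in
#'   [kbp_target_names()]; `case_id` ignored), same row order as `features`.
#' @param alpha Significance level for the selection flags (default 0.05).
#' @param p_method `"t"` or `"permutation"`.
#' @param n_perm Number of permutation draws when `p_method = "permutation"`.
#' @return Object of class `correlation_report`: matrices `rho`, `p` and
#'   logical `significant` (features x targets), plus `alpha` and `n`.
#' @export
spearman_correlations <- function(features, targets, alpha = 0.05,
                                  p_method = c("t", "permutation"),
                                  n_perm = 10000) {
  p_method <- match.arg(p_method)
  features <- features[, setdiff(names(features), "case_id"), drop = FALSE]
  targets <- targets[, setdiff(names(targets), "case_id"), drop = FALSE]
  n <- nrow(features)
  if (n < 5) stop("need at least 5 cases for the correlation screen")
  if (n != nrow(targets)) stop("features and targets differ in case count")
  if (anyNA(features) || anyNA(targets)) stop("missing values are not allowed")
  rho <- matrix(NA_real_, ncol(features), ncol(targets),
                dimnames = list(names(features), names(targets)))
  p <- rho
  for (i in seq_len(ncol(features))) {
    x <- features[[i]]
    if (length(unique(x)) == 1L) {
      warning("feature '", names(features)[i],
              "' is constant; correlation undefined, treated as not significant")
      p[i, ] <- 1
      next
    }
    for (j in seq_len(ncol(targets))) {
      y <- targets[[j]]
      if (length(unique(y)) == 1L) {
        warning("target '", names(targets)[j],
                "' is constant; correlation undefined, treated as not significant")
        p[i, j] <- 1
        next
      }
      r <- stats::cor(x, y, method = "spearman")
      rho[i, j] <- r
      p[i, j] <- if (p_method == "t") spearman_p_t(r, n) else
        spearman_p_perm(x, y, r, n_perm)
    }
  }
  sig <- !is.na(rho) & p <= alpha
  structure(list(rho = rho, p = p, significant = sig, alpha = alpha, n = n,
                 p_method = p_method),
            class = "correlation_report")
}

spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

spearman_p_perm <- function(x, y, rho_obs, n_perm) {
  rx <- rank(x)
  null <- vapply(seq_len(n_perm), function(k)
    stats::cor(rx, sample(rank(y))), numeric(1))
  (1 + sum(abs(null) >= abs(rho_obs) - 1e-12)) / (n_perm + 1)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman screen: %d features x %d targets, n = %d, alpha = %g (%s P)\n",
              nrow(x$rho), ncol(x$rho), x$n, x$alpha, x$p_method))
  stars <- ifelse(x$significant, "*", " ")
  tab <- matrix(paste0(sprintf("% .3f", x$rho), stars),
                nrow(x$rho), dimnames = dimnames(x$rho))
  print(tab, quote = FALSE)
  invisible(x)
}

#' Write / read a correlation report as CSV
#'
#' Long layout: one row per (feature, target) pair with `rho`, `p` and
#' `significant` columns, so the table can be regenerated or supplied from a
#' published correlation screen.
#'
#' @param report A `correlation_report` (or, for reading, a CSV path).
#' @param path Output CSV path.
#' @param alpha Significance level to apply on read.
#' @name correlation_report_io
#' @export
write_correlation_report <- function(report, path) {
  long <- expand.grid(feature = rownames(report$rho),
                      target = colnames(report$rho),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$rho <- report$rho[cbind(long$feature, long$target)]
  long$p <- report$p[cbind(long$feature, long$target)]
  long$significant <- report$significant[cbind(long$feature, long$target)]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @param n Training cohort size to record (informational on read).
#' @rdname correlation_report_io
#' @export
read_correlation_report <- function(path, alpha = 0.05, n = NA_integer_) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("feature", "target", "rho", "p")
  if (!all(need %in% names(long)))
    stop("correlation CSV must have columns: ", paste(need, collapse = ", "))
  feats <- unique(long$feature); targs <- unique(long$target)
  rho <- matrix(NA_real_, length(feats), length(targs),
                dimnames = list(feats, targs))
  p <- rho
  rho[cbind(long$feature, long$target)] <- long$rho
  p[cbind(long$feature, long$target)] <- long$p
  sig <- !is.na(rho) & !is.na(p) & p <= alpha
  structure(list(rho = rho, p = p, significant = sig, alpha = alpha, n = n,
                 p_method = "external"),
            class = "correlation_report")
}

#' Select features for a target group from a correlation screen
#'
#' A feature is retained for a group (angle: start/stop; dose: MLD/V10/V20)
#' iff its correlation P value is <= `alpha` for at least one target in the
#' group; features significant for neither group are excluded from modeling
#' altogether.
#'
#' @param report A `correlation_report`.
#' @param group `"angle"` or `"dose"`.
#' @param alpha Significance level; defaults to the report's.
#' @return Character vector of selected feature names (report row order).
#' @export
select_features <- function(report, group = c("angle", "dose"),
                            alpha = report$alpha) {
  group <- match.arg(group)
  targs <- intersect(kbp_target_names(group), colnames(report$p))
  if (length(targs) < length(kbp_target_names(group)))
    stop("report does not cover all '", group, "' targets")
  pm <- report$p[, targs, drop = FALSE]
  keep <- apply(!is.na(report$rho[, targs, drop = FALSE]) & pm <= alpha, 1, any)
  sel <- rownames(pm)[keep]
  if (!length(sel))
    stop("no feature is significantly correlated with the '", group,
         "' targets at alpha = ", alpha)
  sel
}

#' Features excluded from both target groups
#'
#' @inheritParams select_features
#' @return Character vector of feature names significant for neither group.
#' @export
excluded_features <- function(report, alpha = report$alpha) {
  ang <- tryCatch(select_features(report, "angle", alpha), error = function(e) character(0))
  dos <- tryCatch(select_features(report, "dose", alpha), error = function(e) character(0))
  setdiff(rownames(report$p), union(ang, dos))
}

# ---- Standardization -------------------------------------------------------

#' Fit / apply feature standardization
#'
#' Columns are centered to mean 0 and scaled to unit variance using
#' *population* variance (divide by n), matching the usual machine-learning
#' scaler. Fitting uses training rows only; `standardize_apply()` reuses the
#' stored parameters, so test data are never refit.
#'
#' @param x `data.frame` or matrix of numeric training columns.
#' @return `standardize_fit()`: object of class `standardizer` with `center`
#'   and `scale` vectors. `standardize_apply()`: the transformed matrix.
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sc <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  bad <- names(sc)[sc == 0]
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  structure(list(center = ctr, scale = sc), class = "standardizer")
}

#' @param fit A `standardizer` from `standardize_fit()`.
#' @param inverse Apply the inverse transform instead.
#' @rdname standardize_fit
#' @export
standardize_apply <- function(fit, x, inverse = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- names(fit$center)
  x <- x[, names(fit$center), drop = FALSE]
  if (inverse)
    sweep(sweep(x, 2, fit$scale, `*`), 2, fit$center, `+`)
  else
    sweep(sweep(x, 2, fit$center), 2, fit$scale, `/`)
}

# ---- SVR with grid search + LOO CV -----------------------------------------

#' Hyperparameter grid for epsilon-SVR
#'
#' Builds the exhaustive grid explored by [fit_svr_grid_loo()], in declared
#' order (ties in the CV score are broken by the first grid point). `gamma`
#' entries may be the string `"scale"` (the `1 / (p * mean column variance)`
#' heuristic on the standardized features) or numbers. `gamma` is dropped for
#' the linear kernel.
#'
#' @param kernels Subset of `c("radial", "linear")`.
#' @param cost SVR cost parameter C values.
#' @param epsilon Epsilon-tube widths (same units as the target).
#' @param gamma RBF kernel widths; `"scale"` or numeric, as characters or
#'   numbers.
#' @return `data.frame` with columns `kernel`, `cost`, `epsilon`, `gamma`.
#' @export
svr_grid <- function(kernels = c("radial", "linear"),
                     cost = c(0.1, 1, 10, 100),
                     epsilon = c(0.01, 0.1, 0.5, 1),
                     gamma = c("scale", 0.01, 0.1, 1)) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  rows <- list()
  for (k in kernels) {
    gs <- if (k == "radial") as.character(gamma) else "scale"
    for (g in gs) for (e in epsilon) for (C in cost)
      rows[[length(rows) + 1L]] <-
        data.frame(kernel = k, cost = C, epsilon = e, gamma = g,
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' A compact grid for quick experiments and simulation studies
#'
#' RBF kernel only with the scale-heuristic width; useful when the full
#' [svr_grid()] would be needlessly slow (e.g. repeated-seed simulation).
#'
#' @return `data.frame` as in [svr_grid()].
#' @export
svr_grid_compact <- function() {
  svr_grid(kernels = "radial", cost = c(1, 10, 100),
           epsilon = c(0.1, 0.5), gamma = "scale")
}

resolve_gamma <- function(gamma_spec, xs) {
  if (identical(gamma_spec, "scale")) {
    v <- mean(apply(xs, 2, stats::var)) # ~1 on standardized features
    1 / (ncol(xs) * v)
  } else as.numeric(gamma_spec)
}

svm_fit <- function(xs, y, kernel, cost, epsilon, gamma, cross = 0) {
  e1071::svm(x = xs, y = y, type = "eps-regression", kernel = kernel,
             cost = cost, epsilon = epsilon, gamma = gamma,
             scale = FALSE, cross = cross)
}

# native kernel-expansion prediction from stored support vectors; keeps the
# trained model JSON-serializable without binary objects
svr_raw_predict <- function(model, xs) {
  if (model$kernel == "radial") {
    d2 <- outer(rowSums(xs^2), rowSums(model$sv^2), `+`) -
      2 * xs %*% t(model$sv)
    K <- exp(-model$gamma * d2)
  } else {
    K <- xs %*% t(model$sv)
  }
  drop(K %*% model$coefs - model$rho)
}

#' Train an epsilon-SVR for one target with exhaustive grid search and
#' leave-one-out cross-validation
#'
#' For every point of the hyperparameter grid the leave-one-out (LOO) CV
#' score is computed: each of the `n` cases is predicted by a model trained
#' on the other `n - 1`, and the score is the negative root-mean-squared
#' error of those held-out predictions. The best grid point (ties broken by
#' grid order) is refit on all `n` cases. Features are standardized
#' internally with training statistics ([standardize_fit()]); the target is
#' left in native units. A constant target yields a constant predictor with
#' a warning. The procedure is deterministic for fixed inputs, grid and
#' seed.
#'
#' @param features `data.frame` containing at least the `feature_names`
#'   columns (a `case_id` column, if present, is recorded for leakage checks).
#' @param y Numeric target vector, one value per row of `features`.
#' @param target Target name (one of [kbp_target_names()], or free-form).
#' @param feature_names Columns to use as predictors (the selected features).
#' @param grid Hyperparameter grid from [svr_grid()].
#' @param seed Integer seed recorded in the model metadata and set before
#'   fitting (the fit itself is deterministic; the seed pins any library
#'   internals).
#' @return Object of class `svr_model`: selected features, standardization
#'   parameters, chosen hyperparameters, support-vector expansion
#'   (`sv`, `coefs`, `rho`), LOO RMSE and per-case LOO predictions, the full
#'   grid-search table, and training metadata.
#' @export
fit_svr_grid_loo <- function(features, y, target = "target",
                             feature_names = setdiff(names(features), "case_id"),
                             grid = svr_grid(), seed = 1L) {
  missing_f <- setdiff(feature_names, names(features))
  if (length(missing_f))
    stop("features table lacks column(s): ", paste(missing_f, collapse = ", "))
  n <- nrow(features)
  if (n < 10) stop("need at least 10 training cases")
  if (length(y) != n) stop("target length does not match feature rows")
  case_ids <- if ("case_id" %in% names(features))
    as.character(features$case_id) else sprintf("case%03d", seq_len(n))

  if (length(unique(y)) == 1L) {
    warning("target '", target, "' is constant; returning constant predictor")
    return(structure(list(target = target, features = feature_names,
                          constant = y[1], n = n, seed = as.integer(seed),
                          case_ids = case_ids, loo_rmse = 0,
                          loo_predictions = rep(y[1], n),
                          version = "1.0"),
                     class = "svr_model"))
  }

  set.seed(as.integer(seed))
  x <- as.matrix(features[, feature_names, drop = FALSE])
  scaler <- standardize_fit(x)
  xs <- standardize_apply(scaler, x)

  grid$loo_rmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    gam <- resolve_gamma(grid$gamma[g], xs)
    m <- svm_fit(xs, y, grid$kernel[g], grid$cost[g], grid$epsilon[g], gam,
                 cross = n)
    # n folds of size 1: per-fold MSE is the squared held-out residual
    grid$loo_rmse[g] <- sqrt(mean(m$MSE))
  }
  best <- which.max(-grid$loo_rmse) # first max on ties = first grid point
  gam <- resolve_gamma(grid$gamma[best], xs)

  # explicit LOO predictions at the chosen hyperparameters, for reporting
  # and fold-isolation checks
  loo_pred <- loo_predictions(xs, y, grid$kernel[best], grid$cost[best],
                              grid$epsilon[best], gam)

  fit <- svm_fit(xs, y, grid$kernel[best], grid$cost[best],
                 grid$epsilon[best], gam)
  structure(list(
    target = target, features = feature_names,
    center = scaler$center, scale = scaler$scale,
    kernel = grid$kernel[best], cost = grid$cost[best],
    epsilon = grid$epsilon[best], gamma = gam,
    gamma_spec = grid$gamma[best],
    sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    loo_rmse = grid$loo_rmse[best],
    loo_predictions = as.numeric(loo_pred),
    grid_results = grid, n = n, seed = as.integer(seed),
    case_ids = case_ids, version = "1.0"
  ), class = "svr_model")
}

loo_predictions <- function(xs, y, kernel, cost, epsilon, gamma) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    m <- svm_fit(xs[-i, , drop = FALSE], y[-i], kernel, cost, epsilon, gamma)
    unname(stats::predict(m, xs[i, , drop = FALSE]))
  }, numeric(1))
}

#' @export
print.svr_model <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("svr_model '%s': constant predictor (%g), n = %d\n",
                x$target, x$constant, x$n))
    return(invisible(x))
  }
  cat(sprintf("svr_model '%s': %s kernel, C = %g, epsilon = %g, gamma = %.4g\n",
              x$target, x$kernel, x$cost, x$epsilon, x$gamma))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  n = %d, LOO RMSE = %.4g, %d support vectors\n",
              x$n, x$loo_rmse, length(x$coefs)))
  invisible(x)
}

#' Predict a target for new cases
#'
#' @param object A `svr_model`.
#' @param newdata `data.frame` (or named vector for one case) containing the
#'   model's selected feature columns; a missing feature is an error.
#' @param ... Unused.
#' @return Numeric predictions in native target units (no post-processing;
#'   see [predict_plan_parameters()] for range handling).
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f))
    stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- standardize_apply(structure(list(center = object$center,
                                         scale = object$scale),
                                    class = "standardizer"), x)
  svr_raw_predict(object, xs)
}

#' Train the five plan-parameter models
#'
#' One independent epsilon-SVR per target: arc start and stop angle on the
#' angle feature set, MLD / V10 / V20 on the dose feature set (feature sets
#' from [select_features()]).
#'
#' @param train_table Training table with `case_id`, the 11 feature columns
#'   and the 5 target columns ([kbp_target_names()]).
#' @param selection Named list with `angle` and `dose` feature-name vectors.
#' @param grid Hyperparameter grid (shared across targets).
#' @param seed Base seed; target `k` uses `seed + k - 1`.
#' @return Object of class `kbp_models`: list of `svr_model` by target.
#' @export
fit_plan_models <- function(train_table, selection, grid = svr_grid(),
                            seed = 1L) {
  stopifnot(all(c("angle", "dose") %in% names(selection)))
  targets <- kbp_target_names()
  models <- list()
  for (k in seq_along(targets)) {
    tg <- targets[k]
    fs <- if (tg %in% kbp_target_names("angle")) selection$angle else selection$dose
    models[[tg]] <- fit_svr_grid_loo(train_table, train_table[[tg]],
                                     target = tg, feature_names = fs,
                                     grid = grid, seed = as.integer(seed) + k - 1L)
  }
  structure(models, class = "kbp_models", selection = selection,
            seed = as.integer(seed))
}

#' Predict all plan parameters for one case, with range post-processing
#'
#' Applies every model in a [fit_plan_models()] bundle, then enforces the
#' physical ranges: angles are reduced into `[0, 360)` modulo 360, MLD is
#' clipped at 0, V10/V20 are clipped into `[0, 100]`, and (optionally)
#' V20 is clamped to V20 <= V10 — a DVH consistency the independent
#' per-target models cannot guarantee. Every adjustment is reported via
#' `message()` and recorded in the `"adjustments"` attribute.
#'
#' @param models A `kbp_models` bundle.
#' @param features One case: `geometry_features`, named vector, or one-row
#'   `data.frame`.
#' @param clamp_v20 Enforce V20 <= V10 (default `TRUE`).
#' @return Named numeric vector over [kbp_target_names()].
#' @export
predict_plan_parameters <- function(models, features, clamp_v20 = TRUE) {
  stopifnot(inherits(models, "kbp_models"))
  if (inherits(features, "geometry_features"))
    features <- as.data.frame(as.list(unclass(features)))
  raw <- vapply(models, function(m) predict(m, features)[1], numeric(1))
  out <- raw
  adj <- character(0)
  for (a in kbp_target_names("angle")) {
    if (out[a] < 0 || out[a] >= 360) {
      out[a] <- out[a] %% 360
      adj <- c(adj, sprintf("%s wrapped to [0,360): %.2f -> %.2f", a, raw[a], out[a]))
    }
  }
  if (out["mld_gy"] < 0) {
    adj <- c(adj, sprintf("mld_gy clipped at 0 (was %.3f)", out["mld_gy"]))
    out["mld_gy"] <- 0
  }
  for (v in c("v10_pct", "v20_pct")) {
    if (out[v] < 0 || out[v] > 100) {
      new <- min(max(out[v], 0), 100)
      adj <- c(adj, sprintf("%s clipped to [0,100]: %.2f -> %.2f", v, out[v], new))
      out[v] <- new
    }
  }
  if (clamp_v20 && out["v20_pct"] > out["v10_pct"]) {
    adj <- c(adj, sprintf("v20_pct clamped to v10_pct: %.2f -> %.2f",
                          out["v20_pct"], out["v10_pct"]))
    out["v20_pct"] <- out["v10_pct"]
  }
  for (msg in adj) message("prediction post-processing: ", msg)
  structure(out, adjustments = adj)
}

# ---- RMSE + external validation --------------------------------------------

#' Root-mean-squared error, optionally circular
#'
#' With `circular = TRUE` each residual is the wrapped angular difference in
#' `(-180, 180]` degrees, so e.g. predicting 350 against 10 is a 20-degree
#' error, not 340.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @param circular Treat values as angles in degrees.
#' @return RMSE (>= 0).
#' @export
rmse <- function(predicted, actual, circular = FALSE) {
  if (length(predicted) != length(actual))
    stop("predicted and actual differ in length")
  d <- predicted - actual
  if (circular) {
    d <- (d + 180) %% 360 - 180
    d[d == -180] <- 180
  }
  sqrt(mean(d^2))
}

#' External validation of trained plan-parameter models
#'
#' Predicts every test case (without the V20 clamp, so residuals reflect the
#' raw models) and reports per-target linear RMSE, circular RMSE for the
#' angle targets, and the predicted-vs-actual pairs for scatter-style review.
#' Test case ids must be disjoint from the training ids recorded in the
#' models; an overlap is a data-leakage error.
#'
#' @param models A `kbp_models` bundle.
#' @param test_table Test table with `case_id`, feature and target columns.
#' @return Object of class `validation_report`: `summary` (`data.frame` with
#'   `target`, `rmse`, `rmse_circular`) and `pairs` (long `data.frame` with
#'   `case_id`, `target`, `actual`, `predicted`).
#' @export
run_validation <- function(models, test_table) {
  stopifnot(inherits(models, "kbp_models"))
  train_ids <- unique(unlist(lapply(models, `[[`, "case_ids")))
  overlap <- intersect(as.character(test_table$case_id), train_ids)
  if (length(overlap))
    stop("leakage: test case(s) present in training set: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  targets <- kbp_target_names()
  pairs <- do.call(rbind, lapply(targets, function(tg) {
    data.frame(case_id = as.character(test_table$case_id), target = tg,
               actual = test_table[[tg]],
               predicted = predict(models[[tg]], test_table),
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(targets, function(tg) {
    pr <- pairs[pairs$target == tg, ]
    data.frame(target = tg,
               rmse = rmse(pr$predicted, pr$actual),
               rmse_circular = if (tg %in% kbp_target_names("angle"))
                 rmse(pr$predicted, pr$actual, circular = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, pairs = pairs,
                 n_test = nrow(test_table)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("external validation on %d cases\n", x$n_test))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- Model persistence -----------------------------------------------------

#' Persist / restore trained models as versioned JSON
#'
#' Numbers are written with 17 significant digits, so a write -> read ->
#' write cycle is byte-identical and restored models predict bit-exactly.
#'
#' @param models A `kbp_models` bundle (or single `svr_model`).
#' @param path JSON file path.
#' @return `write_models()`: the path, invisibly. `read_models()`: the
#'   restored `kbp_models`.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "svr_model")) {
    models <- structure(stats::setNames(list(models), models$target),
                        class = "kbp_models", selection = NULL, seed = models$seed)
  }
  doc <- list(format = "kbplan-models", version = "1.0",
              seed = attr(models, "seed"),
              selection = attr(models, "selection"),
              models = lapply(unclass(models), serialize_svr))
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

serialize_svr <- function(m) {
  out <- unclass(m)
  if (!is.null(out$grid_results)) out$grid_results <- as.list(out$grid_results)
  if (!is.null(out$sv)) out$sv <- apply(out$sv, 1, identity, simplify = FALSE)
  if (!is.null(out$center)) { out$center_names <- names(out$center)
    out$center <- unname(out$center); out$scale <- unname(out$scale) }
  out
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "kbplan-models"))
    stop("not a kbplan model document: ", path)
  models <- lapply(doc$models, function(m) {
    if (!is.null(m$sv)) {
      m$sv <- if (is.list(m$sv)) do.call(rbind, m$sv) else as.matrix(m$sv)
      dimnames(m$sv) <- NULL
    }
    if (!is.null(m$center)) {
      m$center <- stats::setNames(m$center, m$center_names)
      m$scale <- stats::setNames(m$scale, m$center_names)
      m$center_names <- NULL
    }
    if (!is.null(m$grid_results))
      m$grid_results <- as.data.frame(m$grid_results, stringsAsFactors = FALSE)
    structure(m, class = "svr_model")
  })
  sel <- doc$selection
  if (!is.null(sel)) sel <- lapply(sel, as.character)
  structure(models, class = "kbp_models", selection = sel, seed = doc$seed)
}

#' Read / write the plan-parameter training table
#'
#' CSV dialect shared by the synthetic generator and the modeling stage:
#' `case_id`, the 11 feature columns ([kbp_feature_names()]) and, for
#' training tables, the 5 target columns ([kbp_target_names()]).
#'
#' @param path CSV path.
#' @param require_targets Error if the target columns are absent.
#' @return `data.frame`.
#' @export
read_training_table <- function(path, require_targets = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", kbp_feature_names(),
            if (require_targets) kbp_target_names())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("training table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @param tab Table to write.
#' @rdname read_training_table
#' @export
write_training_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
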