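#' Validate a pipeline run configuration
#'
#' A run configuration can be an R list or a YAML file. Recognized keys (all
#' optional except `seed`): `seed`, `alpha`, `n_train`, `n_test`,
#' `grid_shape`, `spacing`, `grid` (`"full"` or `"compact"`), `clamp_v20`,
#' `clamp_span`, `out_dir`, `verbose`. Unknown keys are rejected so typos
#' cannot silently change a run.
#'
#' @param config List or path to a YAML file.
#' @return Validated config list of class `run_config` with defaults filled.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "alpha", "n_train", "n_test", "grid_shape", "spacing",
             "grid", "clamp_v20", "clamp_span", "out_dir", "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set `seed`")
  defaults <- list(alpha = 0.05, n_train = 125L, n_test = 30L,
                   grid_shape = c(96L, 96L, 80L), spacing = c(3, 3, 3),
                   grid = "full", clamp_v20 = TRUE, clamp_span = FALSE,
                   out_dir = "kbplan-run", verbose = TRUE)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!config$grid %in% c("full", "compact"))
    stop("`grid` must be \"full\" or \"compact\"")
  structure(config, class = "run_config")
}

#' Run the full knowledge-based planning pipeline on a synthetic cohort
#'
#' End-to-end flow: generate the synthetic cohort (anatomies, features,
#' ground-truth plan parameters) -> Spearman feature selection -> SVR
#' training with grid search and LOO CV -> external validation on the held
#' out test cohort -> plan-spec assembly for every test case -> synthetic
#' dose generation and DVH evaluation of each automated plan -> paired
#' comparison against reference plans (dose grids generated with an
#' independent noise seed, standing in for the manual cohort). Every
#' artifact is written under `out_dir` together with a manifest recording
#' the configuration, package version and an MD5 checksum per file, so a
#' rerun with the same config can be verified bit-for-bit.
#'
#' @param config A [run_config()] (list, YAML path, or validated object).
#' @return Invisibly, a list with the output paths, the trained models, the
#'   validation report and the cohort comparison.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(config$verbose)) message("[kbplan] ", ...)
  paths <- list()
  out <- function(f) file.path(config$out_dir, f)

  say("stage 1/6: synthetic cohort (", config$n_train, " train + ",
      config$n_test, " test)")
  cc <- cohort_config(n_train = config$n_train, n_test = config$n_test,
                      grid_shape = config$grid_shape,
                      spacing = config$spacing, seed = config$seed)
  cohort <- generate_cohort(cc, keep_structures = TRUE)
  tab <- cohort$table
  train <- tab[tab$cohort == "train", ]
  test <- tab[tab$cohort == "test", ]
  paths$training_table <- write_training_table(train, out("training_table.csv"))
  paths$test_table <- write_training_table(test, out("test_table.csv"))

  say("stage 2/6: Spearman feature selection (alpha = ", config$alpha, ")")
  report <- spearman_correlations(train[kbp_feature_names()],
                                  train[kbp_target_names()],
                                  alpha = config$alpha)
  paths$correlations <- write_correlation_report(report, out("correlations.csv"))
  selection <- list(angle = select_features(report, "angle"),
                    dose = select_features(report, "dose"))
  say("  angle features: ", paste(selection$angle, collapse = ", "))
  say("  dose features:  ", paste(selection$dose, collapse = ", "))

  say("stage 3/6: SVR training (", config$grid, " grid, LOO CV)")
  grid <- if (config$grid == "full") svr_grid() else svr_grid_compact()
  models <- fit_plan_models(train, selection, grid = grid, seed = config$seed)
  paths$models <- write_models(models, out("models.json"))

  say("stage 4/6: external validation on ", nrow(test), " cases")
  validation <- run_validation(models, test)
  utils::write.csv(validation$summary, out("validation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(validation$pairs, out("validation_pairs.csv"),
                   row.names = FALSE)
  paths$validation <- out("validation_summary.csv")

  say("stage 5/6: plan specs + dosimetric evaluation of test cases")
  test_idx <- which(tab$cohort == "test")
  spec_dir <- out("plan_specs")
  dir.create(spec_dir, showWarnings = FALSE)
  auto_metrics <- list(); ref_metrics <- list(); checks <- list()
  for (k in seq_along(test_idx)) {
    i <- test_idx[k]
    ss <- cohort$structures[[i]]
    feats <- structure(as.numeric(tab[i, kbp_feature_names()]),
                       names = kbp_feature_names(),
                       class = "geometry_features", case_id = tab$case_id[i])
    spec <- withCallingHandlers(
      assemble_plan_spec(feats, models, clamp_span = config$clamp_span,
                         clamp_v20 = config$clamp_v20),
      warning = function(w) { say("  ", tab$case_id[i], ": ",
                                  conditionMessage(w))
        invokeRestart("muffleWarning") })
    write_plan_spec(spec, file.path(spec_dir, paste0(tab$case_id[i], ".json")))
    d_auto <- generate_dose_grid(ss, case_seed = derive_seed(cc$seed, i, 3L))
    d_ref <- generate_dose_grid(ss, case_seed = derive_seed(cc$seed, i, 4L))
    auto_metrics[[k]] <- evaluate_plan(d_auto, ss)
    ref_metrics[[k]] <- evaluate_plan(d_ref, ss)
    checks[[k]] <- check_plan_against_spec(auto_metrics[[k]], spec)
  }
  paths$plan_specs <- spec_dir
  auto_tab <- metrics_table(auto_metrics)
  ref_tab <- metrics_table(ref_metrics)
  utils::write.csv(auto_tab, out("metrics_automated.csv"), row.names = FALSE)
  utils::write.csv(ref_tab, out("metrics_reference.csv"), row.names = FALSE)
  acceptable <- vapply(checks, function(x) attr(x, "acceptable"), logical(1))
  say("  ", sum(acceptable), "/", length(acceptable),
      " automated plans meet every applicable constraint")

  say("stage 6/6: paired cohort comparison")
  comparison <- compare_plan_cohorts(ref_tab, auto_tab)
  paths$comparison <- write_comparison(comparison, out("comparison.csv"))

  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    format = "kbplan-run-manifest", version = "1.0",
    package_version = as.character(utils::packageVersion("kbplan")),
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  writeLines(jsonlite::toJSON(manifest, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), out("manifest.json"))
  paths$manifest <- out("manifest.json")
  invisible(list(paths = paths, models = models, validation = validation,
                 comparison = comparison, selection = selection,
                 acceptable = acceptable))
}
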