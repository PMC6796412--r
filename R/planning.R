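#' Default SBRT plan template
#'
#' Protocol constants kept identical for every patient: the prescription
#' (50 Gy in 5 fractions covering 95% of the PTV, maximum dose capped at
#' 150% of prescription), the arc geometry (two coplanar arcs, 4 degree
#' gantry spacing between control points, collimator and couch at 0), and
#' the clinical dose criteria: PTV Dmin > 45.5 Gy, Dmax < 70 Gy, CI > 0.8;
#' maximum-dose limits for bronchus 30 Gy, esophagus 32.5 Gy, spinal cord
#' 30 Gy, rib 54 Gy, heart 30 Gy; lung mean dose < 5 Gy, V10 < 15%,
#' V20 < 10%. Inequalities are strict: a metric exactly at its bound counts
#' as a violation.
#'
#' @return A named list (`plan_template`).
#' @export
default_plan_template <- function() {
  structure(list(
    prescription_gy = 50.0,
    fractions = 5L,
    coverage_pct = 95.0,
    max_dose_pct = 150.0,
    n_arcs = 2L,
    gantry_spacing_deg = 4.0,
    collimator_deg = 0.0,
    couch_deg = 0.0,
    span_sanity_deg = c(180.0, 300.0),
    span_clamp_deg = c(220.0, 260.0),
    constraints = data.frame(
      index = c("ptv_dmin_gy", "ptv_dmax_gy", "ptv_ci",
                "bronchus_dmax_gy", "esophagus_dmax_gy", "spinal_cord_dmax_gy",
                "rib_dmax_gy", "heart_dmax_gy",
                "lung_dmean_gy", "lung_v10_pct", "lung_v20_pct"),
      direction = c(">", "<", ">", "<", "<", "<", "<", "<", "<", "<", "<"),
      limit = c(45.5, 70.0, 0.8, 30.0, 32.5, 30.0, 54.0, 30.0,
                5.0, 15.0, 10.0),
      stringsAsFactors = FALSE
    )
  ), class = "plan_template")
}

circular_span <- function(start, stop) (stop - start) %% 360

#' Assemble an automated plan specification for one case
#'
#' Combines the per-patient predictions (arc start/stop gantry angles from
#' the angle models; MLD / V10 / V20 optimization objectives from the dose
#' models) with the invariant protocol template into a self-contained,
#' serializable plan-parameter document for a treatment planning system.
#' Both arcs share the predicted start/stop pair.
#'
#' If the predicted arc span (circular distance start -> stop) falls outside
#' the sanity window (default 180-300 degrees), a warning is raised; with
#' `clamp_span = TRUE` the span is clamped into the historical 220-260 degree
#' range by moving the stop angle.
#'
#' @param features One case's `geometry_features` (or named vector /
#'   one-row `data.frame`).
#' @param models A [fit_plan_models()] bundle covering all five targets.
#' @param template A [default_plan_template()] (or modified copy).
#' @param clamp_span Clamp out-of-window spans (default `FALSE`: warn only).
#' @param clamp_v20 Passed to [predict_plan_parameters()].
#' @return Object of class `plan_spec`.
#' @export
assemble_plan_spec <- function(features, models,
                               template = default_plan_template(),
                               clamp_span = FALSE, clamp_v20 = TRUE) {
  stopifnot(inherits(template, "plan_template"))
  pred <- predict_plan_parameters(models, features, clamp_v20 = clamp_v20)
  start <- unname(pred["start_deg"]); stop <- unname(pred["stop_deg"])
  span <- circular_span(start, stop)
  win <- template$span_sanity_deg
  notes <- attr(pred, "adjustments")
  if (span < win[1] || span > win[2]) {
    warning(sprintf("predicted arc span %.1f outside sanity window [%g, %g] deg",
                    span, win[1], win[2]))
    if (clamp_span) {
      new_span <- min(max(span, template$span_clamp_deg[1]),
                      template$span_clamp_deg[2])
      stop <- (start + new_span) %% 360
      notes <- c(notes, sprintf("arc span clamped %.2f -> %.2f deg", span, new_span))
      span <- new_span
    }
  }
  case_id <- attr(features, "case_id")
  arc <- list(start_deg = start, stop_deg = stop, span_deg = span,
              gantry_spacing_deg = template$gantry_spacing_deg,
              collimator_deg = template$collimator_deg,
              couch_deg = template$couch_deg)
  structure(list(
    format = "kbplan-plan-spec", version = "1.0",
    case_id = if (is.null(case_id)) NA_character_ else as.character(case_id),
    prescription = list(dose_gy = template$prescription_gy,
                        fractions = template$fractions,
                        coverage_pct = template$coverage_pct,
                        max_dose_pct = template$max_dose_pct),
    arcs = rep(list(arc), template$n_arcs),
    lung_objectives = list(mld_gy = unname(pred["mld_gy"]),
                           v10_pct = unname(pred["v10_pct"]),
                           v20_pct = unname(pred["v20_pct"])),
    constraints = template$constraints,
    notes = as.list(notes)
  ), class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat("plan_spec", x$case_id, "\n")
  cat(sprintf("  prescription: %g Gy / %d fx, %g%% PTV coverage, max %g%%\n",
              x$prescription$dose_gy, x$prescription$fractions,
              x$prescription$coverage_pct, x$prescription$max_dose_pct))
  a <- x$arcs[[1]]
  cat(sprintf("  %d arc(s): %.1f -> %.1f deg (span %.1f), spacing %g deg\n",
              length(x$arcs), a$start_deg, a$stop_deg, a$span_deg,
              a$gantry_spacing_deg))
  cat(sprintf("  lung objectives: MLD %.2f Gy, V10 %.1f%%, V20 %.1f%%\n",
              x$lung_objectives$mld_gy, x$lung_objectives$v10_pct,
              x$lung_objectives$v20_pct))
  cat(sprintf("  %d template constraints\n", nrow(x$constraints)))
  invisible(x)
}

#' Serialize / restore a plan specification as versioned JSON
#'
#' Numbers carry 17 significant digits; serialize -> parse -> serialize is
#' byte-identical.
#'
#' @param spec A `plan_spec`.
#' @param path JSON path.
#' @return `write_plan_spec()`: path invisibly; `read_plan_spec()`: the spec.
#' @export
write_plan_spec <- function(spec, path) {
  doc <- unclass(spec)
  doc$constraints <- as.list(doc$constraints)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_plan_spec
#' @export
read_plan_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "kbplan-plan-spec"))
    stop("not a kbplan plan spec: ", path)
  doc$constraints <- as.data.frame(doc$constraints, stringsAsFactors = FALSE)
  doc$arcs <- lapply(seq_len(nrow(doc$arcs)), function(i) as.list(doc$arcs[i, ]))
  doc$notes <- as.list(doc$notes)
  structure(doc, class = "plan_spec")
}

#' Check computed plan metrics against a plan specification
#'
#' One verdict per clinical constraint present in the metrics: strict
#' inequality against the template limit (equality at the bound is a
#' violation). Metrics that are `NA` (absent optional OAR) yield an `NA`
#' verdict and are excluded from the overall conjunction.
#'
#' @param metrics A [evaluate_plan()] result.
#' @param spec A `plan_spec` (or a `plan_template`, whose constraints are
#'   used directly).
#' @return `data.frame` with `index`, `direction`, `limit`, `value`, `pass`;
#'   overall acceptability in attribute `"acceptable"`.
#' @export
check_plan_against_spec <- function(metrics, spec) {
  cons <- if (inherits(spec, "plan_template")) spec$constraints else spec$constraints
  value <- vapply(cons$index, function(i)
    if (i %in% names(metrics)) as.numeric(metrics[[i]]) else NA_real_, numeric(1))
  pass <- ifelse(is.na(value), NA,
                 ifelse(cons$direction == "<", value < cons$limit,
                        value > cons$limit))
  out <- data.frame(index = cons$index, direction = cons$direction,
                    limit = cons$limit, value = value, pass = pass,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "acceptable") <- all(out$pass[!is.na(out$pass)])
  out
}

#' Paired comparison of two plan cohorts
#'
#' For every shared metric column computes cohort means and SDs and the
#' two-sided P of the paired Wilcoxon signed-rank test (exact distribution
#' for n <= 25 without ties or zero differences, otherwise the normal
#' approximation with continuity correction). Cases are paired by `case_id`.
#' An index whose differences are all zero is reported with P = 1 and
#' flagged degenerate.
#'
#' @param metrics_a,metrics_b Cohort tables from [metrics_table()] (columns:
#'   `case_id` + metric columns), covering the same case ids.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Object of class `comparison_result`: `data.frame` with `index`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`, `significant`,
#'   `degenerate`.
#' @export
compare_plan_cohorts <- function(metrics_a, metrics_b, alpha = 0.05) {
  if (!setequal(metrics_a$case_id, metrics_b$case_id))
    stop("cohorts must cover the same case ids")
  n <- nrow(metrics_a)
  if (n < 6) stop("need at least 6 paired cases for a meaningful test")
  metrics_b <- metrics_b[match(metrics_a$case_id, metrics_b$case_id), ]
  idx <- setdiff(intersect(names(metrics_a), names(metrics_b)), "case_id")
  rows <- lapply(idx, function(i) {
    a <- metrics_a[[i]]; b <- metrics_b[[i]]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (!length(a))
      return(data.frame(index = i, mean_a = NA_real_, sd_a = NA_real_,
                        mean_b = NA_real_, sd_b = NA_real_, p_value = NA_real_,
                        significant = NA, degenerate = NA))
    d <- b - a
    if (all(d == 0)) {
      p <- 1; degen <- TRUE
    } else {
      degen <- FALSE
      nz <- d[d != 0]
      exact <- length(nz) <= 25 && length(nz) == length(d) &&
        !any(duplicated(abs(nz)))
      p <- suppressWarnings(
        stats::wilcox.test(b, a, paired = TRUE, exact = exact,
                           correct = TRUE)$p.value)
    }
    data.frame(index = i, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b), p_value = p,
               significant = !is.na(p) && p < alpha, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), n = n, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired cohort comparison, n = %d, alpha = %g\n", x$n, x$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a cohort comparison as CSV
#'
#' @param result A `comparison_result`.
#' @param path Output path.
#' @export
write_comparison <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
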