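#' Configuration for the full dynamic-prediction pipeline
#'
#' Defaults reproduce the analysis settings the package is built around:
#' landmark grid 0 to 400 days by 5 (81 points), window 120 days, basis
#' scale 150, Efron ties, Kaplan-Meier curves for attack orders 1 to 7,
#' frailty models on.
#'
#' @param input `"synthetic"` (simulate with `sim`) or a path to a
#'   counting-process CSV in `dialect`.
#' @param sim A [sim_params()] used when `input = "synthetic"`; its seed is
#'   overridden by `seed`.
#' @param dialect A [cohort_dialect()] for file input.
#' @param grid A [landmark_grid()].
#' @param basis_scale Scale of the landmark basis functions.
#' @param km_orders Attack orders for the per-order Kaplan-Meier curves.
#' @param frailty Fit the gamma-frailty rows of the model comparison.
#' @param ties Tie method for Cox fits.
#' @param outcome Windowed outcome mode for landmark datasets.
#' @param plots Also write PNG figures.
#' @param seed Master seed for every source of randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", sim = default_params(),
                            dialect = cohort_dialect(),
                            grid = landmark_grid(), basis_scale = 150,
                            km_orders = 1:7, frailty = TRUE,
                            ties = "efron", outcome = "first_event",
                            plots = FALSE, seed = 20231130) {
  structure(list(input = input, sim = sim, dialect = dialect, grid = grid,
                 basis_scale = basis_scale, km_orders = km_orders,
                 frailty = frailty, ties = ties, outcome = outcome,
                 plots = plots, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dynamic-prediction analysis end to end
#'
#' Stages: load or simulate the cohort; attack-count table; the five-model
#' comparison (calendar/gap/first-event Cox, gamma-frailty variants);
#' per-order Kaplan-Meier step tables; the per-landmark coefficient path;
#' both landmark supermodels on the super prediction dataset; and a run
#' manifest (settings, seed, row counts, warnings) for reproducibility.
#' All numeric artifacts are written as CSV under `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, all fitted objects/tables and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note(sprintf("stage %s: %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  cohort <- stage("input", {
    if (identical(config$input, "synthetic")) {
      p <- config$sim
      p$seed <- config$seed
      simulate_cohort(p)
    } else read_cohort(config$input, dialect = config$dialect)
  })
  smry <- cohort_summary(cohort)
  tab1 <- stage("describe", attack_count_table(cohort))
  utils::write.csv(tab1, file.path(outdir, "attack_count_table.csv"),
                   row.names = FALSE)
  tab2 <- stage("models", {
    if (config$frailty) model_comparison(cohort, ties = config$ties)
    else {
      mc <- model_comparison_plain(cohort, ties = config$ties)
      mc
    }
  })
  utils::write.csv(cbind(model = rownames(tab2), tab2),
                   file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  km_tabs <- stage("km", {
    lapply(config$km_orders, function(k) {
      cv <- km_by_event_order(cohort, k)
      utils::write.csv(cv, file.path(outdir, sprintf("km_order_%d.csv", k)),
                       row.names = FALSE)
      cv
    })
  })
  path <- stage("landmark_path",
                landmark_coefficient_path(cohort, config$grid,
                                          outcome = config$outcome))
  utils::write.csv(path, file.path(outdir, "coefficient_path.csv"),
                   row.names = FALSE)
  n_skipped <- nrow(attr(path, "skipped"))
  if (n_skipped > 0) note(n_skipped, " landmark point(s) skipped")
  super <- stage("super_dataset",
                 make_super_dataset(cohort, config$grid,
                                    scale = config$basis_scale,
                                    outcome = config$outcome))
  sm1 <- stage("supermodel1", fit_supermodel_stratified(super,
                                                        ties = config$ties))
  sm2 <- stage("supermodel2", fit_supermodel_unstratified(super,
                                                          ties = config$ties))
  tab3 <- rbind(
    cbind(model = "super landmark model 1",
          factor = rownames(fit_table(sm1$fit)), fit_table(sm1$fit)),
    cbind(model = "super landmark model 2",
          factor = rownames(fit_table(sm2$fit)), fit_table(sm2$fit)))
  utils::write.csv(tab3, file.path(outdir, "supermodel_table.csv"),
                   row.names = FALSE)
  if (config$plots) {
    try({
      grDevices::png(file.path(outdir, "coefficient_path.png"),
                     width = 900, height = 450)
      plot(path)
      grDevices::dev.off()
      grDevices::png(file.path(outdir, "km_order_1.png"),
                     width = 600, height = 450)
      plot(km_tabs[[1]], main = "Time to first attack")
      grDevices::dev.off()
    }, silent = TRUE)
  }
  manifest <- list(
    package = "slidemark",
    r_version = as.character(getRversion()),
    seed = config$seed,
    input = if (identical(config$input, "synthetic")) "synthetic"
      else config$input,
    n_subjects = smry$n_subjects, n_episodes = smry$n_episodes,
    n_events = smry$n_events,
    n_medication = smry$n_medication, n_placebo = smry$n_placebo,
    grid = list(s_from = min(config$grid$s), s_to = max(config$grid$s),
                n_landmarks = length(config$grid$s),
                window = config$grid$window),
    n_landmark_datasets = length(config$grid$s),
    basis_scale = config$basis_scale,
    rows = list(attack_count_table = nrow(tab1),
                model_comparison = nrow(tab2),
                coefficient_path = nrow(path),
                super_dataset = nrow(super),
                supermodel_table = nrow(tab3)),
    notes = notes)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, attack_counts = tab1, models = tab2,
                 km = km_tabs, path = path, super = super,
                 supermodel1 = sm1, supermodel2 = sm2, table3 = tab3,
                 manifest = manifest, outdir = outdir))
}

# model comparison without the (slower) frailty rows
model_comparison_plain <- function(x, ties = "efron") {
  row_of <- function(fit) {
    b <- fit$coefficients[["treatment"]]
    s <- fit$se[["treatment"]]
    c(coef = b, `exp(coef)` = exp(b), `se(coef)` = s, z = b / s,
      p = 2 * stats::pnorm(-abs(b / s)))
  }
  m <- rbind(
    `Cox-calendar` = row_of(fit_cox(cox_frame(x, "calendar"), ties = ties)),
    `Cox-first event` = row_of(fit_cox(cox_frame(x, "first_event"),
                                       ties = ties)),
    `Cox-gap` = row_of(fit_cox(cox_frame(x, "gap"), ties = ties)))
  as.data.frame(m)
}
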