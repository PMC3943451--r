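# End-to-end orchestration: generate/load -> preprocess -> assumption
# screen -> DIF purification -> split GRM calibration -> 0-100 scores ->
# association + forest importance, with serialized, hash-manifested
# artifacts.

#' Pipeline configuration
#'
#' @param sim a [simulation_config()] describing the synthetic dataset, or
#'   `NULL` when `dataset_csv` is given.
#' @param dataset_csv optional path to an existing dataset CSV (written by
#'   [write_survey_csv()]); read with the default item bank.
#' @param ld_threshold residual-correlation threshold (default 0.2).
#' @param monotonicity_tolerance see [monotonicity_check()] (default 0.03).
#' @param dif_criterion McFadden R-squared change threshold (default 0.02).
#' @param grid_nodes,grm_tol,grm_max_cycles graded-response-model settings.
#' @param ntree,mtry,cond_threshold forest settings.
#' @param seed master seed; overrides `sim$seed` so one (config, seed) pair
#'   determines every reported number.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), dataset_csv = NULL,
                            ld_threshold = 0.2,
                            monotonicity_tolerance = 0.03,
                            dif_criterion = 0.02, grid_nodes = 61L,
                            grm_tol = 1e-3, grm_max_cycles = 200L,
                            ntree = 1000L, mtry = 2L, cond_threshold = 0.2,
                            seed = 1L) {
  if (is.null(sim) && is.null(dataset_csv))
    stop_invalid("sim", "either a simulation config or a dataset is required")
  check_number(ld_threshold, "ld_threshold", lower = 1e-12)
  check_number(monotonicity_tolerance, "monotonicity_tolerance", lower = 1e-12)
  check_number(dif_criterion, "dif_criterion", lower = 1e-12)
  check_count(grid_nodes, "grid_nodes", min = 2L)
  check_number(grm_tol, "grm_tol", lower = 1e-12)
  seed <- check_count(seed, "seed")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "simulation_config"))
    sim$seed <- seed
  }
  structure(list(sim = sim, dataset_csv = dataset_csv,
                 ld_threshold = ld_threshold,
                 monotonicity_tolerance = monotonicity_tolerance,
                 dif_criterion = dif_criterion, grid_nodes = grid_nodes,
                 grm_tol = grm_tol, grm_max_cycles = grm_max_cycles,
                 ntree = ntree, mtry = mtry, cond_threshold = cond_threshold,
                 seed = seed), class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, for both scales and both populations: data generation (or
#' loading), sensory-item removal, category collapse, eligibility filter,
#' weighted descriptives, IRT assumption screening, DIF purification,
#' group-split graded-response calibration, EAP scoring with the 0-100
#' rescale, association summaries, and random-forest conditional
#' permutation importance. Stage validation errors abort with the stage
#' name and cause.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report` with one element per stage
#'   (descriptives, assumptions, dif, grm, scores, associations,
#'   importance, provenance).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  t0 <- Sys.time()
  bank <- default_item_bank()
  data <- run_stage("generate", {
    if (!is.null(config$dataset_csv)) read_survey_csv(config$dataset_csv, bank)
    else simulate_survey(bank, config$sim)
  })
  stage_log("generate", "%d respondents", nrow(data$respondents))
  data <- run_stage("preprocess", {
    d <- drop_sensory_items(data)
    d <- collapse_categories(d)
    suppressMessages(apply_eligibility_filter(d))
  })
  stage_log("preprocess", "%d respondents retained", nrow(data$respondents))
  descr <- run_stage("descriptives", weighted_descriptives(data))

  grid <- quadrature_grid(config$grid_nodes)
  assumptions <- list()
  splits <- list()
  fits <- list()
  scores <- data.frame(id = data$respondents$id,
                       population = data$respondents$population,
                       srgh = data$respondents$srgh,
                       stringsAsFactors = FALSE)
  for (form in c("biological", "lived")) {
    rep_form <- run_stage(paste0("assumptions-", form),
      suppressMessages(check_assumptions(
        data, form, ld_threshold = config$ld_threshold,
        tolerance = config$monotonicity_tolerance)))
    assumptions[[form]] <- rep_form
    stage_log("assumptions", "%s: %d items retained, %d excluded", form,
              length(rep_form$retained), length(rep_form$excluded))
    spec <- run_stage(paste0("dif-", form), suppressWarnings(
      purify(data, form, criterion = config$dif_criterion,
             items = rep_form$retained, grid = grid, tol = config$grm_tol,
             max_cycles = config$grm_max_cycles)))
    splits[[form]] <- spec
    stage_log("dif", "%s: %d split item(s) after %d iteration(s)", form,
              length(spec$items), attr(spec, "iterations"))
    fit <- run_stage(paste0("grm-", form), suppressWarnings(
      fit_grm_em(data, form, items = rep_form$retained, split = spec,
                 grid = grid, tol = config$grm_tol,
                 max_cycles = config$grm_max_cycles)))
    fits[[form]] <- fit
    can_score <- rowSums(!is.na(
      data$responses[, fit$items, drop = FALSE])) > 0
    th <- rep(NA_real_, nrow(data$respondents))
    sub <- data
    sub$respondents <- sub$respondents[can_score, , drop = FALSE]
    sub$responses <- sub$responses[can_score, , drop = FALSE]
    th[can_score] <- eap_score(fit, sub)$theta
    sc <- rep(NA_real_, length(th))
    sc[can_score] <- rescale_scores(th[can_score])
    col <- if (form == "biological") "bhs" else "lhs"
    scores[[paste0("theta_", col)]] <- th
    scores[[col]] <- sc
    stage_log("score", "%s: %d scored, mean %.2f", form, sum(can_score),
              mean(sc, na.rm = TRUE))
  }

  assoc <- run_stage("associations", association_summary(
    scores$bhs, scores$lhs, scores$srgh, scores$population))

  importance <- list()
  complete <- !is.na(scores$bhs) & !is.na(scores$lhs)
  for (pop in sort(unique(scores$population))) {
    sel <- complete & scores$population == pop
    X <- cbind(bhs = scores$bhs[sel], lhs = scores$lhs[sel])
    y <- as.numeric(scores$srgh[sel])
    model <- run_stage(paste0("forest-", pop), fit_random_forest(
      X, y, ntree = config$ntree, mtry = config$mtry,
      seed = config$seed + 101L))
    importance[[pop]] <- list(
      oob_mse = model$oob_mse,
      unconditional = permutation_importance(model, X, y,
                                             seed = config$seed + 202L),
      conditional = conditional_permutation_importance(
        model, X, y, cond_threshold = config$cond_threshold,
        seed = config$seed + 303L))
    stage_log("importance", "%s: conditional bhs=%.4f lhs=%.4f", pop,
              importance[[pop]]$conditional$importance["bhs"],
              importance[[pop]]$conditional$importance["lhs"])
  }

  structure(list(
    descriptives = descr, assumptions = assumptions, splits = splits,
    dif_tables = lapply(splits, attr, "scan"), grm_fits = fits,
    scores = scores, associations = assoc, importance = importance,
    provenance = list(
      config = config, seed = config$seed,
      package_version = as.character(utils::packageVersion("healthscales")),
      r_version = R.version.string,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d respondents scored\n", nrow(x$scores)))
  for (pop in names(x$importance)) {
    ci <- x$importance[[pop]]$conditional$importance
    cat(sprintf("  %s: conditional importance bhs=%.4f lhs=%.4f\n",
                pop, ci["bhs"], ci["lhs"]))
  }
  invisible(x)
}

#' Write a calibration table in the published layout
#'
#' CSV with columns item, split cell, discrimination, two thresholds, plus
#' a JSON metadata block (log-likelihood, cycles, convergence).
#'
#' @param fit a `grm_fit`.
#' @param path CSV path (metadata at `paste0(path, ".json")`).
#' @return `read_grm_fit_csv()` returns the parameter table.
#' @export
write_grm_fit_csv <- function(fit, path) {
  tab <- data.frame(item = fit$params$item_id, split_in = fit$params$cell,
                    discr = fit$params$a, thr1 = fit$params$b1,
                    thr2 = fit$params$b2, stringsAsFactors = FALSE)
  write.csv(tab, path, row.names = FALSE, na = "")
  jsonlite::write_json(list(form = fit$form, loglik = fit$loglik,
                            cycles = fit$cycles, converged = fit$converged),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grm_fit_csv
#' @export
read_grm_fit_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(item_id = tab$item, cell = tab$split_in, a = tab$discr,
             b1 = tab$thr1, b2 = tab$thr2, stringsAsFactors = FALSE)
}

#' Write the pipeline report to a directory
#'
#' JSON report, CSV tables (descriptives, DIF tables, calibration tables in
#' the published layout, scores, box-plot statistics) and a plain-text log;
#' the returned manifest lists every artifact with its md5 content hash.
#' Empty report sections are rejected.
#'
#' @param report a `pipeline_report`.
#' @param directory output directory (created if needed).
#' @return data frame manifest (`file`, `md5`), invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "pipeline_report"))
  required <- c("descriptives", "assumptions", "splits", "grm_fits",
                "scores", "associations", "importance")
  for (sec in required) {
    if (is.null(report[[sec]]) || length(report[[sec]]) == 0L ||
        (is.data.frame(report[[sec]]) && nrow(report[[sec]]) == 0L))
      stop_invalid("report", sprintf("section '%s' is empty", sec))
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(rel) {
    p <- file.path(directory, rel)
    paths <<- c(paths, p)
    p
  }
  write.csv(report$descriptives, wr("descriptives.csv"), row.names = FALSE)
  for (form in names(report$grm_fits)) {
    write_grm_fit_csv(report$grm_fits[[form]],
                      wr(sprintf("grm_%s.csv", form)))
    paths <- c(paths, file.path(directory, sprintf("grm_%s.csv.json", form)))
    write_assumption_report(report$assumptions[[form]],
                            wr(sprintf("assumptions_%s.json", form)))
    write_split_spec(report$splits[[form]],
                     wr(sprintf("split_%s.json", form)))
    dt <- report$dif_tables[[form]]
    if (!is.null(dt))
      write.csv(dt, wr(sprintf("dif_%s.csv", form)), row.names = FALSE)
  }
  write.csv(report$scores, wr("scores.csv"), row.names = FALSE, na = "")
  write.csv(report$associations$correlations, wr("correlations.csv"),
            row.names = FALSE)
  write.csv(report$associations$boxplot_stats, wr("boxplot_stats.csv"),
            row.names = FALSE)
  imp <- NULL
  for (pop in names(report$importance)) {
    for (kind in c("unconditional", "conditional")) {
      v <- report$importance[[pop]][[kind]]$importance
      imp <- rbind(imp, data.frame(population = pop, kind = kind,
                                   predictor = names(v), importance = v,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(imp) <- NULL
  write.csv(imp, wr("importance.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         package_version = report$provenance$package_version,
         r_version = report$provenance$r_version,
         importance = imp,
         correlations = report$associations$correlations),
    wr("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  log_path <- wr("pipeline.log")
  # log content is a pure function of (config, seed) so manifest hashes are
  # stable across reruns; timings go to stderr only
  writeLines(c(sprintf("seed: %d", report$provenance$seed),
               sprintf("respondents scored: %d", nrow(report$scores))),
             log_path)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(directory, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}
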