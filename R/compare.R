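#' Run the four-strategy comparison on a study
#'
#' For every run: extract inhalation events, build the design matrix of each
#' requested strategy, fit the GLM and form the strategy's contrast estimate.
#' Run-level estimates are averaged into subject maps (fixed effects), subject
#' maps into group one-sample t/z maps with FDR thresholding and Hedge's g
#' maps, and the g maps into a winner map. Design efficiencies are summarized
#' per run, subject and study, and block-wise amplitude (habituation)
#' profiles are averaged across runs and subjects. A failed run is recorded
#' and skipped; it does not abort the study.
#'
#' @param study A [generate_study()] result carrying BOLD runs.
#' @param config An [analysis_config()].
#' @return An object of class `sniff_comparison`: a list with `group`
#'   (per-strategy t/z maps and FDR results), `g_maps`, `winner` (when all
#'   four strategies were run), `efficiency` (an `efficiency_study`),
#'   `habituation` (strategy x block matrix of mean amplitudes), `summary`
#'   (plain named list, JSON-ready) and `failures`.
#' @export
run_comparison <- function(study, config = analysis_config()) {
  stopifnot(inherits(study, "sniff_study"), inherits(config, "analysis_config"))
  strategies <- config$strategies
  subject_maps <- setNames(vector("list", length(strategies)), strategies)
  hab_acc <- setNames(vector("list", length(strategies)), strategies)
  failures <- list()
  for (s in seq_along(study$subjects)) {
    run_maps <- setNames(vector("list", length(strategies)), strategies)
    for (r in seq_along(study$subjects[[s]]$runs)) {
      run <- study$subjects[[s]]$runs[[r]]
      if (is.null(run$bold)) stop("study carries no BOLD data; regenerate with bold params")
      res <- tryCatch({
        ev <- respiratory_events(run$trace, config$schedule,
                                 config$normalization, config$peaks)
        out <- list()
        for (strat in strategies) {
          X <- switch(strat,
            SBD1 = build_block_regressors(config$schedule, config$hrf,
                                          config$tr, config$n_volumes, FALSE),
            SBD2 = build_block_regressors(config$schedule, config$hrf,
                                          config$tr, config$n_volumes, TRUE),
            MBD1 = build_event_regressors(ev, config$hrf, config$tr,
                                          config$n_volumes, FALSE),
            MBD2 = build_event_regressors(ev, config$hrf, config$tr,
                                          config$n_volumes, TRUE))
          fit <- fit_glm(run$bold$run, X)
          out[[strat]] <- list(
            estimate = contrast_stats(fit, strat)$estimate,
            habituation = colMeans(blockwise_amplitudes(
              run$bold$run, config$schedule, ev, strat, config$hrf,
              config$tr), na.rm = TRUE))
        }
        out
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- list(
          subject = s, run = r, message = conditionMessage(res))
        next
      }
      for (strat in strategies) {
        run_maps[[strat]] <- c(run_maps[[strat]], list(res[[strat]]$estimate))
        hab_acc[[strat]] <- rbind(hab_acc[[strat]], res[[strat]]$habituation)
      }
    }
    for (strat in strategies) {
      if (length(run_maps[[strat]]) > 0L) {
        subject_maps[[strat]] <- c(
          subject_maps[[strat]],
          list(second_level_subject(run_maps[[strat]])))
      }
    }
  }
  group <- list()
  g_maps <- list()
  for (strat in strategies) {
    gl <- group_level(subject_maps[[strat]])
    group[[strat]] <- c(gl, list(fdr = fdr_threshold(gl$z, config$q)))
    g_maps[[strat]] <- hedges_g_map(subject_maps[[strat]])
  }
  winner <- if (setequal(strategies, c("SBD1", "SBD2", "MBD1", "MBD2"))) {
    winner_map(g_maps, config$g_threshold)
  } else NULL
  eff <- efficiency_study(
    lapply(study$subjects, function(su) lapply(su$runs, `[[`, "trace")),
    config$schedule, config$hrf, config$tr, config$n_volumes,
    config$normalization, config$peaks, on_error = "skip")
  habituation <- do.call(rbind, lapply(hab_acc[strategies], colMeans,
                                       na.rm = TRUE))
  rownames(habituation) <- strategies
  summary_list <- list(
    n_subjects = length(study$subjects),
    strategies = strategies,
    efficiency = c(as.list(eff$sbd),
                   setNames(as.list(eff$grand$mean), eff$grand$design)),
    mean_abs_group_t = vapply(
      group, function(g) mean(abs(g$t$values), na.rm = TRUE), numeric(1)),
    fdr_rejections = vapply(group, function(g) g$fdr$n_rejected, integer(1)),
    winner_counts = if (is.null(winner)) NULL else
      as.list(table(as.character(winner))),
    habituation = apply(habituation, 1, as.list),
    n_failures = length(failures))
  structure(list(group = group, g_maps = g_maps, winner = winner,
                 efficiency = eff, habituation = habituation,
                 subject_maps = subject_maps, summary = summary_list,
                 failures = failures),
            class = "sniff_comparison")
}

#' @export
print.sniff_comparison <- function(x, ...) {
  cat("<sniff_comparison>\n")
  eff <- x$summary$efficiency
  cat("  efficiency:",
      paste(sprintf("%s = %.3f", names(eff), unlist(eff)), collapse = ", "),
      "\n")
  cat("  mean |t| (group):",
      paste(sprintf("%s = %.3f", names(x$summary$mean_abs_group_t),
                    x$summary$mean_abs_group_t), collapse = ", "), "\n")
  if (x$summary$n_failures > 0) {
    cat(sprintf("  %d run(s) failed and were skipped\n", x$summary$n_failures))
  }
  invisible(x)
}

#' Write a comparison summary as JSON
#'
#' @param comparison A [run_comparison()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(comparison, path) {
  stopifnot(inherits(comparison, "sniff_comparison"))
  jsonlite::write_json(comparison$summary, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
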