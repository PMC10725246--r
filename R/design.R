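#' Design matrix on the volume grid
#'
#' @param times Volume onset times in seconds (length `n_volumes`).
#' @param values Numeric matrix, `n_volumes` rows, with unique column names;
#'   must contain a `constant` column of ones.
#' @param label Analysis strategy label (e.g. `"SBD1"`).
#' @return An object of class `sniff_design`.
#' @export
design_matrix <- function(times, values, label = NA_character_) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) stop("times must match design rows")
  cn <- colnames(values)
  if (is.null(cn) || anyDuplicated(cn)) stop("design columns must have unique names")
  if (!"constant" %in% cn) stop("design must contain a constant column")
  if (any(values[, "constant"] != 1)) stop("constant column must be all ones")
  structure(list(times = as.numeric(times), values = values, label = label),
            class = "sniff_design")
}

#' @export
print.sniff_design <- function(x, ...) {
  cat(sprintf("<sniff_design> %s: %d volumes x %d columns (%s)\n",
              ifelse(is.na(x$label), "unlabelled", x$label),
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.sniff_design <- function(x, ...) x$values

# Causal linear convolution truncated to the length of the input signal
# (direct filtering, so exact zeros stay exact).
.convolve_trunc <- function(signal, kernel) {
  k <- length(kernel)
  n <- length(signal)
  padded <- c(rep(0, k - 1), signal)
  as.numeric(stats::filter(padded, kernel, method = "convolution",
                           sides = 1))[k:(k + n - 1)]
}

# Boxcar on the 1 Hz grid t = 0, 1, ..., duration-1 from half-open intervals.
.boxcar_1hz <- function(intervals, duration) {
  x <- numeric(duration)
  t <- seq_len(duration) - 1
  for (i in seq_len(nrow(intervals))) {
    x[t >= intervals$start[i] & t < intervals$end[i]] <- 1
  }
  x
}

# Convolve a 1 Hz neural signal with the HRF and sample at volume onsets.
.predictor_at_volumes <- function(neural_1hz, model, tr, n_volumes) {
  kernel <- hrf_sample(model, rate = 1)
  conv <- .convolve_trunc(neural_1hz, kernel)
  vt <- (seq_len(n_volumes) - 1) * tr
  approx(x = seq_along(conv) - 1, y = conv, xout = vt, rule = 2)$y
}

#' Standard block-design regressors (SBD1/SBD2)
#'
#' Builds unit-height boxcars for the stimulation phases on a 1 Hz grid,
#' convolves them with the hemodynamic kernel and samples the result at the
#' volume onsets `t = 0, tr, ..., (n_volumes - 1) * tr`. With
#' `include_air = FALSE` the design holds the odorant predictor plus constant
#' (SBD1); with `include_air = TRUE` it holds air and odorant predictors plus
#' constant (SBD2). Boxcars are half-open: the sample at a block's end time is
#' off.
#'
#' @param schedule A [block_schedule()].
#' @param model An [hrf_model()].
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param include_air Include the odorless-air predictor?
#' @return A [design_matrix()].
#' @export
build_block_regressors <- function(schedule, model = hrf_model(), tr = 2,
                                   n_volumes = 104, include_air = FALSE) {
  stopifnot(inherits(schedule, "block_schedule"), tr > 0, n_volumes >= 2)
  if (n_volumes * tr > schedule$run_duration + tr + 1e-9) {
    stop("n_volumes * tr exceeds the scheduled run duration")
  }
  dur <- ceiling(schedule$run_duration)
  ph <- schedule_phases(schedule)
  odor <- .predictor_at_volumes(
    .boxcar_1hz(ph[ph$phase == "odorant", ], dur), model, tr, n_volumes)
  vt <- (seq_len(n_volumes) - 1) * tr
  if (include_air) {
    air <- .predictor_at_volumes(
      .boxcar_1hz(ph[ph$phase == "air", ], dur), model, tr, n_volumes)
    design_matrix(vt, cbind(air = air, odorant = odor, constant = 1), "SBD2")
  } else {
    design_matrix(vt, cbind(odorant = odor, constant = 1), "SBD1")
  }
}

#' Inhalation-modulated block-design regressors (MBD1/MBD2)
#'
#' Builds unit-height mini-boxcars on a 1 Hz grid for the labelled inhalation
#' events (half-open `[onset, onset + duration)` windows), convolves with the
#' hemodynamic kernel and samples at volume onsets. `include_air = FALSE`
#' yields the single i_odorant predictor plus constant (MBD1);
#' `include_air = TRUE` yields i_air and i_odorant predictors plus constant
#' (MBD2). Unassigned events enter neither predictor.
#'
#' @param events Labelled events from [assign_events()].
#' @param model An [hrf_model()].
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param include_air Include the i_air predictor?
#' @return A [design_matrix()].
#' @export
build_event_regressors <- function(events, model = hrf_model(), tr = 2,
                                   n_volumes = 104, include_air = FALSE) {
  stopifnot(inherits(events, "inhalation_events"), tr > 0, n_volumes >= 2)
  dur <- ceiling(n_volumes * tr)
  ev_boxcar <- function(cond) {
    sel <- events[events$condition == cond, , drop = FALSE]
    if (nrow(sel) == 0L) return(numeric(dur))
    .boxcar_1hz(data.frame(start = sel$onset, end = sel$onset + sel$duration), dur)
  }
  odor_neural <- ev_boxcar("i_odorant")
  if (all(odor_neural == 0)) {
    stop("degenerate design: no i_odorant events in this run")
  }
  odor <- .predictor_at_volumes(odor_neural, model, tr, n_volumes)
  vt <- (seq_len(n_volumes) - 1) * tr
  if (include_air) {
    air <- .predictor_at_volumes(ev_boxcar("i_air"), model, tr, n_volumes)
    design_matrix(vt, cbind(i_air = air, i_odorant = odor, constant = 1), "MBD2")
  } else {
    design_matrix(vt, cbind(i_odorant = odor, constant = 1), "MBD1")
  }
}

#' Named contrast presets for the four analysis strategies
#'
#' @param label One of `"SBD1"`, `"SBD2"`, `"MBD1"`, `"MBD2"`.
#' @return A named contrast vector keyed by predictor name.
#' @export
contrast_preset <- function(label) {
  switch(label,
         SBD1 = c(odorant = 1),
         SBD2 = c(air = -1, odorant = 1),
         MBD1 = c(i_odorant = 1),
         MBD2 = c(i_air = -1, i_odorant = 1),
         stop("unknown strategy label: ", label))
}

# Resolve a contrast (named vector or preset label) against design columns.
# Names absent from the contrast get weight 0; unknown names are an error.
.resolve_contrast <- function(contrast, columns) {
  if (is.character(contrast) && length(contrast) == 1L) {
    contrast <- contrast_preset(contrast)
  }
  if (is.null(names(contrast)) || any(names(contrast) == "")) {
    stop("contrasts must be keyed by predictor name")
  }
  unknown <- setdiff(names(contrast), columns)
  if (length(unknown)) stop("contrast names not in design: ",
                            paste(unknown, collapse = ", "))
  out <- setNames(numeric(length(columns)), columns)
  out[names(contrast)] <- contrast
  out
}

#' Design efficiency of a contrast
#'
#' Computes `1 / (c (X^T X)^{-1} c^T)` on the task predictors of the design.
#' The constant column is treated as a nuisance term and excluded from the
#' efficiency computation (it always remains part of the design used for
#' model fitting); the contrast is keyed by predictor name, so the result is
#' invariant to column reordering.
#'
#' @param X A [design_matrix()].
#' @param contrast Named contrast vector, or a preset label for
#'   [contrast_preset()].
#' @return An object of class `efficiency_result` with elements `value`,
#'   `design_label`, `subject_id`, `run_id`.
#' @export
efficiency <- function(X, contrast) {
  stopifnot(inherits(X, "sniff_design"))
  task <- setdiff(colnames(X$values), "constant")
  if (length(task) == 0L) stop("design has no task predictors")
  cvec <- .resolve_contrast(contrast, colnames(X$values))
  if (any(cvec[setdiff(names(cvec), task)] != 0)) {
    stop("contrast puts weight on the constant term")
  }
  cvec <- cvec[task]
  M <- crossprod(X$values[, task, drop = FALSE])
  if (rcond(M) < 1e-12) {
    stop("rank-deficient design: X^T X is singular or near-singular")
  }
  val <- drop(1 / (cvec %*% solve(M, cvec)))
  structure(list(value = val, design_label = X$label,
                 subject_id = NA_character_, run_id = NA_character_),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency> %s: %.4f\n",
              ifelse(is.na(x$design_label), "design", x$design_label), x$value))
  invisible(x)
}

#' Design-efficiency study over simulated or recorded breathing
#'
#' Runs the respiratory pipeline on every trace, builds the MBD1/MBD2 designs
#' per run and evaluates their efficiency; averages run values within subject
#' and summarizes across subjects. The standard block designs depend only on
#' the schedule, so SBD1/SBD2 are evaluated once and reported alongside.
#'
#' @param traces List of subjects, each a list of [resp_trace()] runs (or a
#'   `sniff_study` from [generate_study()]).
#' @param schedule A [block_schedule()].
#' @param model An [hrf_model()].
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param norm A [norm_params()].
#' @param peaks A [peak_params()].
#' @param on_error `"stop"` propagates a failing run (the default);
#'   `"skip"` drops it from the averages and records it in `failures`.
#' @return An object of class `efficiency_study` with elements `runs`
#'   (per-run values), `subject_means`, `grand` (per-design mean and sd across
#'   subjects), `sbd` (the two block-design values) and `failures`.
#' @export
efficiency_study <- function(traces, schedule = block_schedule(),
                             model = hrf_model(), tr = 2, n_volumes = 104,
                             norm = norm_params(), peaks = peak_params(),
                             on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (inherits(traces, "sniff_study")) {
    traces <- lapply(traces$subjects, function(s) lapply(s$runs, `[[`, "trace"))
  }
  stopifnot(length(traces) >= 1L)
  rows <- list()
  failures <- list()
  for (s in seq_along(traces)) {
    stopifnot(length(traces[[s]]) >= 1L)
    for (r in seq_along(traces[[s]])) {
      row <- tryCatch({
        ev <- respiratory_events(traces[[s]][[r]], schedule, norm, peaks)
        X1 <- build_event_regressors(ev, model, tr, n_volumes,
                                     include_air = FALSE)
        X2 <- build_event_regressors(ev, model, tr, n_volumes,
                                     include_air = TRUE)
        data.frame(subject = s, run = r, design = c("MBD1", "MBD2"),
                   value = c(efficiency(X1, "MBD1")$value,
                             efficiency(X2, "MBD2")$value))
      }, error = function(e) e)
      if (inherits(row, "error")) {
        if (on_error == "stop") stop(row)
        failures[[length(failures) + 1L]] <- list(
          subject = s, run = r, message = conditionMessage(row))
        next
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no run yielded a valid event design")
  runs <- do.call(rbind, rows)
  subject_means <- aggregate(value ~ subject + design, data = runs, FUN = mean)
  grand <- aggregate(value ~ design, data = subject_means,
                     FUN = function(v) c(mean = mean(v), sd = sd(v)))
  grand <- data.frame(design = grand$design,
                      mean = grand$value[, "mean"], sd = grand$value[, "sd"])
  sbd1 <- efficiency(build_block_regressors(schedule, model, tr, n_volumes,
                                            include_air = FALSE), "SBD1")$value
  sbd2 <- efficiency(build_block_regressors(schedule, model, tr, n_volumes,
                                            include_air = TRUE), "SBD2")$value
  structure(list(runs = runs, subject_means = subject_means, grand = grand,
                 sbd = c(SBD1 = sbd1, SBD2 = sbd2), failures = failures),
            class = "efficiency_study")
}

#' @export
print.efficiency_study <- function(x, ...) {
  cat("<efficiency_study>\n")
  cat(sprintf("  SBD1 = %.3f, SBD2 = %.3f (schedule-determined)\n",
              x$sbd["SBD1"], x$sbd["SBD2"]))
  for (i in seq_len(nrow(x$grand))) {
    cat(sprintf("  %s grand mean = %.3f (sd %.3f across %d subjects)\n",
                x$grand$design[i], x$grand$mean[i], x$grand$sd[i],
                length(unique(x$subject_means$subject))))
  }
  invisible(x)
}
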