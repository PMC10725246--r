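#' Breathing simulation parameters
#'
#' The generator emulates resting nasal breathing during scanning: cycles of
#' a raised-cosine inhalation bump around a zero baseline (the belt signal is
#' AC-coupled) whose lengths jitter around the subject's mean rate (lognormal
#' cycle lengths with a given coefficient of variation),
#' a piecewise-constant multiplicative gain with Poisson-timed jumps emulating
#' the belt hardware recalibrating itself mid-run, and additive Gaussian
#' sensor noise scaled to the current gain.
#'
#' @param rate_mean Mean inhalation rate, inhalations per minute.
#' @param rate_sd_between Between-subject SD of the rate (per minute).
#' @param cycle_jitter_cv Within-subject coefficient of variation of cycle
#'   lengths.
#' @param recalib_prob_per_min Expected number of gain jumps per minute.
#' @param recalib_scale_range Range of the multiplicative gain after a jump
#'   (sampled log-uniformly).
#' @param noise_sd Additive noise SD as a fraction of the breath amplitude.
#' @param sampling_rate Output sampling rate in Hz.
#' @return An object of class `breathing_params`.
#' @export
breathing_params <- function(rate_mean = 14.5, rate_sd_between = 3.1,
                             cycle_jitter_cv = 0.15,
                             recalib_prob_per_min = 0.3,
                             recalib_scale_range = c(0.2, 5),
                             noise_sd = 0.05, sampling_rate = 400) {
  stopifnot(rate_mean > 0, rate_sd_between >= 0, cycle_jitter_cv >= 0,
            recalib_prob_per_min >= 0, length(recalib_scale_range) == 2L,
            all(recalib_scale_range > 0), noise_sd >= 0, sampling_rate > 0)
  structure(list(rate_mean = rate_mean, rate_sd_between = rate_sd_between,
                 cycle_jitter_cv = cycle_jitter_cv,
                 recalib_prob_per_min = recalib_prob_per_min,
                 recalib_scale_range = recalib_scale_range,
                 noise_sd = noise_sd, sampling_rate = sampling_rate),
            class = "breathing_params")
}

#' BOLD simulation parameters
#'
#' Ground-truth neural activity is either inhalation-locked (short bursts at
#' the labelled inhalation events, the odorant bursts attenuated block by
#' block by the habituation profile) or a sustained boxcar over each block.
#' The neural signal is convolved with the hemodynamic kernel, sampled at the
#' TR, and corrupted with AR(1) Gaussian noise; null voxels carry noise only.
#'
#' @param amp_odorant Response amplitude per odorant inhalation (signal units).
#' @param amp_air Response amplitude per odorless inhalation.
#' @param habituation Per-odorant-block multipliers in (0, 1].
#' @param neural_mode `"inhalation_locked"` or `"sustained_boxcar"`.
#' @param noise_sd Marginal SD of the AR(1) noise (signal units).
#' @param ar1 Lag-1 autocorrelation of the noise, in [0, 1).
#' @param n_voxels_active,n_voxels_null Voxel counts.
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes.
#' @return An object of class `bold_params`.
#' @export
bold_params <- function(amp_odorant = 1, amp_air = 0.3,
                        habituation = c(1, 0.8, 0.6, 0.5, 0.4, 0.3),
                        neural_mode = c("inhalation_locked", "sustained_boxcar"),
                        noise_sd = 0.5, ar1 = 0.3,
                        n_voxels_active = 20, n_voxels_null = 20,
                        tr = 2, n_volumes = 104) {
  neural_mode <- match.arg(neural_mode)
  stopifnot(all(habituation > 0), all(habituation <= 1),
            noise_sd >= 0, ar1 >= 0, ar1 < 1,
            n_voxels_active >= 0, n_voxels_null >= 0, tr > 0, n_volumes >= 2)
  structure(list(amp_odorant = amp_odorant, amp_air = amp_air,
                 habituation = habituation, neural_mode = neural_mode,
                 noise_sd = noise_sd, ar1 = ar1,
                 n_voxels_active = as.integer(n_voxels_active),
                 n_voxels_null = as.integer(n_voxels_null),
                 tr = tr, n_volumes = as.integer(n_volumes)),
            class = "bold_params")
}

#' Simulate a respiratory belt trace
#'
#' Cycle lengths are lognormal with mean `60 / rate` seconds and coefficient
#' of variation `cycle_jitter_cv` (degenerate at the mean when the CV is 0);
#' each cycle is a raised-cosine bump peaking mid-cycle; gain jumps arrive as
#' a Poisson process and draw a new log-uniform gain; Gaussian noise is added
#' in proportion to the current gain. The first cycle starts at t = 0.
#'
#' @param duration Trace duration in seconds.
#' @param params A [breathing_params()]; `rate` overrides `rate_mean` for a
#'   single subject's trace.
#' @param rate Inhalation rate for this trace (per minute); defaults to
#'   `params$rate_mean`.
#' @param seed Optional integer seed.
#' @return A [resp_trace()] with attribute `ground_truth`, a list holding the
#'   true inhalation `peak_times` within the run.
#' @export
simulate_breathing <- function(duration, params = breathing_params(),
                               rate = params$rate_mean, seed = NULL) {
  stopifnot(inherits(params, "breathing_params"), duration > 0, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  fs <- params$sampling_rate
  mu <- 60 / rate
  cv <- params$cycle_jitter_cv
  # draw cycle lengths covering the run
  lens <- numeric(0)
  total <- 0
  while (total < duration) {
    L <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(1, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    } else mu
    lens <- c(lens, L)
    total <- total + L
  }
  starts <- cumsum(c(0, lens[-length(lens)]))
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (i in seq_along(lens)) {
    lo <- starts[i]
    hi <- min(lo + lens[i], duration)
    idx <- which(t >= lo & t < hi)
    # raised cosine around a zero baseline (belt signals are AC-coupled):
    # -0.5 at the cycle edges, +0.5 at the mid-cycle inhalation peak
    x[idx] <- -cos(2 * pi * (t[idx] - lo) / lens[i]) / 2
  }
  # piecewise-constant gain with Poisson-timed recalibration jumps
  gain <- rep(1, n)
  n_jumps <- rpois(1, params$recalib_prob_per_min * duration / 60)
  if (n_jumps > 0) {
    jump_t <- sort(runif(n_jumps, 0, duration))
    jump_g <- exp(runif(n_jumps, log(params$recalib_scale_range[1]),
                        log(params$recalib_scale_range[2])))
    seg <- findInterval(t, jump_t)
    gain <- c(1, jump_g)[seg + 1]
  }
  x <- x * gain
  if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd) * gain
  peaks <- starts + lens / 2
  out <- resp_trace(x, fs)
  attr(out, "ground_truth") <- list(peak_times = peaks[peaks < duration],
                                    cycle_starts = starts, rate = rate)
  out
}

# 1 Hz neural time course implied by labelled events / schedule and the
# ground-truth amplitudes. Overlapping event windows take the larger value.
.neural_signal <- function(events, schedule, params, duration) {
  x <- numeric(duration)
  t <- seq_len(duration) - 1
  ph <- schedule_phases(schedule)
  odor_ph <- ph[ph$phase == "odorant", , drop = FALSE]
  hab <- rep_len(params$habituation, nrow(odor_ph))
  if (params$neural_mode == "sustained_boxcar") {
    for (k in seq_len(nrow(odor_ph))) {
      sel <- t >= odor_ph$start[k] & t < odor_ph$end[k]
      x[sel] <- pmax(x[sel], params$amp_odorant * hab[k])
    }
    for (k in which(ph$phase == "air")) {
      sel <- t >= ph$start[k] & t < ph$end[k]
      x[sel] <- pmax(x[sel], params$amp_air)
    }
  } else {
    for (i in seq_len(nrow(events))) {
      cond <- as.character(events$condition[i])
      if (cond == "unassigned") next
      amp <- if (cond == "i_air") params$amp_air else {
        k <- which(events$onset[i] >= odor_ph$start &
                     events$onset[i] + events$duration[i] <= odor_ph$end)
        params$amp_odorant * hab[k[1]]
      }
      sel <- t >= events$onset[i] & t < events$onset[i] + events$duration[i]
      x[sel] <- pmax(x[sel], amp)
    }
  }
  x
}

# Stationary AR(1) noise with marginal sd `sd` (50-sample burn-in).
.ar1_noise <- function(n, sd, ar1) {
  if (sd == 0) return(numeric(n))
  burn <- 50L
  innov <- rnorm(n + burn, 0, sd * sqrt(1 - ar1^2))
  e <- as.numeric(stats::filter(innov, ar1, method = "recursive"))
  e[(burn + 1):(burn + n)]
}

#' Simulate an inhalation-locked BOLD run
#'
#' @param events Labelled events (from [assign_events()] or ground truth), or
#'   a raw [resp_trace()] that is passed through the default respiratory
#'   pipeline first.
#' @param schedule A [block_schedule()].
#' @param model An [hrf_model()].
#' @param params A [bold_params()].
#' @param seed Optional integer seed.
#' @return List with `run` (a [bold_run()]), `signal` (the noiseless active
#'   time course at the TR grid), `events`, `active` (active voxel indices)
#'   and `truth` (the amplitude parameters used).
#' @export
simulate_bold <- function(events, schedule = block_schedule(),
                          model = hrf_model(), params = bold_params(),
                          seed = NULL) {
  stopifnot(inherits(params, "bold_params"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(events, "resp_trace")) {
    events <- respiratory_events(events, schedule)
  }
  if (params$neural_mode == "inhalation_locked" &&
      !any(events$condition == "i_odorant")) {
    stop("no i_odorant events: cannot simulate inhalation-locked activity")
  }
  duration <- ceiling(params$n_volumes * params$tr)
  neural <- .neural_signal(events, schedule, params, duration)
  signal <- .predictor_at_volumes(neural, model, params$tr, params$n_volumes)
  n_vox <- params$n_voxels_active + params$n_voxels_null
  Y <- matrix(0, n_vox, params$n_volumes)
  for (v in seq_len(n_vox)) {
    Y[v, ] <- .ar1_noise(params$n_volumes, params$noise_sd, params$ar1)
  }
  active <- seq_len(params$n_voxels_active)
  Y[active, ] <- sweep(Y[active, , drop = FALSE], 2, signal, `+`)
  list(run = bold_run(Y, tr = params$tr),
       signal = signal, events = events, active = active,
       truth = list(amp_odorant = params$amp_odorant,
                    amp_air = params$amp_air,
                    habituation = params$habituation,
                    neural_mode = params$neural_mode))
}

#' Generate a synthetic multi-subject study
#'
#' Per-subject inhalation rates are drawn from a truncated normal
#' (`rate_mean`, `rate_sd_between`, truncated above 5 per minute); each run
#' gets an independent breathing trace, and (unless `bold = NULL`) a BOLD run
#' simulated from the events extracted by the default respiratory pipeline.
#' All randomness descends from the master seed, so regenerating from the
#' manifest reproduces the study exactly.
#'
#' @param n_subjects,n_runs Study dimensions.
#' @param duration Run duration in seconds.
#' @param breathing A [breathing_params()].
#' @param bold A [bold_params()], or `NULL` to generate breathing only.
#' @param seed Master seed (integer).
#' @param schedule A [block_schedule()].
#' @param model An [hrf_model()].
#' @return An object of class `sniff_study`: `subjects` (each with `rate` and
#'   `runs`, each run holding `trace` and optionally `bold`) plus a `manifest`
#'   of every parameter and derived seed.
#' @export
generate_study <- function(n_subjects = 33, n_runs = 12, duration = 208,
                           breathing = breathing_params(), bold = bold_params(),
                           seed = 1, schedule = block_schedule(),
                           model = hrf_model()) {
  stopifnot(n_subjects >= 1, n_runs >= 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  rates <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    repeat {
      r <- rnorm(1, breathing$rate_mean, breathing$rate_sd_between)
      if (r > 5) break
    }
    rates[s] <- r
  }
  run_seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_subjects * n_runs),
                      nrow = n_subjects * n_runs)
  manifest <- list(n_subjects = n_subjects, n_runs = n_runs,
                   duration = duration, seed = seed,
                   breathing = unclass(breathing),
                   bold = if (is.null(bold)) NULL else unclass(bold),
                   subject_rates = rates, run_seeds = run_seeds)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      idx <- (s - 1) * n_runs + r
      trace <- simulate_breathing(duration, breathing, rate = rates[s],
                                  seed = run_seeds[idx, 1])
      trace$subject_id <- sprintf("sub-%02d", s)
      trace$run_id <- sprintf("run-%02d", r)
      run <- list(trace = trace)
      if (!is.null(bold)) {
        sim <- simulate_bold(trace, schedule, model, bold,
                             seed = run_seeds[idx, 2])
        sim$run$subject_id <- trace$subject_id
        sim$run$run_id <- trace$run_id
        run$bold <- sim
      }
      runs[[r]] <- run
    }
    subjects[[s]] <- list(rate = rates[s], runs = runs)
  }
  structure(list(subjects = subjects, manifest = manifest),
            class = "sniff_study")
}

#' Regenerate a study from its manifest
#'
#' @param manifest The `manifest` element of a [generate_study()] result.
#' @return The identical `sniff_study`.
#' @export
regenerate_study <- function(manifest) {
  generate_study(
    n_subjects = manifest$n_subjects, n_runs = manifest$n_runs,
    duration = manifest$duration,
    breathing = do.call(breathing_params, manifest$breathing),
    bold = if (is.null(manifest$bold)) NULL else do.call(bold_params, manifest$bold),
    seed = manifest$seed)
}

#' @export
print.sniff_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<sniff_study> %d subjects x %d runs of %g s (seed %d)%s\n",
              m$n_subjects, m$n_runs, m$duration, m$seed,
              if (is.null(m$bold)) ", breathing only" else ""))
  invisible(x)
}
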