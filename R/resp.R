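#' Respiratory belt trace
#'
#' A uniformly sampled respiratory amplitude series with its sampling rate and
#' an optional time origin relative to the start of the functional run.
#'
#' @param samples Numeric vector of belt amplitudes (arbitrary units). Must be
#'   finite and of length at least 2.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param t0 Time of the first sample in seconds relative to run start.
#' @param subject_id,run_id Optional identifiers carried through the pipeline.
#'
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(samples, sampling_rate, t0 = 0,
                       subject_id = NA_character_, run_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a respiratory trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("respiratory samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0), subject_id = subject_id, run_id = run_id),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<resp_trace> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate, dur, x$t0))
  invisible(x)
}

#' Sample times of a respiratory trace
#'
#' @param trace A [resp_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Respiratory normalization parameters
#'
#' Parameters of the amplitude-normalization stage that turns a raw belt trace
#' into a range-limited signal with clearly identifiable peaks: median filter
#' window, downsampling target rate, and the iterated root transform
#' `y / |y|^(1/p)` that boosts small amplitudes and attenuates large ones
#' (robust against the belt hardware recalibrating itself mid-run).
#'
#' @param p Root exponent of the iterated transform (> 1).
#' @param n_iterations Number of iterations of the transform (>= 1).
#' @param median_window_s Median-filter window in seconds.
#' @param target_rate Rate (Hz) to which the trace is downsampled.
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(p = 2, n_iterations = 4, median_window_s = 0.1,
                        target_rate = 1) {
  stopifnot(p > 1, n_iterations >= 1, median_window_s > 0, target_rate > 0)
  structure(list(p = p, n_iterations = as.integer(n_iterations),
                 median_window_s = median_window_s, target_rate = target_rate),
            class = "norm_params")
}

#' Peak-detection and event parameters
#'
#' @param prominence Minimum topographic prominence of a retained peak, in
#'   normalized amplitude units.
#' @param min_separation_s Minimum separation between retained peaks (s).
#' @param event_duration_s Duration of the inhalation window preceding each
#'   peak (s).
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(prominence = 0.75, min_separation_s = 2,
                        event_duration_s = 2) {
  stopifnot(prominence > 0, min_separation_s > 0, event_duration_s > 0)
  structure(list(prominence = prominence, min_separation_s = min_separation_s,
                 event_duration_s = event_duration_s),
            class = "peak_params")
}

#' Median-filter a respiratory trace
#'
#' Centered one-dimensional rolling median. The window in samples is
#' `round(window_s * sampling_rate)`; an even window is allowed (the median of
#' an even number of samples is the mean of the two central order statistics,
#' and the centered span places the extra sample on the left). At the trace
#' edges the window shrinks to the available samples.
#'
#' @param trace A [resp_trace()].
#' @param window_s Window length in seconds; must map to at least one sample.
#' @return The filtered trace (same length and rate).
#' @export
median_filter_trace <- function(trace, window_s = 0.1) {
  stopifnot(inherits(trace, "resp_trace"))
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be positive")
  w <- as.integer(round(window_s * trace$sampling_rate))
  if (w < 1L) stop("window shorter than one sample at this sampling rate")
  out <- trace
  out$samples <- .rolling_median(trace$samples, w)
  out
}

#' Downsample and z-transform a respiratory trace
#'
#' Downsampling averages non-overlapping windows of `sampling_rate /
#' target_rate` consecutive samples (a crude but effective anti-aliasing
#' step); the ratio must be a whole number. The result is standardized to
#' mean 0 and population standard deviation 1.
#'
#' @param trace A [resp_trace()].
#' @param target_rate Output rate in Hz; must divide the input rate.
#' @return A standardized trace at `target_rate`.
#' @export
downsample_standardize <- function(trace, target_rate = 1) {
  stopifnot(inherits(trace, "resp_trace"), target_rate > 0)
  factor <- trace$sampling_rate / target_rate
  if (factor < 1) stop("target_rate exceeds the sampling rate")
  if (abs(factor - round(factor)) > 1e-8) {
    stop("sampling_rate must be an integer multiple of target_rate")
  }
  factor <- as.integer(round(factor))
  n_out <- length(trace$samples) %/% factor
  if (n_out < 2L) stop("trace too short to downsample to target_rate")
  x <- trace$samples[seq_len(n_out * factor)]
  m <- .colMeans(x, factor, n_out)
  mu <- mean(m)
  s <- sqrt(mean((m - mu)^2))  # population denominator
  if (s < 1e-12) stop("constant trace: z-transform undefined")
  out <- trace
  out$samples <- (m - mu) / s
  out$sampling_rate <- target_rate
  out
}

#' Iterative root normalization of a standardized trace
#'
#' Applies `y <- y / |y|^(1/p)` for `n_iterations` iterations, which equals
#' `sign(y) * |y|^((1 - 1/p)^k)` in closed form — `sign(y) * |y|^(2^(-k))`
#' for the default `p = 2`. On a z-transformed trace this
#' boosts small amplitudes towards +/-1 and attenuates large ones, making the
#' peak structure insensitive to step changes in belt gain. Zero maps to zero;
#' +/-1 are fixed points; the ordering of absolute values is preserved.
#'
#' The trace is expected to be z-transformed already (not enforced).
#'
#' @param trace A [resp_trace()].
#' @param params A [norm_params()].
#' @return The normalized trace.
#' @export
iterative_normalize <- function(trace, params = norm_params()) {
  stopifnot(inherits(trace, "resp_trace"), inherits(params, "norm_params"))
  y <- trace$samples
  for (k in seq_len(params$n_iterations)) {
    a <- abs(y)
    nz <- a > 0
    y[nz] <- y[nz] / a[nz]^(1 / params$p)
  }
  out <- trace
  out$samples <- y
  out
}

# Local maxima with plateau handling: a run of equal values higher than its
# immediate neighbours is one maximum, located at the upper-middle sample of
# the run. Returns integer indices.
.local_maxima <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j + 1L) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of peak index p: walk out left and right until a
# strictly higher sample or the trace boundary; the base on each side is the
# minimum encountered, and prominence is peak height minus the higher base.
.prominence <- function(x, p) {
  left_base <- x[p]
  i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < left_base) left_base <- x[i]
    i <- i - 1L
  }
  right_base <- x[p]
  i <- p + 1L
  while (i <= length(x) && x[i] <= x[p]) {
    if (x[i] < right_base) right_base <- x[i]
    i <- i + 1L
  }
  x[p] - max(left_base, right_base)
}

#' Detect respiratory peaks
#'
#' Finds local maxima of the (normalized) trace, computes their topographic
#' prominence, discards peaks below the prominence threshold, and greedily
#' enforces the minimum separation in descending order of prominence (ties
#' broken in favour of the earlier peak). Peak times are reported on the
#' trace's sample grid without sub-sample interpolation.
#'
#' @param trace A [resp_trace()], typically at 1 Hz after
#'   [preprocess_respiratory()].
#' @param params A [peak_params()].
#' @return Numeric vector of strictly increasing peak times in seconds.
#' @export
detect_peaks <- function(trace, params = peak_params()) {
  stopifnot(inherits(trace, "resp_trace"), inherits(params, "peak_params"))
  x <- trace$samples
  if (length(x) < 3L) stop("trace too short for peak detection")
  cand <- .local_maxima(x)
  if (length(cand) == 0L) return(numeric(0))
  prom <- vapply(cand, function(p) .prominence(x, p), numeric(1))
  keep <- prom >= params$prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(numeric(0))
  ord <- order(-prom, cand)
  min_sep_samples <- params$min_separation_s * trace$sampling_rate
  accepted <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - accepted) >= min_sep_samples)) {
      accepted <- c(accepted, cand[k])
    }
  }
  sort(trace$t0 + (accepted - 1L) / trace$sampling_rate)
}

#' Extract inhalation events from peak times
#'
#' Each retained peak yields one inhalation event covering the
#' `event_duration_s` seconds that precede it. Events whose window would start
#' before the run are dropped (not clipped).
#'
#' @param peaks Numeric vector of peak times in seconds.
#' @param params A [peak_params()].
#' @param run_duration Run duration in seconds; peaks outside `[0,
#'   run_duration]` are ignored.
#' @return A data frame of class `inhalation_events` with columns `onset`,
#'   `duration`, `peak_time` and `condition` (initially `"unassigned"`).
#' @export
extract_inhalation_events <- function(peaks, params = peak_params(),
                                      run_duration = Inf) {
  stopifnot(inherits(params, "peak_params"))
  peaks <- sort(peaks[peaks >= 0 & peaks <= run_duration])
  onset <- peaks - params$event_duration_s
  keep <- onset >= 0
  ev <- data.frame(
    onset = onset[keep],
    duration = rep(params$event_duration_s, sum(keep)),
    peak_time = peaks[keep],
    condition = factor(rep("unassigned", sum(keep)),
                       levels = c("i_air", "i_odorant", "unassigned")),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("inhalation_events", "data.frame")
  ev
}

#' Assign inhalation events to stimulation phases
#'
#' An event is labelled `i_air` or `i_odorant` only when it falls entirely
#' inside a single phase: phases are half-open intervals `[start, end)` and an
#' event qualifies iff `onset >= start` and `onset + duration <= end`. Events
#' that straddle a phase boundary remain `unassigned`.
#'
#' @param events Events from [extract_inhalation_events()].
#' @param schedule A [block_schedule()].
#' @return The events with the `condition` column filled in.
#' @export
assign_events <- function(events, schedule) {
  stopifnot(inherits(events, "inhalation_events"),
            inherits(schedule, "block_schedule"))
  ph <- schedule_phases(schedule)
  cond <- as.character(events$condition)
  for (i in seq_len(nrow(events))) {
    o <- events$onset[i]
    e <- o + events$duration[i]
    hit <- which(o >= ph$start & e <= ph$end)
    cond[i] <- if (length(hit) >= 1L) {
      if (ph$phase[hit[1L]] == "air") "i_air" else "i_odorant"
    } else {
      "unassigned"
    }
  }
  events$condition <- factor(cond,
                             levels = c("i_air", "i_odorant", "unassigned"))
  events
}

#' Full respiratory preprocessing pipeline
#'
#' Median filter, downsample to the target rate, z-transform, and iteratively
#' normalize, in that order.
#'
#' @param trace A raw [resp_trace()].
#' @param params A [norm_params()].
#' @return The preprocessed trace at `params$target_rate`.
#' @export
preprocess_respiratory <- function(trace, params = norm_params()) {
  trace <- median_filter_trace(trace, params$median_window_s)
  trace <- downsample_standardize(trace, params$target_rate)
  iterative_normalize(trace, params)
}

#' Extract labelled inhalation events from a raw trace
#'
#' Convenience wrapper running [preprocess_respiratory()], [detect_peaks()],
#' [extract_inhalation_events()] and [assign_events()].
#'
#' @param trace A raw [resp_trace()].
#' @param schedule A [block_schedule()]; `NULL` leaves events unassigned.
#' @param norm A [norm_params()].
#' @param peaks A [peak_params()].
#' @return Labelled `inhalation_events`.
#' @export
respiratory_events <- function(trace, schedule = NULL, norm = norm_params(),
                               peaks = peak_params()) {
  run_duration <- length(trace$samples) / trace$sampling_rate
  pre <- preprocess_respiratory(trace, norm)
  pk <- detect_peaks(pre, peaks)
  ev <- extract_inhalation_events(pk, peaks, run_duration)
  if (!is.null(schedule)) ev <- assign_events(ev, schedule)
  ev
}
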