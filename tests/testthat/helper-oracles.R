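# Independent brute-force oracles used to validate the fast implementations.
# These are written from the definitions, not from the package code paths.

# Sliding median over a centered window that shrinks at the edges; even
# windows span one extra sample on the left and average the two central
# order statistics (R's median() does this for even counts).
oracle_rolling_median <- function(x, w) {
  n <- length(x)
  left <- w %/% 2
  right <- w - left - 1
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - left)
    hi <- min(n, i + right)
    median(x[lo:hi])
  }, numeric(1))
}

# Exhaustive peak detection: every sample is tested for being a local
# maximum (plateaus collapse to their upper-middle sample), prominence is
# found by walking out to the first strictly higher sample or the boundary,
# and the separation rule is enforced greedily by descending prominence
# (ties to the earlier peak). Returns indices.
oracle_peaks <- function(x, prominence, min_sep_samples) {
  n <- length(x)
  is_peak <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j < n && x[j + 1] < x[i]) is_peak[(i + j + 1) %/% 2] <- TRUE
  }
  idx <- which(is_peak)
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(p) {
    lo <- p
    while (lo > 1 && x[lo - 1] <= x[p]) lo <- lo - 1
    hi <- p
    while (hi < n && x[hi + 1] <= x[p]) hi <- hi + 1
    left_base <- min(x[lo:p])
    right_base <- min(x[p:hi])
    x[p] - max(left_base, right_base)
  }, numeric(1))
  keep <- prom >= prominence
  idx <- idx[keep]
  prom <- prom[keep]
  accepted <- integer(0)
  for (k in order(-prom, idx)) {
    if (all(abs(idx[k] - accepted) >= min_sep_samples)) {
      accepted <- c(accepted, idx[k])
    }
  }
  sort(accepted)
}

# Benjamini-Hochberg by direct step-up over all candidate thresholds.
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  mask <- rep(FALSE, m)
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  mask
}

# OLS through the explicit normal equations.
oracle_ols <- function(X, y) unname(drop(solve(t(X) %*% X) %*% t(X) %*% y))

# A breathing-like raw belt trace: a zero-baseline sinusoid of the given
# period, optionally rescaled from half-way through (emulating a hardware
# gain recalibration).
make_sine_breathing <- function(duration, period, fs = 400,
                                second_half_scale = 1) {
  t <- (seq_len(duration * fs) - 1) / fs
  x <- sin(2 * pi * t / period)
  x[t >= duration / 2] <- x[t >= duration / 2] * second_half_scale
  resp_trace(x, fs)
}

# Smooth random traces for oracle-equivalence checks.
make_random_trace <- function(n, rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  resp_trace(x, rate)
}

# Labelled events at explicit onsets (2 s duration) for design tests.
make_events <- function(onsets, conditions, duration = 2) {
  ev <- data.frame(onset = onsets, duration = duration,
                   peak_time = onsets + duration,
                   condition = factor(conditions,
                                      levels = c("i_air", "i_odorant",
                                                 "unassigned")))
  class(ev) <- c("inhalation_events", "data.frame")
  ev
}

# Direct O(n * k) linear convolution truncated to the signal length.
oracle_convolve <- function(signal, kernel) {
  n <- length(signal)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_along(kernel)) {
      if (t - k + 1 >= 1) out[t] <- out[t] + kernel[k] * signal[t - k + 1]
    }
  }
  out
}
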