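#' Block stimulation schedule
#'
#' Describes the alternating air/odorant block structure of one functional
#' run. The default reproduces a 208 s run: a 16 s odorless lead-in followed
#' by six cycles of 16 s odorant and 16 s odorless air.
#'
#' @param run_duration Run duration in seconds.
#' @param block_duration Duration of one block in seconds.
#' @param n_odor_blocks Number of odorant blocks.
#' @param first_phase Phase of the first block, `"air"` or `"odorant"`.
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(run_duration = 208, block_duration = 16,
                           n_odor_blocks = 6, first_phase = c("air", "odorant")) {
  first_phase <- match.arg(first_phase)
  stopifnot(run_duration > 0, block_duration > 0, n_odor_blocks >= 1)
  sched <- structure(
    list(run_duration = run_duration, block_duration = block_duration,
         n_odor_blocks = as.integer(n_odor_blocks), first_phase = first_phase),
    class = "block_schedule"
  )
  ph <- schedule_phases(sched)
  if (abs(max(ph$end) - run_duration) > 1e-9) {
    stop("phases do not tile the run: check run_duration, block_duration, n_odor_blocks")
  }
  if (sum(ph$phase == "odorant") != n_odor_blocks) {
    stop("schedule does not contain n_odor_blocks odorant blocks")
  }
  sched
}

#' Phase intervals of a schedule
#'
#' @param schedule A [block_schedule()].
#' @return Data frame with columns `start`, `end`, `phase` (half-open
#'   intervals `[start, end)` tiling the run).
#' @export
schedule_phases <- function(schedule) {
  stopifnot(inherits(schedule, "block_schedule"))
  n_blocks <- round(schedule$run_duration / schedule$block_duration)
  start <- (seq_len(n_blocks) - 1) * schedule$block_duration
  phase <- if (schedule$first_phase == "air") {
    ifelse(seq_len(n_blocks) %% 2 == 1, "air", "odorant")
  } else {
    ifelse(seq_len(n_blocks) %% 2 == 1, "odorant", "air")
  }
  data.frame(start = start, end = start + schedule$block_duration,
             phase = phase, stringsAsFactors = FALSE)
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> %g s run, %g s blocks, %d odorant blocks, first phase %s\n",
              x$run_duration, x$block_duration, x$n_odor_blocks, x$first_phase))
  invisible(x)
}
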