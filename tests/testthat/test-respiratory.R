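test_that("median filter preserves constants, suppresses spikes, matches the sliding-median oracle", {
  const <- resp_trace(rep(3.2, 500), 400)
  expect_equal(median_filter_trace(const, 0.1)$samples, rep(3.2, 500))

  spike <- rep(0, 2000)
  spike[777] <- 1
  tr <- resp_trace(spike, 400)
  out <- median_filter_trace(tr, 0.1)  # 40-sample window
  expect_equal(out$samples, rep(0, 2000))

  set.seed(11)
  for (w_s in c(0.01, 0.025, 0.1)) {
    x <- rnorm(300)
    tr <- resp_trace(x, 400)
    w <- round(w_s * 400)
    expect_equal(median_filter_trace(tr, w_s)$samples,
                 oracle_rolling_median(x, w), tolerance = 1e-12)
  }
  expect_error(median_filter_trace(resp_trace(rnorm(10), 400), 0),
               "positive")
  expect_error(median_filter_trace(resp_trace(rnorm(10), 4), 0.01),
               "window")
})

test_that("downsampling averages 1 s windows and standardizes with the population sd", {
  tr <- resp_trace(rnorm(208 * 400, sd = 3, mean = 5), 400)
  out <- downsample_standardize(tr, 1)
  expect_length(out$samples, 208)
  expect_equal(out$sampling_rate, 1)
  expect_equal(mean(out$samples), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(out$samples^2)), 1, tolerance = 1e-9)

  # hand example: 4 Hz [0,0,0,0,4,4,4,4] -> window means [0,4] -> z = [-1,1]
  hand <- downsample_standardize(resp_trace(c(0, 0, 0, 0, 4, 4, 4, 4), 4), 1)
  expect_equal(hand$samples, c(-1, 1))

  expect_error(downsample_standardize(resp_trace(rep(2, 800), 400), 1),
               "constant")
  expect_error(downsample_standardize(resp_trace(rnorm(100), 1), 2),
               "exceeds")
})

test_that("iterative normalization matches its closed form and fixed points", {
  # closed form sign(y) |y|^((1-1/p)^k) on random traces, to 1e-12;
  # for p = 2 this is the iterated square root sign(y) |y|^(2^-k)
  set.seed(21)
  for (p in c(2, 3)) {
    for (k in 1:4) {
      y <- rnorm(200)
      tr <- resp_trace(y, 1)
      out <- iterative_normalize(tr, norm_params(p = p, n_iterations = k))
      expect_equal(out$samples, sign(y) * abs(y)^((1 - 1 / p)^k),
                   tolerance = 1e-12)
      if (p == 2) {
        expect_equal(out$samples, sign(y) * abs(y)^(2^(-k)),
                     tolerance = 1e-12)
      }
    }
  }
  # frozen values computed from the closed form
  one <- function(v) iterative_normalize(resp_trace(c(v, 0), 1),
                                         norm_params())$samples[1]
  expect_equal(one(16), 1.189207115, tolerance = 1e-8)
  expect_equal(one(-0.0625), -0.840896415, tolerance = 1e-8)
  fixed <- iterative_normalize(resp_trace(c(0, 1, -1), 1), norm_params())
  expect_equal(fixed$samples, c(0, 1, -1))
  # order of magnitudes is preserved
  y <- c(0.1, -0.5, 2, -4, 0.01)
  out <- iterative_normalize(resp_trace(y, 1), norm_params())$samples
  expect_equal(order(abs(out)), order(abs(y)))
})

test_that("peak detection finds sine peaks, applies the separation rule, and matches the oracle", {
  tr <- resp_trace(sin(2 * pi * 0.25 * (0:59)), 1)
  pk <- detect_peaks(tr, peak_params())
  expect_equal(pk, seq(1, 57, by = 4))

  expect_equal(detect_peaks(resp_trace(rep(1, 10), 1), peak_params()),
               numeric(0))
  expect_equal(detect_peaks(resp_trace(1:10, 1), peak_params()), numeric(0))

  # two peaks 1 s apart (2 Hz trace): only the more prominent survives
  x <- c(0, 1.0, 0, 0.8, 0)
  pk <- detect_peaks(resp_trace(x, 2), peak_params(prominence = 0.5,
                                                   min_separation_s = 2))
  expect_equal(pk, 0.5)
  # at 2 s separation both are retained ("at least 2 s" is inclusive)
  pk2 <- detect_peaks(resp_trace(c(0, 1.0, 0, 0, 0, 0.8, 0), 2),
                      peak_params(prominence = 0.5, min_separation_s = 2))
  expect_equal(pk2, c(0.5, 2.5))

  # oracle equivalence on random smooth traces
  for (seed in 1:25) {
    tr <- make_random_trace(sample(50:300, 1), seed = seed)
    got <- detect_peaks(tr, peak_params(prominence = 0.3,
                                        min_separation_s = 3))
    want <- (oracle_peaks(tr$samples, 0.3, 3) - 1)
    expect_equal(got, as.numeric(want))
  }
  expect_error(detect_peaks(resp_trace(c(1, 2), 1)), "short")
})

test_that("inhalation events precede peaks and drop pre-run windows", {
  ev <- extract_inhalation_events(c(10, 20), peak_params(), 208)
  expect_equal(ev$onset, c(8, 18))
  expect_equal(ev$duration, c(2, 2))
  expect_equal(as.character(ev$condition), rep("unassigned", 2))

  ev <- extract_inhalation_events(c(1, 5), peak_params(), 208)
  expect_equal(ev$onset, 3)  # the peak at 1 s would start at -1 s

  expect_equal(nrow(extract_inhalation_events(numeric(0), peak_params(), 208)),
               0)
})

test_that("event assignment honours half-open phases and partitions the events", {
  sched <- block_schedule()
  ev <- make_events(c(8, 15, 20), rep("unassigned", 3))
  out <- assign_events(ev, sched)
  expect_equal(as.character(out$condition),
               c("i_air", "unassigned", "i_odorant"))

  # boundary conventions: onset at phase start is in; end at phase end is in
  ev <- make_events(c(16, 30, 14), rep("unassigned", 3))
  out <- assign_events(ev, sched)
  expect_equal(as.character(out$condition),
               c("i_odorant", "i_odorant", "i_air"))

  # partition: every event gets exactly one label; counts are order-invariant
  set.seed(5)
  onsets <- runif(60, 0, 205)
  ev <- make_events(onsets, rep("unassigned", 60))
  out1 <- assign_events(ev, sched)
  perm <- sample(60)
  out2 <- assign_events(make_events(onsets[perm], rep("unassigned", 60)), sched)
  expect_equal(nrow(out1), 60)
  expect_equal(table(out1$condition), table(out2$condition))
  expect_equal(sum(table(out1$condition)), 60)
})

test_that("normalization makes peak detection robust to belt recalibration jumps", {
  raw <- make_sine_breathing(200, period = 4, second_half_scale = 5)
  by_half <- function(pk) c(sum(pk < 100), sum(pk >= 100))

  filtered <- median_filter_trace(raw, 0.1)
  z <- downsample_standardize(filtered, 1)
  with_norm <- detect_peaks(iterative_normalize(z, norm_params()),
                            peak_params())
  without_norm <- detect_peaks(z, peak_params())

  halves <- by_half(with_norm)
  expect_lte(abs(halves[1] - halves[2]), 1)
  expect_gt(halves[1], 20)
  # without amplitude normalization the small-amplitude half is missed
  raw_halves <- by_half(without_norm)
  expect_lt(raw_halves[1], halves[1] / 2)
})
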