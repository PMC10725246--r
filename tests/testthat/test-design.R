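test_that("the dual-gamma kernel starts at zero, peaks on time, and respects amplitude conventions", {
  m <- hrf_model()
  h <- hrf_sample(m, rate = 1)
  expect_length(h, 32)
  expect_equal(h[1], 0)
  # dense-evaluation oracle for the argmax of the positive lobe
  dense <- hrf_sample(m, rate = 100)
  t_dense <- (seq_along(dense) - 1) / 100
  expect_lt(abs(t_dense[which.max(dense)] -
                  (m$peak_delay - m$peak_dispersion)), 0.02)
  expect_lte(abs(t_dense[which.max(dense)] - m$peak_delay), 1)
  # one sign change: positive lobe then undershoot
  signs <- sign(h[h != 0])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_equal(max(hrf_sample(hrf_model(amplitude_convention = "peak1"))), 1)
  expect_equal(sum(hrf_sample(hrf_model(amplitude_convention = "sum1"))), 1)
})

test_that("block regressors follow the schedule and the convolution oracle", {
  sched <- block_schedule()
  ph <- schedule_phases(sched)
  odor_on <- sum(ph$end[ph$phase == "odorant"] - ph$start[ph$phase == "odorant"])
  expect_equal(odor_on, 96)  # 6 x 16 s of odorant before convolution

  X <- build_block_regressors(sched, include_air = TRUE)
  expect_equal(nrow(X$values), 104)
  expect_equal(X$times, seq(0, 206, by = 2))
  expect_equal(colnames(X$values), c("air", "odorant", "constant"))

  # independent construction: direct convolution of the boxcar, sampled at TR
  box <- as.numeric(outer(0:207, seq_len(nrow(ph)), function(t, i) {
    t >= ph$start[i] & t < ph$end[i] & ph$phase[i] == "odorant"
  }) %*% rep(1, nrow(ph)))
  conv <- oracle_convolve(box, hrf_sample(hrf_model(), 1))
  expect_equal(X$values[, "odorant"], conv[seq(1, 208, by = 2)],
               tolerance = 1e-10)

  expect_error(build_block_regressors(sched, n_volumes = 200), "exceeds")
})

test_that("event regressors are built from labelled events only and need odorant events", {
  ev <- make_events(c(16, 40), c("i_odorant", "i_air"))
  X <- build_event_regressors(ev, include_air = TRUE)
  expect_equal(colnames(X$values), c("i_air", "i_odorant", "constant"))

  # a single event at [16, 18): the kernel is zero at lag 0, so the predictor
  # is zero up to and including the volume at t = 16 and positive at t = 18
  X1 <- build_event_regressors(make_events(16, "i_odorant"))
  v <- X1$values[, "i_odorant"]
  expect_true(all(v[X1$times <= 16] == 0))
  expect_gt(v[X1$times == 18], 0)

  # unassigned events enter neither predictor
  ev2 <- make_events(c(16, 100), c("i_odorant", "unassigned"))
  X2 <- build_event_regressors(ev2, include_air = TRUE)
  expect_equal(X2$values[, "i_odorant"], v)
  expect_equal(X2$values[, "i_air"], rep(0, 104))

  expect_error(build_event_regressors(make_events(10, "i_air")),
               "degenerate")
})

test_that("efficiency matches hand-computed cases and is name-keyed", {
  # single task column [1,1,-1,-1]: c (X'X)^-1 c' = 1/4
  X <- design_matrix(0:3, cbind(s = c(1, 1, -1, -1), constant = 1), "toy")
  expect_equal(efficiency(X, c(s = 1))$value, 4)

  # two orthogonal indicator columns, differential contrast -> 1
  X2 <- design_matrix(0:3, cbind(x1 = c(1, 0, 1, 0), x2 = c(0, 1, 0, 1),
                                 constant = 1), "toy2")
  expect_equal(efficiency(X2, c(x1 = -1, x2 = 1))$value, 1)

  # column order must not matter when the contrast is keyed by name
  X2r <- design_matrix(0:3, X2$values[, c("x2", "x1", "constant")], "toy2r")
  expect_equal(efficiency(X2r, c(x1 = -1, x2 = 1))$value,
               efficiency(X2, c(x1 = -1, x2 = 1))$value)

  # duplicated column + difference contrast -> rank error
  Xd <- design_matrix(0:3, cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                                 constant = 1), "dup")
  expect_error(efficiency(Xd, c(a = -1, b = 1)), "rank|singular")
  expect_error(efficiency(X, c(nope = 1)), "not in design")
})

test_that("efficiency scales quadratically with kernel amplitude", {
  sched <- block_schedule()
  e_sum1 <- efficiency(build_block_regressors(
    sched, hrf_model(amplitude_convention = "sum1")), "SBD1")$value
  e_cal <- efficiency(build_block_regressors(
    sched, hrf_model(amplitude_convention = "calibrated")), "SBD1")$value
  amp <- sniffglm:::.CALIBRATED_AMPLITUDE
  expect_equal(e_cal / e_sum1, amp^2, tolerance = 1e-10)
  # and the SBD1/SBD2 ratio is amplitude-convention-free
  r <- function(conv) {
    m <- hrf_model(amplitude_convention = conv)
    efficiency(build_block_regressors(sched, m), "SBD1")$value /
      efficiency(build_block_regressors(sched, m, include_air = TRUE),
                 "SBD2")$value
  }
  expect_equal(r("sum1"), r("peak1"), tolerance = 1e-10)
  expect_equal(r("sum1"), r("calibrated"), tolerance = 1e-10)
})

test_that("adding a correlated regressor never increases contrast efficiency (Schur oracle)", {
  set.seed(33)
  for (rep in 1:20) {
    n <- 40
    base <- matrix(rnorm(n * 2), n, 2)
    colnames(base) <- c("a", "b")
    X <- design_matrix(seq_len(n), cbind(base, constant = 1), "rand")
    cvec <- c(a = runif(1, -1, 1), b = runif(1, -1, 1))
    e0 <- efficiency(X, cvec)$value
    z <- 0.6 * base[, "a"] + rnorm(n)  # correlated extra regressor
    Xz <- design_matrix(seq_len(n),
                        cbind(base, z = z, constant = 1), "rand+z")
    e1 <- efficiency(Xz, cvec)$value
    expect_lte(e1, e0 + 1e-10)
    # closed form via the Schur complement of the augmented Gram matrix
    M <- crossprod(base)
    cv <- c(cvec["a"], cvec["b"])
    v0 <- drop(cv %*% solve(M, cv))
    mz <- drop(crossprod(base, z))
    s <- drop(crossprod(z) - mz %*% solve(M, mz))
    v1 <- v0 + (drop(cv %*% solve(M, mz)))^2 / s
    expect_equal(e1, 1 / v1, tolerance = 1e-8)
  }
})

test_that("event-design efficiency grows with nested event sets", {
  set.seed(44)
  for (rep in 1:10) {
    onsets <- sort(sample(seq(0, 200, by = 2), 12))
    base <- make_events(onsets, rep("i_odorant", 12))
    extra_onset <- sample(setdiff(seq(0, 200, by = 2), onsets), 1)
    grown <- make_events(sort(c(onsets, extra_onset)),
                         rep("i_odorant", 13))
    e0 <- efficiency(build_event_regressors(base), "MBD1")$value
    e1 <- efficiency(build_event_regressors(grown), "MBD1")$value
    expect_gte(e1, e0 * (1 - 1e-6))
  }
})

test_that("the efficiency study averages runs within subject and keeps SBD fixed", {
  p <- breathing_params(recalib_prob_per_min = 0, noise_sd = 0)
  tr1 <- simulate_breathing(208, p, rate = 14, seed = 101)
  tr2 <- simulate_breathing(208, p, rate = 17, seed = 102)
  # identical runs within a subject: subject mean equals the run value
  es <- efficiency_study(list(list(tr1, tr1), list(tr2, tr2)))
  runs <- es$runs
  for (s in 1:2) {
    for (d in c("MBD1", "MBD2")) {
      v <- runs$value[runs$subject == s & runs$design == d]
      expect_equal(v[1], v[2])
      expect_equal(es$subject_means$value[es$subject_means$subject == s &
                                            es$subject_means$design == d],
                   v[1])
    }
  }
  # SBD values do not depend on the traces
  es2 <- efficiency_study(list(list(tr2)))
  expect_equal(es$sbd, es2$sbd)
})
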