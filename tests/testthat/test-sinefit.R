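test_that("model-matched noiseless segments recover Pmax exactly", {
  fx <- sine_segments(A = 30, C = 10)
  fit <- fit_sine_pmax(fx$waveform, fx$landmarks)
  expect_true(fit$converged)
  expect_equal(fit$p_max, 40, tolerance = 1e-6)
  expect_equal(fit$omega, fx$omega, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_gte(fit$n_points, 8)
  # different geometry
  fx2 <- sine_segments(A = 18, C = 22, period_sys = 0.5)
  fit2 <- fit_sine_pmax(fx2$waveform, fx2$landmarks)
  expect_equal(fit2$p_max, 40, tolerance = 1e-6)
})

test_that("Pmax is unbiased to ~1 mm Hg under 1 mm Hg noise", {
  set.seed(42)
  errs <- replicate(40, {
    fx <- sine_segments(A = 30, C = 10, noise_sd = 1)
    abs(fit_sine_pmax(fx$waveform, fx$landmarks)$p_max - 40)
  })
  expect_lt(mean(errs), 2)
})

test_that("constant-pressure segments yield a flagged degenerate fit", {
  fx <- sine_segments(A = 30, C = 10)
  wf <- fx$waveform
  wf$pressure <- rep(15, length(wf$pressure))
  fit <- fit_sine_pmax(wf, fx$landmarks)
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_lt(fit$amplitude, 1e-3)
})

test_that("Pmax is invariant to a uniform time shift of the beat", {
  syn <- synth_waveform(n_beats = 4, noise_sd = 0.2, seed = 11,
                        hr_jitter_sd = 0)
  wf1 <- syn$waveform
  wf2 <- wf1
  wf2$t0 <- 3.7
  db1 <- deriv_bundle(wf1)
  b <- segment_beats(wf1, db1$dpdt)
  lm1 <- locate_landmarks(wf1, b[2, ], db1$dpdt, db1$smoothed)
  lm2 <- locate_landmarks(wf2, b[2, ], deriv_bundle(wf2)$dpdt)
  f1 <- fit_sine_pmax(wf1, lm1)
  f2 <- fit_sine_pmax(wf2, lm2)
  expect_equal(f2$p_max, f1$p_max, tolerance = 1e-9)
  expect_equal(lm2$t_dpdt_max - lm1$t_dpdt_max, 3.7, tolerance = 1e-9)
})

test_that("too-few isovolumic samples are rejected", {
  fx <- sine_segments()
  lm <- fx$landmarks
  lm$idx_ic_start <- lm$idx_dpdt_max - 2L  # 3-sample IC range
  expect_error(fit_sine_pmax(fx$waveform, lm), "too few")
})

test_that("beat selection averages the k most stable converged fits", {
  mkfit <- function(p_max, rmse, converged = TRUE, cl = 0.9) {
    structure(list(p_max = p_max, rmse = rmse, converged = converged,
                   cycle_len = cl), class = "rv_sinefit")
  }
  # identical beats: mean equals the single-beat value exactly
  fits <- replicate(10, mkfit(38.5, 0.2), simplify = FALSE)
  out <- select_beats(fits, k = 3)
  expect_identical(out$p_max, 38.5)
  expect_length(out$selected, 3)

  # a high-RMSE beat is never selected when three better ones exist
  fits <- list(mkfit(40, 0.1), mkfit(41, 0.2), mkfit(60, 5.0), mkfit(39, 0.3))
  out <- select_beats(fits, k = 3)
  expect_false(3 %in% out$selected)
  expect_equal(out$p_max, mean(c(40, 41, 39)))

  # off-tempo beats (cycle length beyond 10% of median) are ineligible
  fits <- list(mkfit(40, 0.1), mkfit(41, 0.2), mkfit(39, 0.3),
               mkfit(80, 0.05, cl = 1.5))
  out <- select_beats(fits, k = 3)
  expect_false(4 %in% out$selected)

  # fewer than k eligible -> error advising manual selection
  fits <- list(mkfit(40, 0.1), mkfit(41, 0.2, converged = FALSE),
               mkfit(39, 0.3, converged = FALSE))
  expect_error(select_beats(fits, k = 3), "manual")
  # manual override bypasses the stability rule
  out <- select_beats(fits, k = 3, beats = c(1, 2, 3))
  expect_equal(out$selected, 1:3)
})

test_that("averaged Pmax tracks generator truth within 3% at 0.5 mm Hg noise", {
  errs <- sapply(1:10, function(s) {
    syn <- synth_waveform(n_beats = 10, noise_sd = 0.5, seed = 100 + s)
    fit <- rv_pvloop(syn$waveform, syn$record)
    abs(fit$p_max - syn$truth$p_max) / syn$truth$p_max
  })
  expect_lt(median(errs), 0.03)
  expect_lt(max(errs), 0.06)
})
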