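test_that("dP/dt matches analytic derivatives", {
  fs <- 1000
  # constant trace -> identically zero
  wf <- rv_waveform(rep(10, 500), fs)
  expect_lt(max(abs(compute_dpdt(wf))), 1e-9)
  # sine: max derivative 2*pi at t ~ 0, within 0.5%
  t <- seq(0, 1, by = 1 / fs)
  wf <- rv_waveform(sin(2 * pi * t), fs)
  expect_equal(max(compute_dpdt(wf)), 2 * pi, tolerance = 5e-3)
  # linear ramp 0..100 mm Hg over 1 s -> ~100 mm Hg/s away from edges
  wf <- rv_waveform(seq(0, 100, length.out = fs + 1), fs)
  d <- compute_dpdt(wf)
  expect_equal(d[20:(fs - 20)], rep(100, fs - 39), tolerance = 1e-6)
  # window longer than signal errors
  expect_error(compute_dpdt(rv_waveform(1:10, 1000)), "window")
})

test_that("segmentation finds each generated cardiac cycle", {
  syn <- synth_waveform(n_beats = 12, noise_sd = 0.3, seed = 2, hr = 68)
  beats <- segment_beats(syn$waveform)
  expect_gte(nrow(beats), 10)
  expect_lte(nrow(beats), 12)
  expect_true(all(beats$start < beats$end))
  expect_true(all(diff(beats$start) > 0))
  expect_true(all(beats$end[-nrow(beats)] == beats$start[-1]))
})

test_that("a 10-s recording at HR 68 yields 11 complete beats (+/- 1)", {
  syn <- synth_waveform(duration_s = 10, hr = 68, noise_sd = 0.3, seed = 7)
  beats <- segment_beats(syn$waveform)
  expect_gte(nrow(beats), 10)
  expect_lte(nrow(beats), 12)
})

test_that("constant and beat-free traces give an empty segmentation", {
  wf <- rv_waveform(rep(12, 4000), 1000)
  expect_warning(beats <- segment_beats(wf), "no systolic upstrokes")
  expect_equal(nrow(beats), 0)
})

test_that("two identical concatenated beats split into equal cycles", {
  syn <- synth_waveform(n_beats = 2, noise_sd = 0, hr_jitter_sd = 0)
  beats <- segment_beats(syn$waveform)
  expect_equal(nrow(beats), 2)
  lens <- beats$end - beats$start
  expect_lte(abs(diff(lens)), 1)
})

test_that("landmarks recover generator fiducials within 2 samples when noiseless", {
  syn <- synth_waveform(n_beats = 5, noise_sd = 0, seed = 1, hr_jitter_sd = 0)
  wf <- syn$waveform
  db <- deriv_bundle(wf)
  beats <- segment_beats(wf, db$dpdt)
  truth <- syn$truth$landmarks
  for (i in seq_len(nrow(beats))) {
    lm <- locate_landmarks(wf, beats[i, ], db$dpdt, db$smoothed)
    k <- which.min(abs(truth[, "t_dpdt_max"] - lm$t_dpdt_max))
    got <- c(lm$t_ic_start, lm$t_dpdt_max, lm$t_rvsp, lm$t_dpdt_min,
             lm$t_ir_end)
    expect_lt(max(abs(got - truth[k, ])), 2 / wf$sampling_rate)
    expect_equal(lm$edp, syn$truth$edp, tolerance = 0.02)
    expect_equal(lm$bdp, syn$truth$bdp, tolerance = 0.05)
    # ordering invariant
    expect_true(lm$t_ic_start < lm$t_dpdt_max &&
                lm$t_dpdt_max < lm$t_rvsp &&
                lm$t_rvsp < lm$t_dpdt_min &&
                lm$t_dpdt_min < lm$t_ir_end)
    expect_gt(lm$dpdt_max, 0); expect_lt(lm$dpdt_min, 0)
  }
})

test_that("landmark times are invariant under affine pressure rescaling", {
  syn <- synth_waveform(n_beats = 3, noise_sd = 0, seed = 4, hr_jitter_sd = 0)
  wf1 <- syn$waveform
  wf2 <- wf1
  wf2$pressure <- 2 * wf1$pressure + 3
  suppressWarnings({
    b1 <- segment_beats(wf1)
    b2 <- segment_beats(wf2)
  })
  expect_identical(b1, b2)
  lm1 <- locate_landmarks(wf1, b1[2, ])
  lm2 <- suppressWarnings(locate_landmarks(wf2, b2[2, ]))
  for (f in c("t_ic_start", "t_dpdt_max", "t_rvsp", "t_dpdt_min", "t_ir_end"))
    expect_equal(lm1[[f]], lm2[[f]], tolerance = 1e-9)
  # pressures transform affinely
  expect_equal(lm2$edp, 2 * lm1$edp + 3, tolerance = 1e-6)
  expect_equal(lm2$rvsp, 2 * lm1$rvsp + 3, tolerance = 1e-6)
  expect_equal(lm2$bdp, 2 * lm1$bdp + 3, tolerance = 1e-6)
})

test_that("degenerate beats whose peak coincides with max dP/dt are rejected", {
  # triangle wave: derivative is maximal from the first rising sample, so no
  # one-fifth upcrossing precedes it
  fs <- 1000
  p <- c(seq(5, 30, length.out = 300), seq(30, 5, length.out = 500))
  wf <- rv_waveform(p, fs)
  beat <- data.frame(start = 1L, end = length(p) + 1L)
  expect_error(locate_landmarks(wf, beat), "landmark error")
})

test_that("fiducial recovery stays within 5 ms across HR and noise (property)", {
  worst <- c()
  for (s in 1:4) for (hr in c(50, 75, 100)) {
    syn <- synth_waveform(n_beats = 6, noise_sd = 0.5, seed = 1000 * s + hr,
                          hr = hr)
    wf <- syn$waveform
    db <- deriv_bundle(wf)
    beats <- segment_beats(wf, db$dpdt)
    truth <- syn$truth$landmarks
    errs <- NULL
    for (i in seq_len(nrow(beats))) {
      lm <- tryCatch(locate_landmarks(wf, beats[i, ], db$dpdt, db$smoothed),
                     error = function(e) NULL)
      if (is.null(lm)) next
      sf <- fit_sine_pmax(wf, lm)
      k <- which.min(abs(truth[, "t_dpdt_max"] - lm$t_dpdt_max))
      got <- c(lm$t_ic_start, sf$t_dpdt_max, lm$t_rvsp, sf$t_dpdt_min,
               lm$t_ir_end)
      errs <- rbind(errs, abs(got - truth[k, ]))
    }
    expect_gte(nrow(errs), 4)
    worst <- c(worst, max(apply(errs, 2, median)))
  }
  # median per-fiducial error within each recording stays below 5 ms
  expect_lt(max(worst), 0.005)
})
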