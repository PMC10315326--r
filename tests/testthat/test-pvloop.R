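test_that("noiseless recordings with measured diastolic pressures are recovered exactly", {
  syn <- synth_waveform(n_beats = 8, noise_sd = 0, seed = 1,
                        esp_method = "mpap", include_measured = TRUE)
  fit <- rv_pvloop(syn$waveform, syn$record, esp_method = "mpap")
  tr <- syn$truth
  for (f in c("p_max", "esp", "esv", "edv", "ees", "ea", "alpha", "beta",
              "eed"))
    expect_equal(fit[[f]], tr[[f]], tolerance = 1e-6,
                 label = sprintf("field %s", f))
  # internal consistency invariants
  expect_equal(fit$edv - fit$esv, fit$sv, tolerance = 1e-9)
  expect_equal(fit$ees, fit$esp / fit$esv, tolerance = 1e-9)
  expect_equal(fit$ees, fit$p_max / fit$edv, tolerance = 1e-9)
  expect_equal(fit$eed, fit$beta * (fit$n_edp + fit$alpha), tolerance = 1e-9)
})

test_that("noiseless waveform-derived path recovers truth to sampling precision", {
  syn <- synth_waveform(n_beats = 8, noise_sd = 0, seed = 2)
  fit <- rv_pvloop(syn$waveform, syn$record)
  tr <- syn$truth
  expect_equal(fit$p_max, tr$p_max, tolerance = 1e-6)
  expect_equal(fit$esp, tr$esp, tolerance = 1e-3)
  expect_equal(fit$beta, tr$beta, tolerance = 0.02)
  expect_equal(fit$eed, tr$eed, tolerance = 0.03)
})

test_that("ESP method changes only ESP-derived quantities", {
  syn <- synth_waveform(n_beats = 8, noise_sd = 0.3, seed = 3)
  f1 <- rv_pvloop(syn$waveform, syn$record, esp_method = "modified")
  f2 <- rv_pvloop(syn$waveform, syn$record, esp_method = "mpap")
  expect_identical(f1$p_max, f2$p_max)
  expect_identical(f1$sv, f2$sv)
  expect_identical(f1$edp, f2$edp)
  expect_false(isTRUE(all.equal(f1$esp, f2$esp)))
  expect_false(isTRUE(all.equal(f1$esv, f2$esv)))
})

test_that("missing cardiac-output source fails with a stage-named error", {
  syn <- synth_waveform(n_beats = 6, noise_sd = 0.2, seed = 4)
  rec <- syn$record
  rec$co_thermo <- NULL
  expect_error(rv_pvloop(syn$waveform, rec, sv_method = "thermo"),
               "\\[sv\\] SV source unavailable")
  expect_silent(fit <- rv_pvloop(syn$waveform, rec, sv_method = "fick"))
  expect_identical(fit$sv_method, "fick")
})

test_that("external volumes drive the EDPVR in the CMR variant", {
  syn <- synth_waveform(n_beats = 6, noise_sd = 0, seed = 5,
                        include_measured = TRUE)
  rec <- syn$record
  rec$esv_cmr <- 70; rec$edv_cmr <- 140
  rec$rvedp <- 6; rec$rvbdp <- 2    # n_edp = 5
  fit <- rv_pvloop(syn$waveform, rec, volume_source = "external")
  expect_identical(fit$volume_source, "external")
  expect_equal(fit$beta, log(4) / 70, tolerance = 1e-9)
  expect_true(any(grepl("external", fit$flags)))
  rec2 <- syn$record
  expect_error(rv_pvloop(syn$waveform, rec2, volume_source = "external"),
               "\\[volumes\\]")
})

test_that("degenerate diastolic pressures flag rather than crash, strict errors", {
  syn <- synth_waveform(n_beats = 6, noise_sd = 0, seed = 6)
  rec <- syn$record
  rec$rvedp <- 3; rec$rvbdp <- 5    # n_edp = -1
  fit <- rv_pvloop(syn$waveform, rec)
  expect_true(is.na(fit$beta) && is.na(fit$eed))
  expect_true(any(grepl("non-physiologic", fit$flags)))
  expect_false(is.na(fit$esv))      # partial results retained
  expect_error(rv_pvloop(syn$waveform, rec, strict = TRUE), "\\[edpvr\\]")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  syn <- synth_waveform(n_beats = 8, noise_sd = 0.3, seed = 7)
  fit <- rv_pvloop(syn$waveform, syn$record)
  cf <- coef(fit)
  expect_named(cf, c("p_max", "esp", "sv", "esv", "edv", "ees", "ea",
                     "ees_over_ea", "n_edp", "alpha", "beta", "eed"))
  expect_equal(unname(cf["edv"] - cf["esv"]), unname(cf["sv"]),
               tolerance = 1e-9)
  # predictions hit the anchors
  expect_equal(predict(fit, fit$esv), 1, tolerance = 1e-8)
  expect_equal(predict(fit, fit$edv), fit$n_edp, tolerance = 1e-8)
  expect_equal(predict(fit, fit$esv, relation = "espvr"), fit$esp,
               tolerance = 1e-9)
  r <- residuals(fit)
  expect_true(length(r) > 20 && all(is.finite(r)))
  expect_output(print(fit), "Pmax")
  expect_output(print(summary(fit)), "Per-beat")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  sims <- simulate(fit, nsim = 1, seed = 1, n_beats = 2)
  expect_s3_class(sims[[1]]$waveform, "rv_waveform")
})

test_that("manual beat selection is honoured", {
  syn <- synth_waveform(n_beats = 8, noise_sd = 0.3, seed = 8)
  fit <- rv_pvloop(syn$waveform, syn$record, beats = c(2, 4, 6))
  expect_equal(which(fit$beat_table$selected), c(2, 4, 6))
})
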