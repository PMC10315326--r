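test_that("closed-form volumes match the two-point line construction", {
  # p_max = 2*esp forces esv = sv
  v <- estimate_volumes(40, 20, 60)
  expect_equal(v$esv, 60); expect_equal(v$edv, 120)
  expect_equal(v$ees, 1 / 3); expect_equal(v$ea, 1 / 3)
  # independent 2x2 linear-solve oracle: edv - esv = sv and
  # esp*edv - p_max*esv = 0 (collinearity through the origin)
  v2 <- estimate_volumes(50, 30, 60)
  sol <- solve(rbind(c(-1, 1), c(-50, 30)), c(60, 0))
  expect_equal(v2$esv, sol[1], tolerance = 1e-12)
  expect_equal(v2$edv, sol[2], tolerance = 1e-12)
  expect_equal(v2$esv, 90); expect_equal(v2$edv, 150)
  expect_error(estimate_volumes(20, 25, 60), "Pmax must exceed ESP")
  expect_error(estimate_volumes(20, -1, 60), "ESP")
  expect_error(estimate_volumes(20, 10, 0), "SV")
})

test_that("EDPVR fit reproduces the closed form when EDV = 2 ESV", {
  # edv = 2*esv: anchor ratio becomes e^{b*esv} + 1 = n_edp
  ed <- fit_edpvr(70, 140, 5)
  expect_equal(ed$beta, log(4) / 70, tolerance = 1e-10)
  expect_equal(ed$alpha, 1 / 3, tolerance = 1e-9)
  ed2 <- fit_edpvr(50, 100, 10)
  expect_equal(ed2$beta, log(9) / 50, tolerance = 1e-10)
  expect_equal(ed2$alpha, 0.125, tolerance = 1e-9)
  # substitution check at the EDV anchor
  expect_equal(ed2$alpha * expm1(ed2$beta * 100), 10, tolerance = 1e-9)
})

test_that("EDPVR existence boundary is rejected with the documented error", {
  expect_error(fit_edpvr(70, 140, 1.5), "at or below volume ratio")
  expect_error(fit_edpvr(70, 140, 2), "at or below volume ratio")
  expect_error(fit_edpvr(70, 140, 0.8), "must exceed 1")
  expect_error(fit_edpvr(140, 70, 5), "edv > esv")
})

test_that("Eed equals the EDPVR slope at EDV and its algebraic identity", {
  ed <- fit_edpvr(70, 140, 5)
  eed <- compute_eed(ed$alpha, ed$beta, 140)
  expect_equal(eed, (1 / 3) * (log(4) / 70) * 16, tolerance = 1e-9)
  expect_equal(eed, 0.10562, tolerance = 1e-4)
  # identity Eed = beta * (n_edp + alpha)
  expect_equal(eed, ed$beta * (5 + ed$alpha), tolerance = 1e-9)
  ed2 <- fit_edpvr(50, 100, 10)
  expect_equal(compute_eed(ed2$alpha, ed2$beta, 100), 0.44493,
               tolerance = 1e-4)
  expect_error(compute_eed(0.1, 8, 100), "overflow")
  expect_error(compute_eed(-0.1, 0.02, 100), "> 0")
})

test_that("fitted beta matches a dense grid scan on random valid instances", {
  set.seed(99)
  for (i in 1:60) {
    esv <- runif(1, 30, 120)
    edv <- esv * runif(1, 1.3, 2.5)
    n_edp <- runif(1, edv / esv + 0.5, 12)
    ed <- fit_edpvr(esv, edv, n_edp)
    expect_lt(abs(ed$beta - grid_beta(esv, edv, n_edp)), 1e-6)
    # both anchors reproduced
    expect_equal(ed$alpha * expm1(ed$beta * esv), 1, tolerance = 1e-8)
    expect_equal(ed$alpha * expm1(ed$beta * edv), n_edp, tolerance = 1e-8)
  }
})

test_that("beta and Eed are monotone in normalized RVEDP and volume scale", {
  esv <- 70; edv <- 140
  ns <- seq(3, 9, by = 0.5)
  fits <- lapply(ns, function(n) fit_edpvr(esv, edv, n))
  betas <- vapply(fits, `[[`, numeric(1), "beta")
  eeds <- mapply(function(f) compute_eed(f$alpha, f$beta, edv), fits)
  expect_true(all(diff(betas) > 0))
  expect_true(all(diff(eeds) > 0))
  # with n_edp fixed, beta decreases as volumes scale up
  scales <- c(0.6, 0.8, 1, 1.3, 1.7)
  b2 <- vapply(scales, function(s) fit_edpvr(esv * s, edv * s, 5)$beta,
               numeric(1))
  expect_true(all(diff(b2) < 0))
})

test_that("EDPVR approaches the chord line in the small-stiffness limit", {
  esv <- 70; edv <- 140
  n_edp <- edv / esv + 1e-4
  ed <- fit_edpvr(esv, edv, n_edp)
  v <- seq(0, edv, length.out = 400)
  dev <- max(abs(edpvr_pressure(ed$alpha, ed$beta, v) - v / esv))
  expect_lt(dev / (edv / esv), 1e-3)
})
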