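# Shared fixtures, all generated in code.

# Pure-sine fixture for direct Pmax-fit tests: samples P(t) = C + A sin(w t
# + phi) over the isovolumic phase support, with hand-built landmark indices
# (no detection involved), so the fit is tested in isolation.
sine_segments <- function(A = 30, C = 10, period_sys = 0.4, fs = 1000,
                          noise_sd = 0, margin = 0.15) {
  w <- 2 * pi / period_sys
  th5 <- acos(1 / 5)
  th0 <- -(th5 + margin)
  th_end <- pi + th5 + margin
  t <- seq(0, (th_end - th0) / w, by = 1 / fs)
  theta <- th0 + w * t
  p <- C + A * sin(theta)
  if (noise_sd > 0) p <- p + rnorm(length(p), 0, noise_sd)
  wf <- suppressWarnings(rv_waveform(p, fs))
  at_phase <- function(x) which.min(abs(theta - x))
  lm <- structure(list(
    t_ic_start = (at_phase(-th5) - 1) / fs,
    t_dpdt_max = (at_phase(0) - 1) / fs,
    t_rvsp = (at_phase(pi / 2) - 1) / fs,
    t_dpdt_min = (at_phase(pi) - 1) / fs,
    t_ir_end = (at_phase(pi + th5) - 1) / fs,
    idx_ic_start = at_phase(-th5),
    idx_dpdt_max = at_phase(0),
    idx_dpdt_min = at_phase(pi),
    idx_ir_end = at_phase(pi + th5),
    cycle_len = length(p) / fs,
    rvsp = max(p), bdp = min(p), edp = C + A * sin(-th5),
    dpdt_max = A * w, dpdt_min = -A * w,
    beat_start = 1L, beat_end = length(p) + 1L),
    class = "rv_landmarks")
  list(waveform = wf, landmarks = lm, p_max = C + A, omega = w)
}

# Precomputed derivative bundle for landmark tests.
deriv_bundle <- function(wf, window_ms = 15) {
  d <- compute_dpdt(wf, window_ms)
  attr(d, "detection") <- rvsb:::detection_series(wf, d)
  list(dpdt = d, smoothed = rvsb:::smooth_pressure(wf, window_ms))
}

# Independent brute-force EDPVR beta: two-stage dense grid scan of the
# anchor-ratio equation, no root finder involved.
grid_beta <- function(esv, edv, n_edp, b_max = 0.5, n_grid = 4001) {
  g <- function(b) expm1(b * edv) / expm1(b * esv) - n_edp
  bs <- seq(b_max / n_grid, b_max, length.out = n_grid)
  gs <- g(bs)
  k <- which(gs > 0)[1]
  stopifnot(!is.na(k), k > 1)
  fine <- seq(bs[k - 1], bs[k], length.out = n_grid)
  gf <- g(fine)
  j <- which(gf > 0)[1]
  # linear interpolation across the final sign change
  fine[j - 1] + (0 - gf[j - 1]) / (gf[j] - gf[j - 1]) * (fine[j] - fine[j - 1])
}
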