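#' Fit the single-beat isovolumic sine and extrapolate Pmax
#'
#' Fits \eqn{P(t) = C + A \sin(\omega t + \phi)} by Levenberg-Marquardt least
#' squares to the union of the isovolumic contraction (IC) and isovolumic
#' relaxation (IR) samples of one beat; the maximum of the fitted sine,
#' \eqn{P_{max} = C + A}, estimates the peak pressure the ventricle would
#' have generated in a non-ejecting beat. Ejection-phase samples are
#' excluded: the IC range runs from the one-fifth dP/dt-max crossing to the
#' dP/dt maximum and the IR range from the dP/dt minimum to the one-fifth
#' dP/dt-min crossing (see [locate_landmarks()]).
#'
#' @details Time is re-zeroed at the IC start, making the fit invariant to
#'   time shifts of the beat. Starting values are closed-form and
#'   deterministic: \code{C} = mean of the fitted samples, \code{A} = half
#'   their range, \code{omega} = \eqn{\pi /} (IR end - IC start), \code{phi}
#'   from the first sample. Convergence uses a relative sum-of-squares
#'   tolerance of 1e-10 with at most 200 iterations. A negative fitted
#'   amplitude is re-phased so that \code{A > 0}. Non-convergence and
#'   degenerate fits (near-zero amplitude, or Pmax more than three RMSE below
#'   the largest fitted sample) are flagged, never silently passed.
#'
#' @param waveform An [rv_waveform()].
#' @param landmarks An \code{rv_landmarks} object for the beat.
#' @return An object of class \code{rv_sinefit}: \code{amplitude},
#'   \code{offset}, \code{omega}, \code{phi}, \code{p_max} (= offset +
#'   amplitude, mm Hg), \code{rmse} (mm Hg), \code{n_points},
#'   \code{converged}, \code{degenerate}, \code{cycle_len} (s) and the fitted
#'   sample indices.
#' @export
fit_sine_pmax <- function(waveform, landmarks) {
  lm <- landmarks
  ic <- lm$idx_ic_start:lm$idx_dpdt_max
  ir <- lm$idx_dpdt_min:lm$idx_ir_end
  if (length(ic) < 4L || length(ir) < 4L)
    stop("too few samples in IC/IR ranges for sine fitting (need >= 4 each)",
         call. = FALSE)
  sel <- c(ic, ir)
  fs <- waveform$sampling_rate
  tt <- waveform$t0 + (sel - 1L) / fs - lm$t_ic_start
  y <- waveform$pressure[sel]

  C0 <- mean(y)
  A0 <- (max(y) - min(y)) / 2
  w0 <- pi / (lm$t_ir_end - lm$t_ic_start)
  s0 <- if (A0 > 0) max(-1, min(1, (y[1L] - C0) / A0)) else 0
  phi0 <- asin(s0)

  converged <- FALSE
  pars <- c(C = C0, A = A0, w = w0, phi = phi0)
  if (A0 > .Machine$double.eps * max(1, abs(C0))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ C + A * sin(w * tt + phi),
        start = list(C = C0, A = A0, w = w0, phi = phi0),
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-12, maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pars <- stats::coef(fit)
      converged <- isTRUE(fit$convInfo$isConv)
    }
  }

  C <- unname(pars["C"]); A <- unname(pars["A"])
  w <- unname(pars["w"]); phi <- unname(pars["phi"])
  if (w < 0) { w <- -w; phi <- pi - phi }           # sin(-wt+phi) = sin(wt+pi-phi)
  if (A < 0) { A <- -A; phi <- phi + pi }           # canonical positive amplitude
  phi <- ((phi + pi) %% (2 * pi)) - pi
  resid <- y - (C + A * sin(w * tt + phi))
  rmse <- sqrt(mean(resid^2))
  p_max <- C + A
  degenerate <- A <= 1e-6 * max(1, abs(C)) || p_max < max(y) - 3 * rmse
  if (degenerate) converged <- FALSE

  # sine-refined isovolumic slope extremes: dP/dt is extremal at sine
  # phases 0 and pi; these use all fitted samples and are far less noisy
  # than locally detected extremum times
  t_at_phase <- function(target, near) {
    k <- round((w * near + phi - target) / (2 * pi))
    (target + 2 * pi * k - phi) / w
  }
  t_max_fit <- lm$t_ic_start + t_at_phase(0, lm$t_dpdt_max - lm$t_ic_start)
  t_min_fit <- lm$t_ic_start + t_at_phase(pi, lm$t_dpdt_min - lm$t_ic_start)

  structure(
    list(amplitude = A, offset = C, omega = w, phi = phi,
         p_max = p_max, rmse = rmse, n_points = length(sel),
         converged = converged, degenerate = degenerate,
         cycle_len = lm$cycle_len, residuals = resid,
         t_dpdt_max = t_max_fit, t_dpdt_min = t_min_fit,
         idx_fitted = sel, t_ic_start = lm$t_ic_start),
    class = "rv_sinefit"
  )
}

#' @export
print.rv_sinefit <- function(x, ...) {
  cat(sprintf(
    "Isovolumic sine fit: Pmax %.2f mm Hg (A %.2f, C %.2f, omega %.2f rad/s)\n",
    x$p_max, x$amplitude, x$offset, x$omega))
  cat(sprintf("  %d points, RMSE %.3f mm Hg, converged: %s%s\n",
              x$n_points, x$rmse, x$converged,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Select stable beats and average Pmax
#'
#' From the per-beat sine fits, keeps converged fits whose cycle length is
#' within 10\% of the median cycle length, selects the \code{k} with the
#' lowest fit RMSE (the "stably measured" beats), and returns their
#' arithmetic mean Pmax together with the selected beat indices.
#'
#' @param fits List of \code{rv_sinefit} objects, one per beat.
#' @param k Number of beats to average (default 3).
#' @param beats Optional manual override: integer indices (into \code{fits})
#'   of the beats to use, bypassing the automatic stability rule.
#' @return A list: \code{p_max} (mean over selected beats, mm Hg),
#'   \code{selected} (beat indices), \code{p_max_per_beat}, \code{eligible}
#'   (logical per beat).
#' @export
select_beats <- function(fits, k = 3, beats = NULL) {
  stopifnot(length(fits) >= 1L)
  pm <- vapply(fits, function(f) f$p_max, numeric(1))
  if (!is.null(beats)) {
    beats <- as.integer(beats)
    if (anyNA(beats) || any(beats < 1L | beats > length(fits)))
      stop("manual beat indices out of range", call. = FALSE)
    return(list(p_max = mean(pm[beats]), selected = beats,
                p_max_per_beat = pm, eligible = rep(TRUE, length(fits))))
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  cl <- vapply(fits, function(f) f$cycle_len, numeric(1))
  med <- stats::median(cl)
  eligible <- conv & abs(cl - med) <= 0.1 * med
  if (sum(eligible) < k)
    stop(sprintf(paste("only %d stable beat(s) for k = %d; inspect the",
                       "recording or select beats manually (beats=)"),
                 sum(eligible), k), call. = FALSE)
  rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  ord <- order(!eligible, rmse)          # eligible first, then lowest RMSE
  selected <- sort(ord[seq_len(k)])
  list(p_max = mean(pm[selected]), selected = selected,
       p_max_per_beat = pm, eligible = eligible)
}
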