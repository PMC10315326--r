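#' Ground-truth parameter set for a synthetic RV pressure beat
#'
#' Builds a fully self-consistent generative parameter set: the target
#' volumes and pressures are chosen first and every waveform and scalar
#' quantity (isovolumic sine, Pmax, cardiac output, pulmonary pressures) is
#' derived from them, so the end-to-end estimation chain has a well-posed
#' ground truth to recover. Defaults emulate a typical heart-failure RHC
#' study (HR 68/min, ESV 75 mL, EDV 142 mL, mPAP 16, sPAP 27.5 mm Hg,
#' normalized RVEDP 5 mm Hg).
#'
#' @details The beat is piecewise: a slow diastolic filling rise from BDP, an
#'   isovolumic-contraction segment lying exactly on the sine
#'   \eqn{C + A\sin(\omega t + \phi)}, an ejection arc that departs the sine
#'   and peaks at RVSP (below the sine maximum \eqn{P_{max} = C + A}), an
#'   isovolumic-relaxation segment back on the same sine, and a relaxation
#'   tail easing down to BDP. The sine is placed so that its one-fifth
#'   slope crossings occur at pressure EDP (defining the IC start and IR
#'   end), its peak slope at the dP/dt extremes, and the pressure peak
#'   midway, making the modified-ESP timing ratio exactly 1/2. True ESP is
#'   therefore mPAP (for \code{esp_method = "mpap"}) or (mPAP + sPAP)/2 (for
#'   \code{"modified"}), and \eqn{P_{max} = ESP \cdot EDV/ESV} enforces
#'   ESPVR collinearity through the origin. CO = SV x HR follows from the
#'   volumes.
#'
#' @param hr Heart rate (beats/min), 40-140.
#' @param esv,edv True end-systolic/end-diastolic volume (mL).
#' @param mpap,spap Mean/systolic pulmonary artery pressure (mm Hg).
#' @param bdp,edp True begin-/end-diastolic RV pressure (mm Hg),
#'   \code{edp > bdp >= 0}.
#' @param rvsp RV systolic peak pressure (mm Hg); defaults to sPAP.
#' @param esp_method Which ESP estimator the truth is made consistent with.
#' @param fs Sampling rate (Hz, default 1000).
#' @param sys_frac Fraction of the nominal cycle spent between IC onset and
#'   IR offset (default 0.45).
#' @param phase_margin Sine phase margin (rad) beyond the one-fifth slope
#'   crossings at each end of the isovolumic sine support (default 0.15).
#' @return A list of generator parameters and derived truths (\code{p_max},
#'   \code{esp}, \code{sv}, \code{co}, \code{ees}, \code{ea}, \code{n_edp},
#'   \code{alpha}, \code{beta}, \code{eed}, sine constants, segment phases).
#' @export
synth_params <- function(hr = 68, esv = 75, edv = 142, mpap = 16,
                         spap = 27.5, bdp = 2, edp = 6, rvsp = spap,
                         esp_method = c("modified", "mpap"), fs = 1000,
                         sys_frac = 0.45, phase_margin = 0.15) {
  esp_method <- match.arg(esp_method)
  if (!(hr >= 40 && hr <= 140))
    stop("hr outside the supported 40-140 /min range", call. = FALSE)
  if (!(edv > esv && esv > 0)) stop("need edv > esv > 0", call. = FALSE)
  if (!(spap >= mpap && mpap > 0)) stop("need spap >= mpap > 0", call. = FALSE)
  if (!(edp > bdp && bdp >= 0)) stop("need edp > bdp >= 0", call. = FALSE)

  esp <- if (esp_method == "mpap") mpap else (mpap + spap) / 2
  p_max <- esp * edv / esv          # ESPVR through the origin
  if (!(rvsp < p_max))
    stop(sprintf("rvsp (%.1f) must lie below the implied Pmax (%.1f)",
                 rvsp, p_max), call. = FALSE)
  if (!(rvsp >= 15 && rvsp <= 80))
    stop("rvsp outside the supported 15-80 mm Hg range", call. = FALSE)
  if (!(edp < p_max)) stop("edp must lie below Pmax", call. = FALSE)

  # sine placed so pressure at the 1/5-slope phase equals EDP
  th5 <- acos(1 / 5)                         # phase of the 1/5 dP/dt crossing
  A <- (p_max - edp) / (1 + sin(th5))
  C <- p_max - A
  theta0 <- -(th5 + phase_margin)            # sine support start
  theta_end <- pi + th5 + phase_margin       # sine support end
  p_on <- C + A * sin(theta0)                # pressure entering/leaving sine
  if (!(bdp < p_on))
    stop(sprintf("bdp (%.1f) must lie below the sine onset pressure (%.1f)",
                 bdp, p_on), call. = FALSE)
  sin_dep_max <- (rvsp - C) / A
  if (sin_dep_max <= 0.05)
    stop("rvsp too close to the sine midline; raise rvsp or edp",
         call. = FALSE)
  theta_dep <- min(0.35, 0.7 * asin(min(1, sin_dep_max)))
  p_dep <- C + A * sin(theta_dep)

  period <- 60 / hr
  t_sys <- sys_frac * period
  omega <- (theta_end - theta0) / t_sys

  sv <- edv - esv
  co <- sv * hr / 1000
  n_edp <- edp - bdp + 1
  if (n_edp <= edv / esv)
    stop("normalized RVEDP must exceed EDV/ESV for a valid EDPVR truth",
         call. = FALSE)
  ed <- fit_edpvr(esv, edv, n_edp)

  list(hr = hr, esv = esv, edv = edv, mpap = mpap, spap = spap,
       bdp = bdp, edp = edp, rvsp = rvsp, esp_method = esp_method, fs = fs,
       sys_frac = sys_frac, phase_margin = phase_margin,
       esp = esp, p_max = p_max, sv = sv, co = co,
       ees = (p_max - esp) / sv, ea = esp / sv,
       n_edp = n_edp, alpha = ed$alpha, beta = ed$beta,
       eed = compute_eed(ed$alpha, ed$beta, edv),
       A = A, C = C, omega = omega, theta0 = theta0,
       theta_end = theta_end, theta_dep = theta_dep,
       p_on = p_on, p_dep = p_dep, t_sys = t_sys, period = period,
       th5 = th5)
}

# One noiseless beat of length n_samp at period T_i; returns pressure vector
# and true landmark times relative to beat start.
synth_beat_pressure <- function(pp, T_i, n_samp) {
  fs <- pp$fs
  t <- (seq_len(n_samp) - 1L) / fs
  t1 <- 0.55 * (T_i - pp$t_sys)              # fill ends / sine starts
  t4 <- t1 + pp$t_sys                        # sine ends / tail starts
  p <- numeric(n_samp)

  fill <- t < t1
  p[fill] <- pp$bdp +
    (pp$p_on - pp$bdp) * (1 - cos(pi * t[fill] / t1)) / 2

  insine <- t >= t1 & t < t4
  th <- pp$theta0 + pp$omega * (t[insine] - t1)
  ps <- pp$C + pp$A * sin(th)
  ej <- th > pp$theta_dep & th < pi - pp$theta_dep
  u <- (th[ej] - pp$theta_dep) / (pi - 2 * pp$theta_dep)
  ps[ej] <- pp$p_dep + (pp$rvsp - pp$p_dep) * sin(pi * u)
  p[insine] <- ps

  tail <- t >= t4
  p_end <- pp$C + pp$A * sin(pp$theta_end)
  p[tail] <- pp$bdp +
    (p_end - pp$bdp) * (1 + cos(pi * (t[tail] - t4) / (T_i - t4))) / 2

  lm <- c(t_ic_start = t1 + (-pp$th5 - pp$theta0) / pp$omega,
          t_dpdt_max = t1 + (0 - pp$theta0) / pp$omega,
          t_rvsp = t1 + (pi / 2 - pp$theta0) / pp$omega,
          t_dpdt_min = t1 + (pi - pp$theta0) / pp$omega,
          t_ir_end = t1 + (pi + pp$th5 - pp$theta0) / pp$omega)
  list(pressure = p, landmarks = lm, t1 = t1, t4 = t4)
}

#' Generate a synthetic RV pressure recording with known ground truth
#'
#' Emulates a polygraph export of consecutive RV pressure beats: a train of
#' beats from the forward model of [synth_params()], with additive Gaussian
#' pressure noise and mild beat-to-beat cycle-length variability. Returns
#' the waveform, a matching [hemo_record()], and the generative truth for
#' every quantity the estimation chain produces.
#'
#' @param n_beats Number of beats (default 12; the clinical convention is
#'   10-15). Alternatively give \code{duration_s}; then
#'   \code{n_beats = floor(duration_s * hr / 60)} complete beats are
#'   generated.
#' @param noise_sd Additive Gaussian pressure noise SD (mm Hg, default 0.5).
#' @param seed Optional RNG seed for reproducibility.
#' @param duration_s Optional recording duration (s), overrides
#'   \code{n_beats}.
#' @param hr_jitter_sd Beat-to-beat cycle-length variability as a fraction
#'   of the nominal period (default 0.02).
#' @param include_measured If TRUE, copy the true EDP/BDP into the record as
#'   externally measured \code{rvedp}/\code{rvbdp} (the clinician-read
#'   polygraph path); default FALSE, leaving diastolic pressures to be
#'   derived from the waveform.
#' @param params A parameter set from [synth_params()]; alternatively pass
#'   its arguments through \code{...}.
#' @param ... Arguments forwarded to [synth_params()].
#' @return A list of class \code{rv_synth}: \code{waveform}
#'   ([rv_waveform()]), \code{record} ([hemo_record()]), \code{truth} (the
#'   [synth_params()] list plus per-beat true landmark times and the seed).
#' @export
#' @examples
#' syn <- synth_waveform(n_beats = 4, noise_sd = 0, seed = 1)
#' range(syn$waveform$pressure)
synth_waveform <- function(n_beats = 12, noise_sd = 0.5, seed = NULL,
                           duration_s = NULL, hr_jitter_sd = 0.02,
                           include_measured = FALSE, params = NULL, ...) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  pp <- if (is.null(params)) synth_params(...) else params
  if (!is.null(duration_s)) n_beats <- floor(duration_s * pp$hr / 60)
  if (n_beats < 1L) stop("need at least one beat", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  jit <- if (hr_jitter_sd > 0) stats::rnorm(n_beats, 0, hr_jitter_sd)
         else numeric(n_beats)
  periods <- pp$period * pmax(1 + jit, (pp$t_sys / pp$period) + 0.1)

  pressure <- numeric(0)
  lm_list <- vector("list", n_beats)
  offset <- 0
  for (b in seq_len(n_beats)) {
    n_samp <- round(periods[b] * pp$fs)
    bt <- synth_beat_pressure(pp, periods[b], n_samp)
    lm_list[[b]] <- bt$landmarks + offset / pp$fs
    pressure <- c(pressure, bt$pressure)
    offset <- offset + n_samp
  }
  if (noise_sd > 0)
    pressure <- pressure + stats::rnorm(length(pressure), 0, noise_sd)

  truth <- pp
  truth$landmarks <- do.call(rbind, lm_list)
  truth$n_beats <- n_beats
  truth$noise_sd <- noise_sd
  truth$hr_jitter_sd <- hr_jitter_sd
  truth$seed <- seed

  wf <- rv_waveform(pressure, pp$fs, patient_id = "synthetic")
  rec <- hemo_record(
    mpap = pp$mpap, spap = pp$spap, hr = pp$hr,
    co_thermo = pp$co, co_fick = pp$co,
    rvedp = if (include_measured) pp$edp,
    rvbdp = if (include_measured) pp$bdp,
    patient_id = "synthetic")
  structure(list(waveform = wf, record = rec, truth = truth),
            class = "rv_synth")
}

#' @export
print.rv_synth <- function(x, ...) {
  cat(sprintf(
    "Synthetic RV recording: %d beats, HR %g/min, noise SD %g mm Hg\n",
    x$truth$n_beats, x$truth$hr, x$truth$noise_sd))
  cat(sprintf(
    "  truth: Pmax %.1f, ESP %.1f mm Hg; ESV %.0f, EDV %.0f mL; beta %.4f /mL; Eed %.3f\n",
    x$truth$p_max, x$truth$esp, x$truth$esv, x$truth$edv,
    x$truth$beta, x$truth$eed))
  invisible(x)
}

#' Default generative parameter distributions for the two-group cohort
#'
#' Two synthetic disease phenotypes: a dilated ("DCM-like") group with large
#' volumes and modest diastolic pressure rise, and a "stiff-like"
#' (restrictive/infiltrative) group with smaller volumes and a steeper
#' diastolic pressure rise. Medians are inspired by published heart-failure
#' cohort tables but the groups are entirely synthetic. Each entry is
#' (lognormal meanlog/sdlog) for volumes and the EDP-BDP difference, and
#' (normal mean/sd) for heart rate and pressures.
#'
#' @return A named list with elements \code{dcm} and \code{stiff}.
#' @export
cohort_defaults <- function() {
  list(
    dcm = list(esv_meanlog = log(90), esv_sdlog = 0.22,
               sv_mean = 58, sv_sd = 8,
               dedp_meanlog = log(3.5), dedp_sdlog = 0.30,
               hr_mean = 70, hr_sd = 8,
               mpap_mean = 16, mpap_sd = 3, pulse_mean = 11, pulse_sd = 2,
               bdp_mean = 2, bdp_sd = 0.7),
    stiff = list(esv_meanlog = log(51), esv_sdlog = 0.22,
                 sv_mean = 46, sv_sd = 7,
                 dedp_meanlog = log(6.5), dedp_sdlog = 0.30,
                 hr_mean = 72, hr_sd = 8,
                 mpap_mean = 18, mpap_sd = 3, pulse_mean = 12, pulse_sd = 2,
                 bdp_mean = 2, bdp_sd = 0.7)
  )
}

#' Generate a two-group synthetic patient cohort
#'
#' Draws per-patient generative parameters from the two phenotype
#' distributions of [cohort_defaults()] (or user-supplied ones), generates a
#' pressure recording for each patient, and returns waveforms, hemodynamic
#' records and ground truths. By construction the stiff-like group has
#' higher true diastolic stiffness beta and end-diastolic elastance Eed.
#'
#' @param n_per_group Patients per group, >= 2.
#' @param seed RNG seed (the whole cohort is reproducible from it).
#' @param noise_sd Pressure noise SD (mm Hg, default 0.5).
#' @param n_beats Beats per recording (default 12).
#' @param group_params List with elements \code{dcm} and \code{stiff} as in
#'   [cohort_defaults()].
#' @param include_measured Passed to [synth_waveform()].
#' @return A list of class \code{rv_cohort}: \code{patients} (list of
#'   per-patient lists with \code{id}, \code{group}, \code{waveform},
#'   \code{record}, \code{truth}) and \code{table} (a per-patient data.frame
#'   of true parameters).
#' @export
synth_cohort <- function(n_per_group = 20, seed = 1, noise_sd = 0.5,
                         n_beats = 12, group_params = cohort_defaults(),
                         include_measured = FALSE) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  for (g in group_params)
    if (any(unlist(g[grepl("_sd", names(g))]) < 0))
      stop("negative spread parameter in group_params", call. = FALSE)
  set.seed(seed)
  draw_patient <- function(g, id, group) {
    for (try in 1:50) {
      esv <- stats::rlnorm(1, g$esv_meanlog, g$esv_sdlog)
      sv <- max(15, stats::rnorm(1, g$sv_mean, g$sv_sd))
      dedp <- stats::rlnorm(1, g$dedp_meanlog, g$dedp_sdlog)
      hr <- min(135, max(45, stats::rnorm(1, g$hr_mean, g$hr_sd)))
      mpap <- max(8, stats::rnorm(1, g$mpap_mean, g$mpap_sd))
      spap <- mpap + max(4, stats::rnorm(1, g$pulse_mean, g$pulse_sd))
      bdp <- max(0, stats::rnorm(1, g$bdp_mean, g$bdp_sd))
      pp <- tryCatch(
        synth_params(hr = hr, esv = esv, edv = esv + sv, mpap = mpap,
                     spap = spap, bdp = bdp, edp = bdp + dedp,
                     esp_method = "modified"),
        error = function(e) NULL)
      if (!is.null(pp)) {
        syn <- synth_waveform(n_beats = n_beats, noise_sd = noise_sd,
                              hr_jitter_sd = 0.02, params = pp,
                              include_measured = include_measured)
        syn$waveform$patient_id <- syn$record$patient_id <- id
        return(list(id = id, group = group, waveform = syn$waveform,
                    record = syn$record, truth = syn$truth))
      }
    }
    stop("could not draw valid generative parameters after 50 tries",
         call. = FALSE)
  }
  ids_d <- sprintf("dcm_%02d", seq_len(n_per_group))
  ids_s <- sprintf("stiff_%02d", seq_len(n_per_group))
  patients <- c(
    lapply(seq_len(n_per_group), function(i)
      draw_patient(group_params$dcm, ids_d[i], "dcm")),
    lapply(seq_len(n_per_group), function(i)
      draw_patient(group_params$stiff, ids_s[i], "stiff")))
  tab <- do.call(rbind, lapply(patients, function(p)
    data.frame(patient_id = p$id, group = p$group,
               hr = p$truth$hr, mpap = p$truth$mpap, spap = p$truth$spap,
               co = p$truth$co, esv = p$truth$esv, edv = p$truth$edv,
               esp = p$truth$esp, p_max = p$truth$p_max,
               n_edp = p$truth$n_edp, beta = p$truth$beta,
               eed = p$truth$eed, stringsAsFactors = FALSE)))
  structure(list(patients = patients, table = tab), class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%s)\n", nrow(x$table),
              paste(sprintf("%s n=%d", names(table(x$table$group)),
                            as.integer(table(x$table$group))),
                    collapse = ", ")))
  med <- stats::aggregate(cbind(esv, edv, n_edp, beta, eed) ~ group,
                          data = x$table, FUN = stats::median)
  print(med, row.names = FALSE, digits = 3)
  invisible(x)
}
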