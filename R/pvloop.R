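#' Single-beat RV pressure-volume loop estimation
#'
#' The central fitter: runs the full single-beat chain on one RV pressure
#' recording and one scalar hemodynamic record, and returns every
#' pressure-volume-loop parameter the method defines. Stages: derivative and
#' beat segmentation; per-beat landmark detection; isovolumic sine fits and
#' Pmax averaging over the stable beats; end-systolic pressure; stroke
#' volume; closed-form ESV/EDV, Ees, Ea under V0 = 0; normalized RVEDP;
#' exponential EDPVR fit giving the diastolic stiffness coefficient beta and
#' the end-diastolic elastance Eed.
#'
#' @param waveform An [rv_waveform()]: 10-15 consecutive beats recommended.
#' @param record An [hemo_record()].
#' @param esp_method End-systolic pressure estimator: \code{"modified"}
#'   (default; mPAP plus the sPAP-mPAP excess weighted by the per-beat RVSP
#'   timing ratio, averaged over the selected beats) or \code{"mpap"}.
#' @param sv_method Stroke-volume source: \code{"thermo"} (thermodilution,
#'   default) or \code{"fick"} (indirect Fick).
#' @param volume_source \code{"estimated"} (default; closed-form from Pmax,
#'   ESP, SV) or \code{"external"} (use \code{esv_cmr}/\code{edv_cmr} from
#'   the record for the EDPVR, e.g. CMR-derived volumes).
#' @param k_beats Number of stable beats averaged (default 3).
#' @param beats Optional manual beat selection (indices into the segmented
#'   beats), bypassing the automatic stability rule.
#' @param smoothing_window_ms Derivative/smoothing window (ms, default 15).
#' @param upstroke_frac,min_beat_interval_ms Segmentation parameters, see
#'   [segment_beats()].
#' @param strict If TRUE, quality flags (non-physiologic normalized RVEDP,
#'   degenerate EDPVR) become errors instead of NA results.
#'
#' @details Externally measured \code{rvedp}/\code{rvbdp} in the record take
#'   precedence over waveform-derived EDP/BDP (recorded in the provenance
#'   flags); otherwise EDP/BDP are averaged over the selected beats. Errors
#'   carry the failing stage name in square brackets. A degenerate EDPVR
#'   (normalized RVEDP at or below EDV/ESV or below 1) yields NA for alpha,
#'   beta and Eed with an explanatory flag unless \code{strict}.
#'
#' @return An object of class \code{rv_pvloop} with fields \code{p_max},
#'   \code{esp}, \code{sv}, \code{esv}, \code{edv} (mm Hg / mL), \code{ees},
#'   \code{ea}, \code{ees_over_ea}, \code{edp}, \code{bdp}, \code{n_edp},
#'   \code{alpha}, \code{beta}, \code{eed}, method tags, quality
#'   \code{flags}, a per-beat table \code{beat_table}, and the configuration
#'   used. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}, \code{residuals}, \code{simulate},
#'   \code{as.data.frame}.
#' @seealso [estimate_volumes()], [fit_edpvr()], [compute_eed()],
#'   [synth_waveform()]
#' @export
#' @examples
#' syn <- synth_waveform(n_beats = 6, noise_sd = 0, seed = 1)
#' fit <- rv_pvloop(syn$waveform, syn$record)
#' coef(fit)
rv_pvloop <- function(waveform, record,
                      esp_method = c("modified", "mpap"),
                      sv_method = c("thermo", "fick"),
                      volume_source = c("estimated", "external"),
                      k_beats = 3, beats = NULL,
                      smoothing_window_ms = 15, upstroke_frac = 0.5,
                      min_beat_interval_ms = 300, strict = FALSE) {
  esp_method <- match.arg(esp_method)
  sv_method <- match.arg(sv_method)
  volume_source <- match.arg(volume_source)
  stopifnot(inherits(waveform, "rv_waveform"), inherits(record, "rv_hemo"))
  flags <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  dpdt <- stage("dpdt", compute_dpdt(waveform, smoothing_window_ms))
  ps <- stage("dpdt", smooth_pressure(waveform, smoothing_window_ms))
  attr(dpdt, "detection") <- stage("dpdt", detection_series(waveform, dpdt))
  beat_df <- stage("segmentation",
                   segment_beats(waveform, dpdt, upstroke_frac,
                                 min_beat_interval_ms,
                                 window_ms = smoothing_window_ms))
  if (nrow(beat_df) == 0L)
    stop("[segmentation] no beats detected", call. = FALSE)

  lms <- vector("list", nrow(beat_df))
  fits <- vector("list", nrow(beat_df))
  ok <- logical(nrow(beat_df))
  for (i in seq_len(nrow(beat_df))) {
    res <- tryCatch({
      lm <- locate_landmarks(waveform, beat_df[i, ], dpdt, ps,
                             smoothing_window_ms)
      list(lm = lm, fit = fit_sine_pmax(waveform, lm))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, sprintf("beat %d skipped: %s", i,
                                conditionMessage(res)))
    } else {
      lms[[i]] <- res$lm; fits[[i]] <- res$fit; ok[i] <- TRUE
    }
  }
  if (!any(ok))
    stop("[landmarks] no analyzable beats", call. = FALSE)
  keep <- which(ok)
  sel <- stage("beat_selection",
               select_beats(fits[keep], k = k_beats,
                            beats = if (!is.null(beats))
                              match(as.integer(beats), keep)))
  selected <- keep[sel$selected]
  p_max <- sel$p_max

  esp <- stage("esp", {
    if (esp_method == "mpap") as.numeric(esp_mpap(record))
    else {
      # timing ratio per selected beat, then averaged; dP/dt extremum times
      # taken from the fitted sine phases (0 and pi), which pool all
      # isovolumic samples and are much less noise-sensitive than local
      # extremum detection
      ratios <- mapply(function(l, f) {
        den <- f$t_dpdt_min - f$t_dpdt_max
        if (den <= 0) stop("landmark error: non-positive systolic interval",
                           call. = FALSE)
        (l$t_rvsp - f$t_dpdt_max) / den
      }, lms[selected], fits[selected])
      record$mpap + (record$spap - record$mpap) * mean(ratios)
    }
  })

  sv <- stage("sv", {
    co <- switch(sv_method, thermo = record$co_thermo, fick = record$co_fick)
    if (is.null(co))
      stop(sprintf("SV source unavailable: co_%s missing from record",
                   sv_method), call. = FALSE)
    stroke_volume(co, record$hr)
  })

  vols <- stage("volumes", estimate_volumes(p_max, esp, sv))
  if (volume_source == "external") {
    if (is.null(record$esv_cmr))
      stop("[volumes] external volume source requested but esv_cmr/edv_cmr",
           " absent from record", call. = FALSE)
    esv <- record$esv_cmr; edv <- record$edv_cmr
    flags <- c(flags, "volumes: external (CMR)")
  } else {
    esv <- vols$esv; edv <- vols$edv
  }

  if (!is.null(record$rvedp) && !is.null(record$rvbdp)) {
    edp <- record$rvedp; bdp <- record$rvbdp
    flags <- c(flags, "diastolic pressures: externally measured")
  } else {
    edp <- mean(vapply(lms[selected], `[[`, numeric(1), "edp"))
    bdp <- mean(vapply(lms[selected], `[[`, numeric(1), "bdp"))
  }
  n_edp <- as.numeric(normalized_rvedp(edp, bdp))
  if (n_edp <= 1) {
    msg <- "normalized RVEDP <= 1 (non-physiologic)"
    if (strict) stop("[edpvr] ", msg, call. = FALSE)
    flags <- c(flags, msg)
  }

  ed <- tryCatch(fit_edpvr(esv, edv, n_edp), error = function(e) e)
  if (inherits(ed, "error")) {
    if (strict) stop("[edpvr] ", conditionMessage(ed), call. = FALSE)
    flags <- c(flags, paste0("edpvr: ", conditionMessage(ed)))
    alpha <- beta <- eed <- NA_real_
  } else {
    alpha <- ed$alpha; beta <- ed$beta
    eed <- stage("eed", compute_eed(alpha, beta, edv))
  }

  beat_table <- data.frame(
    beat = seq_len(nrow(beat_df)),
    start = beat_df$start, end = beat_df$end,
    cycle_len_s = NA_real_, p_max_mmhg = NA_real_, rmse_mmhg = NA_real_,
    converged = FALSE, selected = FALSE)
  for (i in keep) {
    beat_table$cycle_len_s[i] <- lms[[i]]$cycle_len
    beat_table$p_max_mmhg[i] <- fits[[i]]$p_max
    beat_table$rmse_mmhg[i] <- fits[[i]]$rmse
    beat_table$converged[i] <- fits[[i]]$converged
  }
  beat_table$selected[selected] <- TRUE

  structure(
    list(p_max = p_max, esp = esp, esp_method = esp_method,
         sv = sv, sv_method = sv_method,
         esv = esv, edv = edv,
         ees = vols$ees, ea = vols$ea, ees_over_ea = vols$ees / vols$ea,
         edp = edp, bdp = bdp, n_edp = n_edp,
         alpha = alpha, beta = beta, eed = eed,
         volume_source = volume_source, flags = flags,
         beat_table = beat_table, selected = selected,
         landmarks = lms[selected], fits = fits[selected],
         patient_id = record$patient_id %||% waveform$patient_id,
         config = list(esp_method = esp_method, sv_method = sv_method,
                       volume_source = volume_source, k_beats = k_beats,
                       smoothing_window_ms = smoothing_window_ms,
                       upstroke_frac = upstroke_frac,
                       min_beat_interval_ms = min_beat_interval_ms),
         call = match.call()),
    class = "rv_pvloop"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rv_pvloop <- function(x, digits = 4, ...) {
  cat("Single-beat RV pressure-volume loop estimate",
      if (!is.null(x$patient_id)) sprintf("[%s]", x$patient_id), "\n")
  cat(sprintf("  Pmax %.1f, ESP %.1f (%s) mm Hg; SV %.1f mL (%s)\n",
              x$p_max, x$esp, x$esp_method, x$sv, x$sv_method))
  cat(sprintf("  ESV %.1f, EDV %.1f mL (%s); Ees %.3f, Ea %.3f mm Hg/mL; Ees/Ea %.2f\n",
              x$esv, x$edv, x$volume_source, x$ees, x$ea, x$ees_over_ea))
  cat(sprintf("  nEDP %.2f mm Hg; alpha %.4g mm Hg; beta %.4g /mL; Eed %.4g mm Hg/mL\n",
              x$n_edp, x$alpha, x$beta, x$eed))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.rv_pvloop <- function(object, ...) {
  structure(list(fit = object), class = "summary.rv_pvloop")
}

#' @export
print.summary.rv_pvloop <- function(x, ...) {
  print(x$fit)
  cat("\nPer-beat sine fits (selected beats marked):\n")
  print(x$fit$beat_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.rv_pvloop <- function(object, ...) {
  c(p_max = object$p_max, esp = object$esp, sv = object$sv,
    esv = object$esv, edv = object$edv,
    ees = object$ees, ea = object$ea, ees_over_ea = object$ees_over_ea,
    n_edp = object$n_edp, alpha = object$alpha, beta = object$beta,
    eed = object$eed)
}

#' Predict pressures on the fitted ESPVR or EDPVR
#'
#' @param object An \code{rv_pvloop} fit.
#' @param volume Volumes (mL) at which to evaluate.
#' @param relation \code{"edpvr"} (exponential diastolic curve, normalized
#'   pressure scale) or \code{"espvr"} (end-systolic line through the
#'   origin).
#' @param ... Unused.
#' @return Pressures (mm Hg; normalized scale for the EDPVR).
#' @export
predict.rv_pvloop <- function(object, volume,
                              relation = c("edpvr", "espvr"), ...) {
  relation <- match.arg(relation)
  if (relation == "espvr") return(object$esp / object$esv * volume)
  if (is.na(object$beta))
    stop("EDPVR was not fitted (see flags)", call. = FALSE)
  edpvr_pressure(object$alpha, object$beta, volume)
}

#' @export
residuals.rv_pvloop <- function(object, ...) {
  r <- unlist(lapply(object$fits, `[[`, "residuals"))
  attr(r, "beat") <- rep(object$selected,
                         vapply(object$fits, function(f)
                           length(f$residuals), integer(1)))
  r
}

#' Plot the estimated pressure-volume loop
#'
#' Draws the ESPVR line through the origin, the exponential EDPVR, and the
#' schematic single-beat PV loop connecting (EDV, nEDP) - (EDV, Pmax) -
#' (ESV, ESP) - (ESV, 1).
#'
#' @param x An \code{rv_pvloop} fit.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.rv_pvloop <- function(x, ...) {
  v <- seq(0, 1.1 * x$edv, length.out = 200)
  graphics::plot(v, x$esp / x$esv * v, type = "l", col = "firebrick",
                 xlab = "Volume (mL)", ylab = "Pressure (mm Hg)",
                 ylim = c(0, 1.05 * x$p_max),
                 main = "Single-beat RV pressure-volume loop", ...)
  if (!is.na(x$beta))
    graphics::lines(v, edpvr_pressure(x$alpha, x$beta, v), col = "steelblue")
  loop_v <- c(x$edv, x$edv, x$esv, x$esv)
  loop_p <- c(x$n_edp, x$p_max, x$esp, 1)
  graphics::polygon(c(loop_v, x$edv), c(loop_p, x$n_edp), border = "gray30")
  graphics::points(c(x$esv, x$edv), c(x$esp, x$p_max), pch = 19)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("firebrick", "steelblue"),
                   legend = c(sprintf("ESPVR (Ees %.3f)", x$ees),
                              sprintf("EDPVR (beta %.4f)", x$beta)))
  invisible(x)
}

#' Simulate waveforms consistent with a fitted PV-loop estimate
#'
#' Generates synthetic RV pressure recordings whose generative ground truth
#' equals the fitted parameters (volumes, ESP, diastolic pressures, heart
#' rate), useful for posterior-predictive-style checks of the pipeline.
#'
#' @param object An \code{rv_pvloop} fit (with estimated volumes).
#' @param nsim Number of recordings.
#' @param seed Optional RNG seed.
#' @param noise_sd Additive pressure noise SD (mm Hg, default 0.5).
#' @param n_beats Beats per recording (default 12).
#' @param ... Unused.
#' @return A list of \code{nsim} results from [synth_waveform()].
#' @export
simulate.rv_pvloop <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.5, n_beats = 12, ...) {
  if (!is.null(seed)) set.seed(seed)
  hr <- 60 / mean(vapply(object$landmarks, `[[`, numeric(1), "cycle_len"))
  rvsp <- mean(vapply(object$landmarks, `[[`, numeric(1), "rvsp"))
  lapply(seq_len(nsim), function(i)
    synth_waveform(n_beats = n_beats, noise_sd = noise_sd,
                   hr = hr, esv = object$esv, edv = object$edv,
                   mpap = 2 * object$esp - rvsp, spap = rvsp,
                   bdp = object$bdp, edp = object$edp,
                   esp_method = "modified"))
}

#' @export
as.data.frame.rv_pvloop <- function(x, ...) {
  data.frame(
    patient_id = x$patient_id %||% NA_character_,
    p_max_mmhg = x$p_max, esp_mmhg = x$esp, esp_method = x$esp_method,
    sv_ml = x$sv, sv_method = x$sv_method,
    esv_ml = x$esv, edv_ml = x$edv,
    ees_mmhg_per_ml = x$ees, ea_mmhg_per_ml = x$ea,
    ees_over_ea = x$ees_over_ea,
    edp_mmhg = x$edp, bdp_mmhg = x$bdp, n_edp_mmhg = x$n_edp,
    alpha_mmhg = x$alpha, beta_per_ml = x$beta, eed_mmhg_per_ml = x$eed,
    volume_source = x$volume_source,
    flags = paste(x$flags, collapse = "; "),
    stringsAsFactors = FALSE)
}
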