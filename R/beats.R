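#' Pressure derivative dP/dt by local polynomial (Savitzky-Golay) filtering
#'
#' Computes a smoothed first derivative of the pressure trace. A quadratic
#' local polynomial over a short window is differentiated analytically; this
#' is far more stable than a raw first difference when the one-fifth
#' threshold crossings of dP/dt are needed, and it is zero-phase, so landmark
#' times are not shifted. Edges are handled by the filter's one-sided
#' polynomial fits, so the output has the same length as the input.
#'
#' @param waveform An [rv_waveform()].
#' @param window_ms Smoothing window in milliseconds (default 15); converted
#'   to an odd number of samples, minimum 5.
#' @return Numeric vector of dP/dt in mm Hg/s, same length as the input.
#' @export
#' @examples
#' wf <- rv_waveform(sin(2 * pi * seq(0, 1, by = 1e-3)), 1000)
#' max(compute_dpdt(wf)) # ~ 2*pi
compute_dpdt <- function(waveform, window_ms = 15) {
  n <- sg_window(waveform$sampling_rate, window_ms)
  if (n > length(waveform$pressure))
    stop("smoothing window longer than signal", call. = FALSE)
  signal::sgolayfilt(waveform$pressure, p = 2, n = n, m = 1,
                     ts = 1 / waveform$sampling_rate)
}

# Zero-phase smoothed pressure with the same local-polynomial filter; used
# for diastolic-minimum (BDP) and beat-boundary location, never for fitting.
smooth_pressure <- function(waveform, window_ms = 15) {
  n <- sg_window(waveform$sampling_rate, window_ms)
  if (n > length(waveform$pressure))
    stop("smoothing window longer than signal", call. = FALSE)
  signal::sgolayfilt(waveform$pressure, p = 2, n = n, m = 0)
}

sg_window <- function(fs, window_ms) {
  n <- max(5L, as.integer(round(window_ms * fs / 1000)))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Segment a recording into cardiac beats
#'
#' Detects systolic upstrokes as peaks of dP/dt above a fraction of the
#' global dP/dt maximum, then places each cycle boundary at the diastolic
#' pressure minimum preceding the upstroke. No ECG channel is needed.
#'
#' @param waveform An [rv_waveform()].
#' @param dpdt Optional precomputed derivative from [compute_dpdt()].
#' @param upstroke_frac Upstroke detection threshold as a fraction of the
#'   global dP/dt maximum (default 0.5).
#' @param min_beat_interval_ms Minimum spacing between upstrokes (default
#'   300 ms, i.e. a 200/min ceiling on detected rate).
#' @param min_dpdt Absolute floor on the global dP/dt maximum (mm Hg/s,
#'   default 50); below it the trace is considered to contain no beats.
#' @param window_ms Smoothing window passed to the derivative/smoother.
#' @return A data.frame with integer columns \code{start}, \code{end}: sample
#'   indices of each beat as half-open intervals \code{[start, end)}, ordered
#'   and non-overlapping. Zero rows (with a warning) when no upstroke is
#'   found.
#' @export
segment_beats <- function(waveform, dpdt = NULL, upstroke_frac = 0.5,
                          min_beat_interval_ms = 300, min_dpdt = 50,
                          window_ms = 15) {
  if (is.null(dpdt)) dpdt <- compute_dpdt(waveform, window_ms)
  fs <- waveform$sampling_rate
  dmax <- max(dpdt)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (!is.finite(dmax) || dmax < min_dpdt) {
    warning("no systolic upstrokes found (dP/dt max below floor)",
            call. = FALSE)
    return(empty)
  }
  thr <- upstroke_frac * dmax
  above <- dpdt >= thr
  # one-sided polynomial fits at the signal edges can fabricate extreme
  # derivatives; never seed an upstroke there
  n_edge <- sg_window(fs, window_ms)
  above[seq_len(min(n_edge, length(above)))] <- FALSE
  above[seq.int(max(1L, length(above) - n_edge + 1L), length(above))] <- FALSE
  # one peak (earliest argmax) per contiguous run above threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    peaks <- c(peaks, seg[which.max(dpdt[seg])])
  }
  # enforce refractory interval; keep the larger peak (earliest on tie)
  min_gap <- as.integer(round(min_beat_interval_ms * fs / 1000))
  if (length(peaks) > 1L) {
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if (p - last >= min_gap) keep <- c(keep, p)
      else if (dpdt[p] > dpdt[last]) keep[length(keep)] <- p
    }
    peaks <- keep
  }
  if (length(peaks) < 1L) {
    warning("no systolic upstrokes found", call. = FALSE)
    return(empty)
  }

  ps <- smooth_pressure(waveform, window_ms)
  bounds <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    seg <- lo:peaks[i]
    bounds[i] <- seg[which.min(ps[seg])]
  }
  n <- length(waveform$pressure)
  bounds <- unique(bounds)
  if (length(bounds) < 2L) {
    beats <- data.frame(start = bounds, end = n + 1L)
  } else {
    beats <- data.frame(start = bounds[-length(bounds)],
                        end = bounds[-1L])
    # trailing segment kept only when it spans (most of) a full cycle
    med_len <- stats::median(diff(bounds))
    if (n + 1L - bounds[length(bounds)] >= 0.9 * med_len)
      beats <- rbind(beats,
                     data.frame(start = bounds[length(bounds)], end = n + 1L))
  }
  beats[beats$end > beats$start, , drop = FALSE]
}

#' Locate per-beat fiducial landmarks
#'
#' Finds, within one beat, the dP/dt extremes, the one-fifth-of-extreme
#' crossings bounding the isovolumic contraction (IC) and relaxation (IR)
#' ranges, the systolic peak (RVSP), the begin-diastolic pressure (BDP) and
#' the end-diastolic pressure (EDP).
#'
#' @details The IC range runs from the last upward crossing of
#'   \code{dpdt_max / 5} before the dP/dt maximum to the dP/dt maximum; the IR
#'   range runs from the dP/dt minimum to the first point after it where
#'   dP/dt rises back above \code{dpdt_min / 5}. Crossing times are refined by
#'   linear interpolation between samples, and extremum times (dP/dt max/min,
#'   RVSP) by a three-point parabolic vertex; indices stay on the sample
#'   grid. EDP is the (smoothed) pressure at the IC start; BDP is the minimum
#'   smoothed pressure after the IR end within the beat. Ties in extrema are
#'   broken by the earliest sample. All threshold rules are relative, so
#'   landmark times are invariant under affine rescaling of pressure.
#'
#' @param waveform An [rv_waveform()].
#' @param beat One row of [segment_beats()] output (or a list/vector with
#'   \code{start} and \code{end}).
#' @param dpdt Optional precomputed derivative for the whole waveform.
#' @param smoothed Optional precomputed smoothed pressure for the whole
#'   waveform.
#' @param window_ms Smoothing window used when \code{dpdt}/\code{smoothed}
#'   are not supplied.
#' @param detection_window_ms Width (ms, default 31) of the additional
#'   zero-phase smoothing applied to the derivative and pressure series for
#'   threshold-crossing and extremum *detection* only. Because the detection
#'   thresholds are ratios of the same smoothed series, symmetric smoothing
#'   does not bias crossing times on sinusoidal segments; it only suppresses
#'   spurious noise crossings. Reported pressures/slopes still come from the
#'   \code{window_ms} series.
#' @return An object of class \code{rv_landmarks}: times (s, absolute)
#'   \code{t_ic_start}, \code{t_dpdt_max}, \code{t_rvsp}, \code{t_dpdt_min},
#'   \code{t_ir_end}; pressures \code{rvsp}, \code{bdp}, \code{edp} (mm Hg);
#'   slopes \code{dpdt_max}, \code{dpdt_min} (mm Hg/s); sample indices
#'   \code{idx_*}; and \code{cycle_len} (s).
#' @export
locate_landmarks <- function(waveform, beat, dpdt = NULL, smoothed = NULL,
                             window_ms = 15, detection_window_ms = 31) {
  if (is.data.frame(beat)) beat <- as.list(beat[1L, ])
  i0 <- as.integer(beat$start); i1 <- as.integer(beat$end)
  n <- length(waveform$pressure)
  if (!(i0 >= 1L && i0 < i1 && i1 <= n + 1L))
    stop("invalid beat interval", call. = FALSE)
  if (is.null(dpdt)) dpdt <- compute_dpdt(waveform, window_ms)
  if (is.null(smoothed)) smoothed <- smooth_pressure(waveform, window_ms)
  det <- attr(dpdt, "detection")
  if (is.null(det) ||
      !identical(attr(det, "window_ms"), detection_window_ms))
    det <- detection_series(waveform, dpdt, detection_window_ms)
  fs <- waveform$sampling_rate
  idx <- i0:(i1 - 1L)
  p <- waveform$pressure[idx]
  ps <- smoothed[idx]
  d <- dpdt[idx]
  dd <- det$dpdt[idx]     # detection-smoothed derivative
  pd <- det$pressure[idx] # detection-smoothed pressure
  fail <- function(msg)
    stop(sprintf("landmark error in beat [%d,%d): %s", i0, i1, msg),
         call. = FALSE)

  imax <- which.max(dd)
  imin <- which.min(dd)
  if (dd[imax] <= 0 || dd[imin] >= 0) fail("dP/dt extremes have wrong sign")
  if (imax >= imin) fail("dP/dt max does not precede dP/dt min")
  ipk <- which.max(pd)
  if (!(imax < ipk && ipk < imin))
    fail("pressure peak not between dP/dt extremes")

  h_cross <- as.integer(round(0.010 * fs))  # crossing refinement half-width
  # IC start: last upward crossing of dpdt_max/5 before the dP/dt maximum
  th1 <- dd[imax] / 5
  j <- imax - 1L
  while (j >= 1L && !(dd[j] < th1 && dd[j + 1L] >= th1)) j <- j - 1L
  if (j < 1L) fail("no 1/5 dP/dt max upcrossing before dP/dt max")
  x1 <- ls_crossing(dd, j, th1, h_cross, rising = TRUE)
  t_ic <- (x1 - 1) / fs
  idx_ic <- j + 1L
  edp <- interp_at(ps, x1)

  # IR end: first return of dP/dt above dpdt_min/5 after the dP/dt minimum
  th2 <- dd[imin] / 5
  j2 <- imin
  last <- length(dd) - 1L
  while (j2 <= last && !(dd[j2] <= th2 && dd[j2 + 1L] > th2)) j2 <- j2 + 1L
  if (j2 > last) fail("no 1/5 dP/dt min crossing after dP/dt min")
  x2 <- ls_crossing(dd, j2, th2, h_cross, rising = TRUE)
  t_ir <- (x2 - 1) / fs
  idx_ir <- j2

  if (idx_ir + 1L > length(ps)) fail("beat ends at IR crossing")
  tail_idx <- (idx_ir + 1L):length(ps)
  # BDP: local average around the smoothed diastolic minimum (a raw minimum
  # over many near-flat noisy samples would be biased low)
  jmin <- tail_idx[which.min(pd[tail_idx])]
  hw <- as.integer(round(0.010 * fs))
  bwin <- max(min(tail_idx), jmin - hw):min(max(tail_idx), jmin + hw)
  bdp <- mean(pd[bwin])

  # extremum times refined on the lightly smoothed series (the detection
  # series is kink-contaminated near the ejection departure); pressure peak
  # on the detection series with a wide window (the peak is broad)
  # derivative extrema: short window on the lightly smoothed series (the
  # region near an extremum is quickly contaminated by the ejection
  # departure); pressure peak: wide window scaled to the systolic width
  h_ext <- as.integer(round(0.005 * fs))
  h_pk <- max(5L, as.integer(round(0.35 * (imin - imax))))
  t_max <- (imax - 1L + ls_vertex(d, imax, h_ext)) / fs
  t_min <- (imin - 1L + ls_vertex(d, imin, h_ext)) / fs
  t_pk <- (ipk - 1L + ls_vertex_iter(pd, ipk, h_pk)) / fs
  rvsp <- p[ipk]

  if (!(t_ic < t_max && t_max < t_pk && t_pk < t_min && t_min < t_ir))
    fail("landmark ordering violated")
  if (!(rvsp >= edp && rvsp >= bdp)) fail("RVSP below diastolic pressures")

  t_beat0 <- waveform$t0 + (i0 - 1L) / fs
  structure(
    list(t_ic_start = t_beat0 + t_ic,
         t_dpdt_max = t_beat0 + t_max,
         t_rvsp = t_beat0 + t_pk,
         t_dpdt_min = t_beat0 + t_min,
         t_ir_end = t_beat0 + t_ir,
         rvsp = rvsp, bdp = bdp, edp = edp,
         dpdt_max = d[imax], dpdt_min = d[imin],
         idx_ic_start = i0 - 1L + idx_ic,
         idx_dpdt_max = i0 - 1L + imax,
         idx_rvsp = i0 - 1L + ipk,
         idx_dpdt_min = i0 - 1L + imin,
         idx_ir_end = i0 - 1L + idx_ir,
         beat_start = i0, beat_end = i1,
         cycle_len = (i1 - i0) / fs),
    class = "rv_landmarks"
  )
}

#' @export
print.rv_landmarks <- function(x, ...) {
  cat(sprintf(
    "Beat landmarks [%d,%d): IC %.3f..%.3f s, RVSP %.1f mm Hg @ %.3f s,\n",
    x$beat_start, x$beat_end, x$t_ic_start, x$t_dpdt_max, x$rvsp, x$t_rvsp))
  cat(sprintf(
    "  IR %.3f..%.3f s, EDP %.2f, BDP %.2f, dP/dt %+.0f/%+.0f mm Hg/s\n",
    x$t_dpdt_min, x$t_ir_end, x$edp, x$bdp, x$dpdt_max, x$dpdt_min))
  invisible(x)
}

# Extra zero-phase smoothing of the derivative and pressure used only to
# locate extrema and threshold crossings; attach as attr(dpdt, "detection")
# to avoid recomputation across beats.
detection_series <- function(waveform, dpdt, window_ms = 31) {
  n <- sg_window(waveform$sampling_rate, window_ms)
  structure(
    list(dpdt = signal::sgolayfilt(as.numeric(dpdt), p = 2, n = n, m = 0),
         pressure = smooth_pressure(waveform, window_ms)),
    window_ms = window_ms)
}

# Sub-sample offset of an extremum by a parabola through the three samples
# around index i; returns a value in (-1, 1), 0 at edges or degenerate cases.
parab_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (den == 0) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / den
  if (abs(off) >= 1) 0 else off
}

# Sub-sample extremum offset by a least-squares quadratic over a symmetric
# window of half-width h samples around i; falls back to the three-point
# parabola at edges or when the vertex leaves the window. Windowed fitting
# is essential on broad extrema, where a three-point vertex is noise-limited.
ls_vertex <- function(y, i, h) {
  lo <- i - h; hi <- i + h
  if (lo < 1L || hi > length(y)) return(parab_offset(y, i))
  x <- (-h):h
  fit <- stats::lm.fit(cbind(1, x, x * x), y[lo:hi])
  a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
  if (!is.finite(a) || a == 0) return(parab_offset(y, i))
  off <- unname(-b / (2 * a))
  if (abs(off) >= h) parab_offset(y, i) else off
}

# As ls_vertex, but recentring the window on the running vertex estimate;
# suitable for broad symmetric extrema (the systolic pressure peak) where
# the initial argmax may sit well off the true vertex.
ls_vertex_iter <- function(y, i, h) {
  i0 <- i
  for (iter in 1:5) {
    lo <- i - h; hi <- i + h
    if (lo < 1L || hi > length(y)) return(i - i0 + parab_offset(y, i))
    x <- (-h):h
    fit <- stats::lm.fit(cbind(1, x, x * x), y[lo:hi])
    a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
    if (!is.finite(a) || a == 0) return(i - i0 + parab_offset(y, i))
    off <- unname(-b / (2 * a))
    if (abs(off) < 0.5) return(i - i0 + off)
    step <- as.integer(round(max(-h, min(h, off))))
    if (step == 0L) return(i - i0 + off)
    i <- i + step
  }
  i - i0 + max(-h, min(h, off))
}

# Refined threshold-crossing location (fractional index) given the
# bracketing pair (j, j+1): least-squares line over a +/- h window solved
# for y = th, falling back to linear interpolation within the pair.
ls_crossing <- function(y, j, th, h, rising = TRUE) {
  f <- (th - y[j]) / (y[j + 1L] - y[j])
  x0 <- j + f
  lo <- j - h + 1L; hi <- j + h
  if (lo >= 1L && hi <= length(y)) {
    x <- lo:hi
    fit <- stats::lm.fit(cbind(1, x - j), y[x])
    slope <- fit$coefficients[2L]
    if (is.finite(slope) && ((rising && slope > 0) || (!rising && slope < 0))) {
      xc <- j + unname((th - fit$coefficients[1L]) / slope)
      if (abs(xc - x0) <= h) return(xc)
    }
  }
  x0
}

# Linear interpolation of series y at fractional index x.
interp_at <- function(y, x) {
  j <- floor(x)
  if (j < 1L) return(y[1L])
  if (j >= length(y)) return(y[length(y)])
  y[j] + (x - j) * (y[j + 1L] - y[j])
}
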