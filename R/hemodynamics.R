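#' Per-patient scalar hemodynamic record
#'
#' Bundles the scalar right-heart-catheterization measurements needed by the
#' pressure-volume estimation chain: pulmonary artery pressures, cardiac
#' output by one or both clinical methods, heart rate, and (optionally)
#' externally read diastolic RV pressures and external (e.g. CMR-derived)
#' volumes for the external-volume variant.
#'
#' @param mpap Mean pulmonary artery pressure (mm Hg), > 0.
#' @param spap Systolic pulmonary artery pressure (mm Hg), >= \code{mpap}.
#' @param hr Heart rate (beats/min), > 0.
#' @param co_thermo Cardiac output by thermodilution (L/min), optional.
#' @param co_fick Cardiac output by the indirect Fick method (L/min),
#'   optional; at least one CO must be present.
#' @param rvedp,rvbdp Optional externally measured end-/begin-diastolic RV
#'   pressures (mm Hg); when present they take precedence over
#'   waveform-derived EDP/BDP in [rv_pvloop()].
#' @param esv_cmr,edv_cmr Optional external end-systolic/end-diastolic
#'   volumes (mL), \code{edv_cmr > esv_cmr > 0}.
#' @param patient_id Optional label.
#' @return An object of class \code{rv_hemo}.
#' @export
hemo_record <- function(mpap, spap, hr, co_thermo = NULL, co_fick = NULL,
                        rvedp = NULL, rvbdp = NULL,
                        esv_cmr = NULL, edv_cmr = NULL, patient_id = NULL) {
  num1 <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x))
      stop(nm, " must be a single finite number", call. = FALSE)
    x
  }
  mpap <- num1(mpap, "mpap"); spap <- num1(spap, "spap"); hr <- num1(hr, "hr")
  co_thermo <- num1(co_thermo, "co_thermo"); co_fick <- num1(co_fick, "co_fick")
  rvedp <- num1(rvedp, "rvedp"); rvbdp <- num1(rvbdp, "rvbdp")
  esv_cmr <- num1(esv_cmr, "esv_cmr"); edv_cmr <- num1(edv_cmr, "edv_cmr")
  if (!(mpap > 0)) stop("mpap must be > 0", call. = FALSE)
  if (!(spap >= mpap)) stop("spap must be >= mpap", call. = FALSE)
  if (!(hr > 0)) stop("hr must be > 0", call. = FALSE)
  if (is.null(co_thermo) && is.null(co_fick))
    stop("at least one cardiac output (co_thermo or co_fick) is required",
         call. = FALSE)
  for (co in c(co_thermo, co_fick))
    if (!(co > 0)) stop("cardiac output must be > 0", call. = FALSE)
  if (!is.null(esv_cmr) || !is.null(edv_cmr)) {
    if (is.null(esv_cmr) || is.null(edv_cmr) ||
        !(edv_cmr > esv_cmr && esv_cmr > 0))
      stop("external volumes require edv_cmr > esv_cmr > 0", call. = FALSE)
  }
  structure(
    list(mpap = mpap, spap = spap, hr = hr,
         co_thermo = co_thermo, co_fick = co_fick,
         rvedp = rvedp, rvbdp = rvbdp,
         esv_cmr = esv_cmr, edv_cmr = edv_cmr, patient_id = patient_id),
    class = "rv_hemo"
  )
}

#' @export
print.rv_hemo <- function(x, ...) {
  cat("Hemodynamic record",
      if (!is.null(x$patient_id)) sprintf("[%s]", x$patient_id), "\n")
  cat(sprintf("  mPAP %g, sPAP %g mm Hg; HR %g /min; CO thermo %s, Fick %s L/min\n",
              x$mpap, x$spap, x$hr,
              if (is.null(x$co_thermo)) "-" else format(x$co_thermo),
              if (is.null(x$co_fick)) "-" else format(x$co_fick)))
  if (!is.null(x$rvedp) || !is.null(x$rvbdp))
    cat(sprintf("  measured RVEDP %s, RVBDP %s mm Hg\n",
                if (is.null(x$rvedp)) "-" else format(x$rvedp),
                if (is.null(x$rvbdp)) "-" else format(x$rvbdp)))
  if (!is.null(x$esv_cmr))
    cat(sprintf("  external volumes: ESV %g, EDV %g mL\n",
                x$esv_cmr, x$edv_cmr))
  invisible(x)
}

#' Stroke volume from cardiac output and heart rate
#'
#' SV = CO / HR, converted to millilitres.
#'
#' @param co Cardiac output (L/min), > 0.
#' @param hr Heart rate (beats/min), > 0.
#' @return Stroke volume (mL).
#' @export
#' @examples
#' stroke_volume(4.8, 60) # 80 mL
stroke_volume <- function(co, hr) {
  if (any(!is.finite(co)) || any(co <= 0))
    stop("cardiac output must be > 0", call. = FALSE)
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("heart rate must be > 0", call. = FALSE)
  1000 * co / hr
}

#' End-systolic pressure estimators
#'
#' \code{esp_mpap()} takes the mean pulmonary artery pressure itself as the
#' end-systolic pressure. \code{esp_modified()} refines it with the timing of
#' the RV pressure peak between the dP/dt extremes:
#' \deqn{ESP = mPAP + (sPAP - mPAP) \cdot
#'   \frac{t_{RVSP} - t_{dP/dt\,max}}{t_{dP/dt\,min} - t_{dP/dt\,max}}}
#' The time ratio lies in (0, 1) for a valid beat, so the modified estimate
#' is a convex combination of mPAP and sPAP.
#'
#' @param record An [hemo_record()] (for \code{esp_mpap}).
#' @param mpap,spap Mean and systolic pulmonary artery pressure (mm Hg).
#' @param t_rvsp,t_dpdt_max,t_dpdt_min Landmark times (s) from
#'   [locate_landmarks()], or any consistent clock.
#' @return ESP in mm Hg, with attribute \code{estimator}.
#' @export
#' @examples
#' esp_modified(16, 28, t_rvsp = 0.1, t_dpdt_max = 0, t_dpdt_min = 0.2) # 22
esp_mpap <- function(record) {
  structure(record$mpap, estimator = "mpap")
}

#' @rdname esp_mpap
#' @export
esp_modified <- function(mpap, spap, t_rvsp, t_dpdt_max, t_dpdt_min) {
  den <- t_dpdt_min - t_dpdt_max
  if (any(den <= 0))
    stop("landmark error: t_dpdt_min must exceed t_dpdt_max", call. = FALSE)
  ratio <- (t_rvsp - t_dpdt_max) / den
  structure(mpap + (spap - mpap) * ratio, estimator = "modified")
}

#' Normalized right-ventricular end-diastolic pressure
#'
#' Normalized RVEDP = EDP - BDP + 1 (mm Hg). Referencing the end-diastolic
#' to the begin-diastolic pressure removes the offset error introduced by
#' catheter positioning; the +1 places the begin-diastolic anchor of the
#' EDPVR at pressure 1.
#'
#' @param edp End-diastolic pressure (mm Hg).
#' @param bdp Begin-diastolic pressure (mm Hg).
#' @return EDP - BDP + 1, with logical attribute \code{nonphysiologic} set
#'   where the result is <= 1 (EDP at or below BDP): such values cannot
#'   anchor an exponential end-diastolic pressure-volume relationship and
#'   are flagged rather than rejected, so measurement problems stay visible.
#' @export
#' @examples
#' normalized_rvedp(7, 3) # 5
normalized_rvedp <- function(edp, bdp) {
  if (any(!is.finite(edp)) || any(!is.finite(bdp)))
    stop("edp and bdp must be finite", call. = FALSE)
  v <- edp - bdp + 1
  structure(v, nonphysiologic = v <= 1)
}
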