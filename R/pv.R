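#' Closed-form RV volumes and elastances from Pmax, ESP and SV
#'
#' Under the single-beat model the end-systolic pressure-volume relationship
#' (ESPVR) is the straight line through (ESV, ESP) and (EDV, Pmax), assumed
#' to pass through the origin (volume intercept V0 = 0). With
#' \code{EDV - ESV = SV} this gives the closed forms
#' \deqn{ESV = SV \cdot ESP / (P_{max} - ESP), \quad EDV = ESV + SV,}
#' \deqn{E_{es} = (P_{max} - ESP)/SV, \quad E_a = ESP/SV.}
#' Collinearity through the origin makes \eqn{E_{es} = ESP/ESV =
#' P_{max}/EDV}.
#'
#' @param p_max Isovolumic peak pressure from the sine fit (mm Hg).
#' @param esp End-systolic pressure (mm Hg), 0 < esp < p_max.
#' @param sv Stroke volume (mL), > 0.
#' @return A list with \code{esv}, \code{edv} (mL), \code{ees}, \code{ea}
#'   (mm Hg/mL).
#' @export
#' @examples
#' estimate_volumes(40, 20, 60) # esv = sv when p_max = 2*esp
estimate_volumes <- function(p_max, esp, sv) {
  if (!(is.finite(p_max) && is.finite(esp) && is.finite(sv)))
    stop("p_max, esp, sv must be finite", call. = FALSE)
  if (!(esp > 0)) stop("ESP must be > 0", call. = FALSE)
  if (!(sv > 0)) stop("SV must be > 0", call. = FALSE)
  if (!(p_max > esp))
    stop("Pmax must exceed ESP (failed sine fit or ESP overestimate?)",
         call. = FALSE)
  esv <- sv * esp / (p_max - esp)
  list(esv = esv, edv = esv + sv, ees = (p_max - esp) / sv, ea = esp / sv)
}

#' Fit the exponential end-diastolic pressure-volume relationship
#'
#' Finds the unique \eqn{(\alpha, \beta)} with \eqn{\beta > 0} such that the
#' curve \eqn{P = \alpha (e^{\beta V} - 1)} passes through the three points
#' (0, 0), (ESV, 1) and (EDV, normalized RVEDP). The origin is satisfied by
#' the model form; the two nontrivial anchors determine the parameters
#' exactly. \eqn{\beta} is the diastolic stiffness coefficient (1/mL).
#'
#' @details The anchor ratio \eqn{g(\beta) = (e^{\beta EDV} - 1)/(e^{\beta
#'   ESV} - 1)} is strictly increasing in \eqn{\beta} with limit EDV/ESV as
#'   \eqn{\beta \to 0^+}, so a solution with \eqn{\beta > 0} exists iff the
#'   normalized RVEDP exceeds EDV/ESV. The root is bracketed by doubling and
#'   polished by Brent's method to 1e-12 absolute; \eqn{\alpha =
#'   1/(e^{\beta ESV} - 1)} then enforces the ESV anchor exactly.
#'
#' @param esv End-systolic volume (mL), > 0.
#' @param edv End-diastolic volume (mL), > esv.
#' @param n_edp Normalized RVEDP (mm Hg), must exceed \code{edv/esv}.
#' @return A list with \code{alpha} (mm Hg) and \code{beta} (1/mL), both > 0.
#' @export
#' @examples
#' fit_edpvr(70, 140, 5) # beta = log(4)/70, alpha = 1/3
fit_edpvr <- function(esv, edv, n_edp) {
  n_edp <- as.numeric(n_edp)
  if (!(is.finite(esv) && is.finite(edv) && is.finite(n_edp)))
    stop("esv, edv, n_edp must be finite", call. = FALSE)
  if (!(esv > 0 && edv > esv))
    stop("volumes must satisfy edv > esv > 0", call. = FALSE)
  if (n_edp <= 1)
    stop("EDPVR degenerate: normalized RVEDP must exceed 1 (EDP <= BDP)",
         call. = FALSE)
  if (n_edp <= edv / esv)
    stop("EDPVR degenerate: normalized RVEDP at or below volume ratio EDV/ESV",
         call. = FALSE)
  g <- function(b) expm1(b * edv) / expm1(b * esv) - n_edp
  lo <- 1e-10
  if (g(lo) >= 0)   # root indistinguishable from the beta -> 0 limit
    stop("EDPVR degenerate: normalized RVEDP at or below volume ratio EDV/ESV",
         call. = FALSE)
  hi <- 1e-4
  while (g(hi) <= 0) {
    hi <- hi * 2
    if (hi * edv > 700)
      stop("EDPVR fit overflow: no physiologic beta below exp limit",
           call. = FALSE)
  }
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(alpha = 1 / expm1(beta * esv), beta = beta)
}

#' End-diastolic elastance from the fitted EDPVR
#'
#' The end-diastolic elastance is the slope of the exponential EDPVR at EDV:
#' \deqn{E_{ed} = \alpha \beta e^{\beta EDV}.}
#' Via the EDV anchor equation this equals \eqn{\beta (n_{EDP} + \alpha)}.
#'
#' @param alpha EDPVR curve-fitting constant (mm Hg), > 0.
#' @param beta Diastolic stiffness coefficient (1/mL), > 0.
#' @param edv End-diastolic volume (mL), > 0.
#' @return Eed in mm Hg/mL.
#' @export
#' @examples
#' compute_eed(1 / 3, log(4) / 70, 140) # ~0.1056
compute_eed <- function(alpha, beta, edv) {
  if (!(alpha > 0 && beta > 0 && edv > 0))
    stop("alpha, beta, edv must all be > 0", call. = FALSE)
  if (beta * edv > 700)
    stop("Eed overflow: beta * edv too large to be physiologic",
         call. = FALSE)
  alpha * beta * exp(beta * edv)
}

#' Evaluate the fitted EDPVR at given volumes
#'
#' @param alpha,beta EDPVR parameters from [fit_edpvr()].
#' @param volume Volumes (mL) at which to evaluate the curve.
#' @return Pressures \eqn{\alpha(e^{\beta V} - 1)} on the normalized scale
#'   (1 at ESV, normalized RVEDP at EDV).
#' @export
edpvr_pressure <- function(alpha, beta, volume) {
  alpha * expm1(beta * volume)
}
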