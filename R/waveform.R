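#' Construct an RV pressure waveform object
#'
#' A uniformly sampled right-ventricular pressure trace with sampling
#' metadata. This is the basic input container for beat segmentation,
#' landmark detection and the single-beat Pmax fit.
#'
#' @param pressure Numeric vector of pressure samples (mm Hg), length >= 2.
#' @param sampling_rate Sampling rate in Hz (samples per second), > 0.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param patient_id Optional opaque patient label.
#' @param channel_label Optional free-text channel description.
#'
#' @details Samples are uniformly spaced by construction: the time of sample
#'   \code{i} is \code{t0 + (i - 1) / sampling_rate}. Non-finite pressures are
#'   rejected. Pressures outside a physiologic gate of -20..200 mm Hg raise a
#'   warning (the values are kept unchanged; the gate flags likely unit or
#'   calibration problems, it does not clean data).
#'
#' @return An object of class \code{rv_waveform}: a list with elements
#'   \code{pressure}, \code{sampling_rate}, \code{t0}, \code{patient_id},
#'   \code{channel_label}.
#' @seealso [read_waveform_csv()], [segment_beats()], [rv_pvloop()]
#' @export
#' @examples
#' wf <- rv_waveform(10 + 5 * sin(2 * pi * seq(0, 1, by = 1e-3)), 1000)
#' duration(wf)
rv_waveform <- function(pressure, sampling_rate, t0 = 0,
                        patient_id = NULL, channel_label = NULL) {
  pressure <- as.numeric(pressure)
  if (length(pressure) < 2L)
    stop("waveform needs at least 2 samples", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  bad <- which(!is.finite(pressure))
  if (length(bad))
    stop("non-finite pressure values at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  if (any(pressure < -20 | pressure > 200))
    warning("pressure values outside physiologic gate (-20..200 mm Hg)",
            call. = FALSE)
  structure(
    list(pressure = pressure, sampling_rate = sampling_rate, t0 = t0,
         patient_id = patient_id, channel_label = channel_label),
    class = "rv_waveform"
  )
}

#' @export
print.rv_waveform <- function(x, ...) {
  cat("RV pressure waveform",
      if (!is.null(x$patient_id)) sprintf("[%s]", x$patient_id), "\n")
  cat(sprintf("  %d samples at %g Hz (%.3f s), range %.1f..%.1f mm Hg\n",
              length(x$pressure), x$sampling_rate, duration(x),
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Duration and sample times of a waveform
#'
#' @param waveform An \code{rv_waveform}.
#' @return \code{duration()}: total duration \code{(n - 1)/sampling_rate} in
#'   seconds. \code{sample_times()}: vector of sample times in seconds.
#' @export
duration <- function(waveform) {
  (length(waveform$pressure) - 1L) / waveform$sampling_rate
}

#' @rdname duration
#' @export
sample_times <- function(waveform) {
  waveform$t0 + (seq_along(waveform$pressure) - 1L) / waveform$sampling_rate
}

#' Read a digitized RV pressure waveform from CSV
#'
#' Reads the native polygraph-export dialect: a comma-separated, headered,
#' UTF-8 file with either columns \code{time_s,pressure_mmhg} (or any two
#' columns named via \code{time_col}/\code{pressure_col}) or a single
#' pressure column, in which case \code{sampling_rate} must be supplied.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate Sampling rate in Hz; required when the file has no
#'   time column, ignored (with a check) otherwise.
#' @param time_unit Unit of the time column: \code{"s"} (default) or
#'   \code{"ms"}.
#' @param time_col,pressure_col Column names; defaults \code{"time_s"} and
#'   \code{"pressure_mmhg"}. When the file has a single column it is taken as
#'   pressure regardless of its name.
#' @param patient_id Optional label stored on the waveform.
#'
#' @details When a time column is present the sampling rate is inferred from
#'   the median sample spacing; any spacing deviating from the median by more
#'   than 1\% is rejected as non-uniform (derivative-based landmark detection
#'   is sensitive to spacing, so no implicit resampling is done). Time must be
#'   strictly increasing.
#'
#' @return An \code{rv_waveform}.
#' @export
read_waveform_csv <- function(path, sampling_rate = NULL,
                              time_unit = c("s", "ms"),
                              time_col = "time_s",
                              pressure_col = "pressure_mmhg",
                              patient_id = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 0L || nrow(df) < 2L)
    stop("format error: CSV must have at least one column and two rows",
         call. = FALSE)

  if (ncol(df) == 1L) {
    pressure <- as.numeric(df[[1L]])
    if (is.null(sampling_rate))
      stop("format error: single-column CSV requires sampling_rate",
           call. = FALSE)
    fs <- sampling_rate
    t0 <- 0
  } else {
    if (!(time_col %in% names(df)) || !(pressure_col %in% names(df)))
      stop(sprintf("format error: expected columns '%s' and '%s' (found: %s)",
                   time_col, pressure_col, paste(names(df), collapse = ", ")),
           call. = FALSE)
    tm <- as.numeric(df[[time_col]])
    if (time_unit == "ms") tm <- tm / 1000
    if (anyNA(tm)) stop("format error: non-numeric time values", call. = FALSE)
    dt <- diff(tm)
    if (any(dt <= 0)) stop("format error: non-monotone time column",
                           call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("non-uniform sampling: time spacing deviates >1% from median",
           call. = FALSE)
    fs <- 1 / med
    # polygraph rates are integer Hz; snap away text round-trip error
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
    if (!is.null(sampling_rate) &&
        abs(fs - sampling_rate) > 0.01 * sampling_rate)
      stop(sprintf(paste("format error: inferred sampling rate %.6g Hz",
                         "disagrees with supplied %.6g Hz"), fs, sampling_rate),
           call. = FALSE)
    pressure <- as.numeric(df[[pressure_col]])
    t0 <- tm[1L]
  }

  bad <- which(!is.finite(pressure))
  if (length(bad))
    stop("validation error: NaN/non-finite pressure at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  rv_waveform(pressure, fs, t0 = t0, patient_id = patient_id)
}

#' Write a waveform to CSV in the native dialect
#'
#' Writes columns \code{time_s,pressure_mmhg}; \code{read_waveform_csv()} on
#' the result reproduces samples and sampling rate exactly (up to the text
#' round-trip at 15 significant digits).
#'
#' @param waveform An \code{rv_waveform}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  df <- data.frame(time_s = sample_times(waveform),
                   pressure_mmhg = waveform$pressure)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
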