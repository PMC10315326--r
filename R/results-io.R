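#' Write PV-loop estimates to JSON or CSV
#'
#' Serializes one or more [rv_pvloop()] estimates with unit-labelled keys
#' (\code{esv_ml}, \code{beta_per_ml}, \code{eed_mmhg_per_ml}, ...), method
#' tags and quality flags. JSON keeps full double precision, so a write/read
#' cycle reproduces every numeric field.
#'
#' @param estimates A single \code{rv_pvloop} or a list of them (may be
#'   empty: CSV then contains the header only, JSON an empty array).
#' @param path Output path.
#' @param format \code{"json"} or \code{"csv"} (default from the file
#'   extension, falling back to JSON).
#' @return The path, invisibly.
#' @export
write_results <- function(estimates, path, format = NULL) {
  if (inherits(estimates, "rv_pvloop")) estimates <- list(estimates)
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  df <- if (length(estimates))
    do.call(rbind, lapply(estimates, as.data.frame))
  else empty_estimate_row()
  if (format == "csv") {
    op <- options(digits = 15); on.exit(options(op))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

empty_estimate_row <- function() {
  data.frame(patient_id = character(0), p_max_mmhg = numeric(0),
             esp_mmhg = numeric(0), esp_method = character(0),
             sv_ml = numeric(0), sv_method = character(0),
             esv_ml = numeric(0), edv_ml = numeric(0),
             ees_mmhg_per_ml = numeric(0), ea_mmhg_per_ml = numeric(0),
             ees_over_ea = numeric(0), edp_mmhg = numeric(0),
             bdp_mmhg = numeric(0), n_edp_mmhg = numeric(0),
             alpha_mmhg = numeric(0), beta_per_ml = numeric(0),
             eed_mmhg_per_ml = numeric(0), volume_source = character(0),
             flags = character(0), stringsAsFactors = FALSE)
}

#' Read PV-loop estimates written by [write_results()]
#'
#' @param path Path to a JSON or CSV results file.
#' @return A data.frame with one row per estimate.
#' @export
read_results <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) df <- empty_estimate_row()
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}
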