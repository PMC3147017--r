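LABELING_COLS <- c("replicate_id", "compartment", "time_min", "frac32",
                   "below_loq")
COMPARTMENTS <- c("intracellular", "extracellular", "media_small_molecule")

#' Validate a labeling time-series table
#'
#' Checks the tidy table of 32S-fraction measurements used throughout the
#' estimation chain: columns `replicate_id`, `compartment` (one of
#' `intracellular`, `extracellular`, `media_small_molecule`), `time_min`
#' (minutes since labeling start, >= 0), `frac32` (32S fraction in `[0, 1]`)
#' and the logical flag `below_loq`.
#'
#' @param ts A data.frame of labeling measurements.
#' @return The validated data.frame, invisibly usable in pipelines.
#' @export
validate_labeling <- function(ts) {
  miss <- setdiff(LABELING_COLS, names(ts))
  if (length(miss) > 0) {
    stop("labeling series is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(ts$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ts$time_min) || any(!is.finite(ts$time_min)) ||
      any(ts$time_min < 0)) {
    stop("time_min must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(ts$frac32) || any(!is.finite(ts$frac32)) ||
      any(ts$frac32 < 0 | ts$frac32 > 1)) {
    stop("frac32 must lie in [0, 1]", call. = FALSE)
  }
  if (!is.logical(ts$below_loq)) {
    stop("below_loq must be logical", call. = FALSE)
  }
  ts
}

#' Read / write labeling time-series CSV
#'
#' One unambiguous CSV dialect: comma-separated, UTF-8, dot decimal, header
#' mandatory, times in minutes since labeling start.  Columns as in
#' [validate_labeling()].
#'
#' @param path File path.
#' @return `read_labeling_csv()` returns the validated data.frame.
#' @export
read_labeling_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ts <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LABELING_COLS, names(ts))
  if (length(miss) > 0) {
    stop("malformed labeling CSV ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(ts) == 0) {
    ts$time_min <- numeric(0)
    ts$frac32 <- numeric(0)
    ts$replicate_id <- character(0)
    ts$compartment <- character(0)
  }
  if (!is.numeric(ts$time_min) || !is.numeric(ts$frac32)) {
    stop("malformed labeling CSV ", path,
         ": time_min and frac32 must be numeric", call. = FALSE)
  }
  ts$below_loq <- as.logical(ts$below_loq)
  ts$replicate_id <- as.character(ts$replicate_id)
  validate_labeling(ts)
}

#' @rdname read_labeling_csv
#' @param ts A labeling time-series data.frame.
#' @export
write_labeling_csv <- function(ts, path) {
  if (nrow(ts) > 0) validate_labeling(ts)
  utils::write.csv(ts[LABELING_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
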