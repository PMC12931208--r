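#' Write / read a resonance trace as TSV
#'
#' Columns `time_s`, `dlambda_fm`, optionally `fwhm_fm`, plus `channel`.
#'
#' @param trace A [resonance_trace()].
#' @param path Output file.
#' @return `write_trace_tsv` returns `path` invisibly; `read_trace_tsv`
#'   returns a [resonance_trace()].
#' @export
write_trace_tsv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$channel <- attr(trace, "channel")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path)
  resonance_trace(df$time_s, df$dlambda_fm,
                  fwhm_fm = if ("fwhm_fm" %in% names(df)) df$fwhm_fm,
                  channel = if ("channel" %in% names(df)) df$channel[1L]
                            else "unpolarized")
}

#' Write / read an event table as CSV with a JSON metadata sidecar
#'
#' Columns `type`, `onset_s`, `amplitude_fm`, `tau_s`, `snr`; the detector's
#' noise estimate, frame interval and metadata go to `<path>.json`.
#'
#' @param table An `event_table`.
#' @param path Output CSV file.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   returns an `event_table`.
#' @export
write_events_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- list(sigma = attr(table, "sigma"),
               frame_interval = attr(table, "frame_interval"),
               metadata = attr(table, "metadata"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  structure(df, sigma = side$sigma, frame_interval = side$frame_interval,
            metadata = side$metadata,
            class = c("event_table", "data.frame"))
}

#' Write a ground truth to a JSON sidecar
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  payload <- list(events = truth$events,
                  params = truth$params[!vapply(truth$params, is.null,
                                                logical(1))],
                  seed = truth$seed,
                  short_duration = truth$short_duration)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Write a survivor curve as TSV
#'
#' @param curve A [survivor()] curve.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_survivor_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
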