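#' Write a simulated trace to CSV
#'
#' Fixed column order `t,AoP,MAoP,LVP,LAtP,CO,CVV,Sy,HR,LVV,ITP`, values at
#' 6 significant digits (the written precision round-trips through
#' [read_timeseries()]).
#'
#' @param trace a `cv_trace` (or data frame with the standard columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(trace, path) {
  miss <- setdiff(trace_columns, names(trace))
  if (length(miss))
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  cols <- lapply(trace_columns, function(cc) formatC(trace[[cc]], digits = 6,
                                                     format = "g"))
  lines <- c(paste(trace_columns, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trace written by [write_timeseries()]
#'
#' Validates the header (any missing standard column is named in the
#' error) and that every row parses as numeric; malformed rows are
#' reported with their line number.  Beat onsets are re-estimated from the
#' left-ventricular volume waveform since the CSV does not carry the
#' pacing log.
#'
#' @param path CSV path.
#' @return a `cv_trace`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("malformed CSV at line ", bad[1], ": expected ", nf[1],
         " fields, found ", nf[bad[1]])
  df <- utils::read.csv(path)
  miss <- setdiff(trace_columns, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[trace_columns]
  for (cc in trace_columns)
    if (!is.numeric(df[[cc]])) {
      row <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop("non-numeric value in column ", cc, " at line ", row + 1)
    }
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  structure(df, dt = dt, class = c("cv_trace", "data.frame"))
}
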