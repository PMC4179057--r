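fmt_ts <- function(ts) {
  format(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
}

parse_ts <- function(x) {
  op <- options(digits.secs = 6); on.exit(options(op))
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(out)) stopf("unparseable ISO-8601 timestamp(s): %s",
                        paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}

#' Read and write sensor event logs (JSONL)
#'
#' One JSON object per line with fields \code{ts} (ISO-8601 UTC),
#' \code{symbol}, \code{night_id} and optionally \code{source}. Reading
#' validates every line: malformed JSON and unknown symbols are reported
#' with their line numbers, and timestamps must be nondecreasing within
#' each night (violations report both timestamps). Writing then reading a
#' log reproduces the original records.
#'
#' @param path File path.
#' @param alphabet Permitted symbols (default [event_alphabet()]).
#' @param events data.frame with \code{ts}, \code{symbol}, \code{night_id}
#'   and optionally \code{source}.
#' @return \code{read_event_log}: data.frame \code{ts} (POSIXct UTC),
#'   \code{symbol}, \code{night_id}, \code{source}.
#' @export
read_event_log <- function(path, alphabet = event_alphabet()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines_idx <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(lines_idx))
  bad <- character(0)
  for (k in seq_along(lines_idx)) {
    i <- lines_idx[k]
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$ts) || is.null(rec$symbol)) {
      bad <- c(bad, sprintf("line %d: malformed record", i))
    } else if (!rec$symbol %in% alphabet) {
      bad <- c(bad, sprintf("line %d: unknown symbol '%s'", i, rec$symbol))
    } else {
      recs[[k]] <- data.frame(
        ts = rec$ts, symbol = rec$symbol,
        night_id = if (is.null(rec$night_id)) "night" else rec$night_id,
        source = if (is.null(rec$source)) NA_character_ else rec$source,
        stringsAsFactors = FALSE)
    }
  }
  if (length(bad))
    stopf("invalid event log %s:\n  %s", path, paste(bad, collapse = "\n  "))
  ev <- do.call(rbind, recs)
  ev$ts <- parse_ts(ev$ts)
  for (nid in unique(ev$night_id)) {
    t <- ev$ts[ev$night_id == nid]
    k <- which(diff(as.numeric(t)) < 0)
    if (length(k))
      stopf("out-of-order timestamps in night %s: %s followed by %s",
            nid, fmt_ts(t[k[1]]), fmt_ts(t[k[1] + 1]))
  }
  ev
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  n <- nrow(events)
  src <- if ("source" %in% names(events)) events$source else
    rep(NA_character_, n)
  nid <- rep_len(if ("night_id" %in% names(events))
    as.character(events$night_id) else "night", n)
  tss <- fmt_ts(events$ts)
  lines <- vapply(seq_len(n), function(i) {
    rec <- list(ts = tss[i], symbol = events$symbol[i], night_id = nid[i])
    if (!is.na(src[i])) rec$source <- src[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write load-cell logs (CSV)
#'
#' Columns \code{ts} (ISO-8601 UTC with microseconds) and \code{adc_out}
#' (signed integer ADC readout).
#'
#' @param path File path.
#' @param loadcell data.frame with \code{ts}, \code{adc_out}.
#' @return \code{read_loadcell}: data.frame \code{ts} (POSIXct UTC),
#'   \code{adc_out} (integer).
#' @export
read_loadcell <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ts", "adc_out") %in% names(df)))
    stopf("load-cell CSV %s must have columns ts, adc_out", path)
  data.frame(ts = parse_ts(df$ts), adc_out = as.integer(df$adc_out))
}

#' @rdname read_loadcell
#' @export
write_loadcell <- function(loadcell, path) {
  utils::write.csv(
    data.frame(ts = fmt_ts(loadcell$ts), adc_out = loadcell$adc_out),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
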