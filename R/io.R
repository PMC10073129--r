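## Trace and annotation persistence. The canonical container is a CSV with
## a '#'-prefixed key:value metadata header; annotations are JSON with
## 0-based half-open sample intervals.

#' Write a trace to its CSV container
#'
#' Header lines `# key: value` carry the acquisition metadata
#' (sampling_rate_hz, voltage_mv, filters, provenance); the single data
#' column is `current_pA`, printed with 17 significant digits so a
#' write-read round trip is bit-exact.
#'
#' @param trace an [IonTrace-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "IonTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.17g", samplingRate(trace)), con)
  writeLines(sprintf("# voltage_mv: %.17g", appliedVoltage(trace)), con)
  fstate <- filterState(trace)
  if (nrow(fstate))
    writeLines(sprintf("# filters: %s",
                       paste(sprintf("%s/%d/%.17g", fstate$type,
                                     fstate$poles, fstate$cutoff_hz),
                             collapse = ";")), con)
  if (nzchar(trace@provenance))
    writeLines(sprintf("# provenance: %s", trace@provenance), con)
  writeLines("current_pA", con)
  writeLines(sprintf("%.17g", traceCurrent(trace)), con)
  invisible(path)
}

#' Read a trace from its CSV container
#'
#' @param path file written by [writeTrace()] (or any CSV with the same
#'   header convention). A missing `sampling_rate_hz` header is a format
#'   error.
#' @return An [IonTrace-class].
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    meta[[trimws(key)]] <- val
  }
  if (is.null(meta$sampling_rate_hz))
    stop("trace container is missing required metadata field: ",
         "sampling_rate_hz")
  body <- lines[!grepl("^#", lines)]
  stopifnot(body[1] == "current_pA")
  cur <- as.numeric(body[-1])
  fstate <- NULL
  if (!is.null(meta$filters)) {
    parts <- strsplit(strsplit(meta$filters, ";")[[1]], "/")
    fstate <- data.frame(
      type = vapply(parts, `[`, "", 1),
      poles = as.integer(vapply(parts, `[`, "", 2)),
      cutoff_hz = as.numeric(vapply(parts, `[`, "", 3)))
  }
  IonTrace(cur, as.numeric(meta$sampling_rate_hz),
           voltage = if (is.null(meta$voltage_mv)) NA_real_
                     else as.numeric(meta$voltage_mv),
           filter_state = fstate,
           provenance = meta$provenance %||% "")
}

#' Write / read ground-truth or detected annotations as JSON
#'
#' Intervals are serialized as 0-based half-open sample indices, stated
#' in the JSON itself (`index_convention` field).
#'
#' @param annotation list with `events` and (optionally) `segments`
#'   data.frames, as produced by [generateEventTrain()].
#' @param path output path.
#' @return `path` (write) or the annotation list (read).
#' @export
writeAnnotation <- function(annotation, path) {
  payload <- c(list(index_convention = "0-based, half-open"), annotation)
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$index_convention <- NULL
  lapply(raw, as.data.frame)
}
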