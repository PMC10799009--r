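# Tabular serialization of stride streams.
#
# Two dialects:
#   * csv  — a directory of four files (streams.csv, strides.csv,
#            secondly.csv, turns.csv) that can hold any number of streams,
#            keyed by (recording_id, system).
#   * json — a single self-contained document per stream.
# Both carry a schema version string. Numeric values are written with 17
# significant digits so read(write(x)) reproduces every field bit-exactly.
# Missing per-second values are written as the literal sentinel "NA": a row
# with NA values means "measurement missing", an absent row means "no
# walking detected in that second".

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

stream_files <- c(streams = "streams.csv", strides = "strides.csv",
                  secondly = "secondly.csv", turns = "turns.csv")

#' Write stride streams to a CSV directory
#'
#' @param streams A list of `stride_stream` objects (or a single one).
#' @param dir Output directory; created if needed, files overwritten.
#' @return Invisibly, the directory path.
#' @seealso [read_stride_stream()], [write_stride_stream()]
#' @export
write_stride_streams <- function(streams, dir) {
  if (inherits(streams, "stride_stream")) streams <- list(streams)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- function(s) data.frame(recording_id = s$recording_id,
                                system = s$system,
                                stringsAsFactors = FALSE)
  meta <- do.call(rbind, lapply(streams, function(s)
    cbind(key(s), data.frame(participant_id = s$participant_id,
                             cohort = s$cohort, context = s$context,
                             duration_s = fmt_num(s$duration_s),
                             schema = SCHEMA_VERSION,
                             stringsAsFactors = FALSE))))
  strides <- do.call(rbind, lapply(streams, function(s) {
    st <- s$strides
    cbind(key(s)[rep(1, nrow(st)), , drop = FALSE],
          data.frame(participant_id = rep(s$participant_id, nrow(st)),
                     cohort = rep(s$cohort, nrow(st)),
                     context = rep(s$context, nrow(st)),
                     start_s = fmt_num(st$start_s), end_s = fmt_num(st$end_s),
                     laterality = st$laterality,
                     cadence_spm = fmt_num(st$cadence_spm),
                     stride_length_m = fmt_num(st$stride_length_m),
                     speed_mps = fmt_num(st$speed_mps),
                     stringsAsFactors = FALSE))
  }))
  secondly <- do.call(rbind, lapply(streams, function(s) {
    se <- s$secondly
    cbind(key(s)[rep(1, nrow(se)), , drop = FALSE],
          data.frame(second_index = se$second_index,
                     cadence_spm = fmt_num(se$cadence_spm),
                     stride_length_m = fmt_num(se$stride_length_m),
                     stringsAsFactors = FALSE))
  }))
  turns <- do.call(rbind, lapply(streams, function(s) {
    tu <- s$turns
    cbind(key(s)[rep(1, nrow(tu)), , drop = FALSE],
          data.frame(start_s = fmt_num(tu$start_s), end_s = fmt_num(tu$end_s),
                     stringsAsFactors = FALSE))
  }))
  tabs <- list(streams = meta, strides = strides,
               secondly = secondly, turns = turns)
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    if (is.null(tab)) {       # zero streams of this component anywhere
      tab <- data.frame()
    }
    utils::write.csv(tab, file.path(dir, stream_files[[nm]]),
                     row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(dir)
}

read_csv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(tab) == 0 && ncol(tab) == 0) return(NULL)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("parse error in ", basename(path), ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in numeric_cols) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "NA"))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric '%s' in column %s, row %d",
                   basename(path), raw[bad[1]], col, bad[1]), call. = FALSE)
    tab[[col]] <- val
  }
  tab
}

#' Read one stride stream
#'
#' @param path For `dialect = "csv"`, the directory written by
#'   [write_stride_streams()]; for `"json"`, a single-document file.
#' @param dialect `"csv"` or `"json"`.
#' @param recording_id,system Select one stream when the CSV directory holds
#'   several; may be omitted when the directory holds exactly one.
#' @param validate Validate the stream after reading (default `TRUE`).
#' @return A `stride_stream`.
#' @export
read_stride_stream <- function(path, dialect = c("csv", "json"),
                               recording_id = NULL, system = NULL,
                               validate = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "json") return(read_stream_json(path, validate))
  streams <- read_stride_streams(path, validate = validate)
  keys <- vapply(streams, function(s)
    paste(s$recording_id, s$system), "")
  if (!is.null(recording_id))
    streams <- streams[vapply(streams, function(s)
      s$recording_id == recording_id, TRUE)]
  if (!is.null(system))
    streams <- streams[vapply(streams, function(s)
      s$system == system, TRUE)]
  if (length(streams) == 0)
    stop("no stream matching the requested recording_id/system", call. = FALSE)
  if (length(streams) > 1)
    stop("directory holds several streams (", paste(keys, collapse = "; "),
         "); pass recording_id/system", call. = FALSE)
  streams[[1]]
}

#' Read every stride stream in a CSV directory
#'
#' @inheritParams read_stride_stream
#' @param dir Directory written by [write_stride_streams()].
#' @return A list of `stride_stream` objects, ordered by recording then
#'   system.
#' @export
read_stride_streams <- function(dir, validate = TRUE) {
  meta <- read_csv_checked(file.path(dir, "streams.csv"),
                           c("recording_id", "system", "participant_id",
                             "cohort", "context", "duration_s"),
                           "duration_s")
  if (is.null(meta)) return(list())
  strides <- read_csv_checked(file.path(dir, "strides.csv"),
                              c("recording_id", "system", "start_s", "end_s",
                                "laterality"),
                              c("start_s", "end_s", "cadence_spm",
                                "stride_length_m", "speed_mps"))
  secondly <- read_csv_checked(file.path(dir, "secondly.csv"),
                               c("recording_id", "system", "second_index",
                                 "cadence_spm", "stride_length_m"),
                               c("second_index", "cadence_spm",
                                 "stride_length_m"))
  turns <- read_csv_checked(file.path(dir, "turns.csv"),
                            c("recording_id", "system", "start_s", "end_s"),
                            c("start_s", "end_s"))
  pick <- function(tab, rid, sys, cols) {
    if (is.null(tab)) return(NULL)
    sel <- tab$recording_id == rid & tab$system == sys
    out <- tab[sel, cols, drop = FALSE]
    rownames(out) <- NULL
    out
  }
  lapply(seq_len(nrow(meta)), function(i) {
    rid <- meta$recording_id[i]; sys <- meta$system[i]
    st <- pick(strides, rid, sys,
               c("start_s", "end_s", "laterality", "cadence_spm",
                 "stride_length_m", "speed_mps"))
    se <- pick(secondly, rid, sys,
               c("second_index", "cadence_spm", "stride_length_m"))
    if (!is.null(se)) se$second_index <- as.integer(se$second_index)
    tu <- pick(turns, rid, sys, c("start_s", "end_s"))
    stride_stream(system = sys, recording_id = rid,
                  participant_id = meta$participant_id[i],
                  cohort = meta$cohort[i], context = meta$context[i],
                  duration_s = meta$duration_s[i],
                  strides = if (is.null(st)) empty_stride_df() else st,
                  secondly = if (is.null(se)) empty_secondly_df() else se,
                  turns = if (is.null(tu)) empty_turns_df() else tu,
                  validate = validate)
  })
}

#' Write one stride stream
#'
#' `read_stride_stream(write_stride_stream(x, ...))` reproduces `x`
#' bit-exactly for every field, in either dialect.
#'
#' @param stream A `stride_stream`.
#' @param path Target directory (csv) or file (json).
#' @param dialect `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_stride_stream <- function(stream, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") return(write_stride_streams(list(stream), path))
  doc <- list(schema = SCHEMA_VERSION,
              system = stream$system, recording_id = stream$recording_id,
              participant_id = stream$participant_id, cohort = stream$cohort,
              context = stream$context, duration_s = stream$duration_s,
              strides = stream$strides, secondly = stream$secondly,
              turns = stream$turns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", na = "null")
  invisible(path)
}

read_stream_json <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !identical(doc$schema, SCHEMA_VERSION))
    stop("parse error: unknown or missing schema string in ", basename(path),
         call. = FALSE)
  as_df <- function(x, template) {
    if (is.null(x) || (is.list(x) && length(x) == 0)) return(template)
    out <- template[0, , drop = FALSE]
    n <- length(x[[1]])
    for (col in names(template)) {
      v <- x[[col]]
      if (is.null(v)) v <- rep(NA, n)
      out[seq_len(n), col] <- v
    }
    out
  }
  se <- as_df(doc$secondly, empty_secondly_df())
  se$second_index <- as.integer(se$second_index)
  stride_stream(system = doc$system, recording_id = doc$recording_id,
                participant_id = doc$participant_id, cohort = doc$cohort,
                context = doc$context, duration_s = doc$duration_s,
                strides = as_df(doc$strides, empty_stride_df()),
                secondly = se,
                turns = as_df(doc$turns, empty_turns_df()),
                validate = validate)
}
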