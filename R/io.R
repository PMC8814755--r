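# Trace file formats: a self-describing two-column text dialect and a binary
# columnar dialect. Both carry sample_rate_hz, start_time_s, units and a
# schema version; binary round-trips bit-exactly, text keeps >= 15
# significant digits.

TRACE_MAGIC <- "MNPSBIN1"
TRACE_SCHEMA <- 1L

#' Write a current trace to disk
#'
#' @param trace An `mnps_trace`.
#' @param path Output file path.
#' @param format `"text"` (two tab-separated columns `time_s`, `current_a`
#'   after a commented header) or `"binary"` (little-endian doubles; value
#'   exact).
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(trace, path, format = c("text", "binary")) {
  stopifnot(inherits(trace, "mnps_trace"))
  format <- match.arg(format)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(TRACE_MAGIC, con, nchars = 8L, eos = NULL)
    writeBin(TRACE_SCHEMA, con, size = 4L, endian = "little")
    writeBin(c(trace$sample_rate, trace$start_time), con, size = 8L,
             endian = "little")
    writeBin(length(trace$samples), con, size = 4L, endian = "little")
    writeBin(trace$samples, con, size = 8L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# mnps-trace schema_version=%d", TRACE_SCHEMA),
                 sprintf("# sample_rate_hz: %.17g", trace$sample_rate),
                 sprintf("# start_time_s: %.17g", trace$start_time),
                 "# units: ampere",
                 "time_s\tcurrent_a"), con)
    t <- trace_times(trace)
    writeLines(sprintf("%.17g\t%.17g", t, trace$samples), con)
  }
  invisible(path)
}

#' Read a current trace from disk
#'
#' Auto-detects the dialect by magic bytes. The text dialect is validated for
#' header completeness and a uniform time column: any gap exceeding 1.5x the
#' nominal sampling period raises a format error that names the offending
#' line.
#'
#' @param path File written by [write_trace()] (either dialect).
#' @return An `mnps_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  con <- file(path, "rb")
  magic <- tryCatch(readChar(con, 8L, useBytes = TRUE), error = function(e) "")
  close(con)
  if (identical(magic, TRACE_MAGIC)) read_trace_binary(path)
  else read_trace_text(path)
}

read_trace_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8L, useBytes = TRUE)
  schema <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (schema != TRACE_SCHEMA)
    stop("unsupported trace schema version: ", schema, call. = FALSE)
  hdr <- readBin(con, "double", 2L, size = 8L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  x <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(x) != n)
    stop("truncated binary trace: expected ", n, " samples, read ", length(x),
         call. = FALSE)
  raw_trace(x, hdr[1], hdr[2], meta = list(source = path, dialect = "binary"))
}

read_trace_text <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || hdr_idx[1] != 1L)
    stop("trace format error: missing header block in ", path, call. = FALSE)
  hdr <- lines[hdr_idx]
  get_field <- function(name) {
    m <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
    if (length(m) == 0L)
      stop("trace format error: missing header field '", name, "' in ", path,
           call. = FALSE)
    sub(paste0("^#\\s*", name, ":\\s*"), "", m[1])
  }
  rate <- as.numeric(get_field("sample_rate_hz"))
  t0 <- as.numeric(get_field("start_time_s"))
  if (!is.finite(rate) || rate <= 0)
    stop("trace format error: invalid sample_rate_hz", call. = FALSE)
  body_start <- max(hdr_idx) + 1L
  if (grepl("^time_s", lines[body_start])) body_start <- body_start + 1L
  dat <- utils::read.table(text = lines[body_start:length(lines)],
                           col.names = c("time_s", "current_a"),
                           colClasses = "numeric")
  period <- 1 / rate
  if (nrow(dat) > 1L) {
    gaps <- diff(dat$time_s)
    bad <- which(gaps > 1.5 * period | gaps < 0.5 * period)
    if (length(bad))
      stop(sprintf(paste0("trace format error: non-uniform time column at ",
                          "line %d of %s (gap %.3g s, period %.3g s)"),
                   body_start + bad[1], path, gaps[bad[1]], period),
           call. = FALSE)
  }
  raw_trace(dat$current_a, rate, t0,
            meta = list(source = path, dialect = "text"))
}

write_tsv_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' @param path A TSV written by [run_pipeline()] (config-hash comment line,
#'   then a header and tab-separated columns).
#' @return A data.frame; the config hash is attached as attribute
#'   `config_hash`.
#' @export
read_pipeline_table <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- sub("^# config_hash:\\s*", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "config_hash") <- hash
  df
}
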