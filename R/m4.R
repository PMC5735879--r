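#' Write overlap records in the M4 dialect
#'
#' One space-separated line per record with 12 columns:
#' `qname tname score identity qstrand qstart qend qlen tstrand tstart
#' tend tlen`. Coordinates are 0-based half-open on the forward strands;
#' `qstrand` is always 0 (queries are scanned forward only) and
#' `tstrand = 1` means the target was reverse-complemented. `score` is
#' the matched-bp chain score and `identity` the seed-density estimate in
#' percent with two decimals. The dialect is named in a `#`-prefixed
#' header line that round-trip readers skip.
#'
#' @param records Overlap record data frame from [find_overlaps()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_m4 <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(
    "# seedoverlap m4-dialect v1:",
    "qname tname score identity qstrand qstart qend qlen",
    "tstrand tstart tend tlen"
  ), con)
  if (nrow(records)) {
    writeLines(sprintf(
      "%s %s %d %.2f 0 %d %d %d %d %d %d %d",
      records$query_name, records$ref_name, records$score,
      100 * records$identity, records$q_start, records$q_end,
      records$q_len, records$strand, records$r_start, records$r_end,
      records$r_len
    ), con)
  }
  invisible(path)
}

#' Read M4-dialect overlap records
#'
#' Parses the 12-column dialect written by [write_m4()] (header and
#' comment lines starting with `#` are skipped).
#'
#' @param path File to read.
#' @return Data frame with the M4 columns (`identity` converted back to a
#'   fraction).
#' @export
read_m4 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(
      query_name = character(), ref_name = character(), score = integer(),
      identity = numeric(), q_strand = integer(), q_start = integer(),
      q_end = integer(), q_len = integer(), strand = integer(),
      r_start = integer(), r_end = integer(), r_len = integer()
    ))
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 12L)) {
    stop("malformed M4 line ", which(n_fields != 12L)[1L], " in ", path,
      call. = FALSE
    )
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  data.frame(
    query_name = m[, 1L], ref_name = m[, 2L],
    score = as.integer(m[, 3L]), identity = as.numeric(m[, 4L]) / 100,
    q_strand = as.integer(m[, 5L]), q_start = as.integer(m[, 6L]),
    q_end = as.integer(m[, 7L]), q_len = as.integer(m[, 8L]),
    strand = as.integer(m[, 9L]), r_start = as.integer(m[, 10L]),
    r_end = as.integer(m[, 11L]), r_len = as.integer(m[, 12L])
  )
}
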