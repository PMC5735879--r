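#' Detect all-vs-all overlaps
#'
#' Production driver: indexes the reference set, scans every query read's
#' forward-strand k-mers, and runs the per-pair pipeline (strand choice,
#' consistent clustering, mu-3sigma filtering, k'-mer extension, final
#' validation). In self mode (`query_reads = NULL`) each unordered read
#' pair is examined once and reported with `query_id < ref_id`.
#'
#' The pipeline is a pure function of its inputs: repeated runs with the
#' same reads and configuration produce identical records, and the records
#' arrive sorted by (`query_id`, `ref_id`).
#'
#' @param reads Reference reads: a `"packed_reads"` object or character
#'   vector of sequences.
#' @param config An [overlap_config()] list.
#' @param query_reads Optional query set for two-set mode. When supplied,
#'   the low-count k-mer floor is lowered to 1: a k-mer supporting a
#'   cross-set match need not recur inside the reference set.
#' @return Data frame of overlap records, one per reported pair:
#'   `query_id`, `ref_id` (1-based), `query_name`, `ref_name`, `strand`
#'   (0 = forward, 1 = reference reverse-complemented), `q_start`,
#'   `q_end`, `q_len`, `r_start`, `r_end`, `r_len` (0-based half-open,
#'   forward-strand coordinates), `total_hits` (supporting k'-mers),
#'   `score` (matched bp) and `identity` (seed-density estimate).
#'   Attribute `report` carries run statistics.
#' @examples
#' g <- simulate_genome(5000, seed = 1)
#' reads <- c(a = substr(g, 1, 3000), b = substr(g, 1001, 5000))
#' find_overlaps(reads, overlap_config(min_kmer_count = 1))
#' @export
find_overlaps <- function(reads, config = overlap_config(),
                          query_reads = NULL) {
  ref_seqs <- as_seq_vector(reads)
  self_mode <- is.null(query_reads)
  query_seqs <- if (self_mode) character() else as_seq_vector(query_reads)
  ref_names <- read_names(ref_seqs)
  query_names <- if (self_mode) ref_names else read_names(query_seqs)
  # the low-count floor only makes sense when query copies live in the
  # same set as the reference copies
  floor <- if (self_mode) config$min_kmer_count else 1L
  df <- .cpp_overlap_all(
    unname(ref_seqs), unname(query_seqs), self_mode,
    pair_params(config), floor, config$min_olap_len
  )
  q_len <- if (self_mode) nchar(ref_seqs) else nchar(query_seqs)
  out <- data.frame(
    query_id = df$query_id, ref_id = df$ref_id,
    query_name = query_names[df$query_id], ref_name = ref_names[df$ref_id],
    strand = df$strand,
    q_start = df$q_start, q_end = df$q_end,
    q_len = unname(q_len)[df$query_id],
    r_start = df$r_start, r_end = df$r_end,
    r_len = unname(nchar(ref_seqs))[df$ref_id],
    total_hits = df$total_hits, score = df$score, identity = df$identity
  )
  attr(out, "report") <- list(
    n_ref_reads = length(ref_seqs),
    n_query_reads = if (self_mode) length(ref_seqs) else length(query_seqs),
    self_mode = self_mode,
    pairs_examined = attr(df, "pairs_examined"),
    overlaps_reported = nrow(out)
  )
  out
}

read_names <- function(seqs) {
  if (is.null(names(seqs))) sprintf("read%d", seq_along(seqs)) else
    unname(names(seqs))
}

#' Run the overlapper end to end
#'
#' Loads reads, detects overlaps, writes the M4-dialect output file and
#' logs a short run report to standard error.
#'
#' @param ref_path FASTA/FASTQ file with the reference read set.
#' @param out_path Output path for the M4-dialect records.
#' @param query_path Optional query read file; omitted means self-overlap
#'   mode.
#' @param config An [overlap_config()] list.
#' @return The overlap record data frame, invisibly.
#' @export
run_overlapper <- function(ref_path, out_path, query_path = NULL,
                           config = overlap_config()) {
  reads <- load_reads(ref_path)
  query <- if (!is.null(query_path)) load_reads(query_path)
  if (length(reads) == 0) {
    warning("no reads in ", ref_path, "; writing empty output")
    records <- find_overlaps(character(), config)
  } else {
    records <- find_overlaps(reads, config, query_reads = query)
  }
  write_m4(records, out_path)
  rep <- attr(records, "report")
  message(sprintf(
    paste0(
      "reads: %d reference, %d query (%s mode)\n",
      "pairs examined: %.0f; overlaps reported: %d\n",
      "output: %s"
    ),
    rep$n_ref_reads, rep$n_query_reads,
    if (rep$self_mode) "self" else "two-set",
    rep$pairs_examined, rep$overlaps_reported, out_path
  ))
  invisible(records)
}
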