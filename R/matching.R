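#' Collect seed matches for one query read
#'
#' Enumerates the k-mers of the query forward strand only, looks each up
#' in the reference index, and gathers the hits per reference read. For
#' every reference read with at least one hit, the strand with the larger
#' raw match count is chosen (tie broken towards forward) and the match
#' list for that strand is returned, sorted by (`qpos`, `rpos`) and
#' deduplicated.
#'
#' In self-overlap mode (`self = TRUE`) the query set is the reference
#' set; the pair of a read with itself is skipped and each unordered pair
#' is processed once, keeping reference ids strictly greater than
#' `query_id`.
#'
#' @param query A single sequence (character), or a `"packed_reads"`
#'   object together with `query_id` selecting the read.
#' @param index A `"kmer_index"` over the reference set.
#' @param query_id 1-based id of the query read (used for self mode and
#'   carried into the result).
#' @param self Logical; self-overlap mode.
#' @return A list of match lists, one per reference read with hits, each a
#'   list with `query_id`, `ref_id`, `strand` (0 forward / 1 reverse) and
#'   `matches`, a data frame of 0-based k-mer starts `qpos` (query forward
#'   strand) and `rpos` (chosen reference strand).
#' @export
collect_matches <- function(query, index, query_id = 1L, self = FALSE) {
  stopifnot(inherits(index, "kmer_index"))
  seq <- if (inherits(query, "packed_reads")) {
    sequences(query, ids = query_id)[[1L]]
  } else {
    as.character(query)[[1L]]
  }
  raw <- .cpp_collect_matches(index$ptr, seq, as.integer(query_id), self)
  lapply(raw, function(m) {
    list(
      query_id = as.integer(query_id), ref_id = m$ref_id,
      strand = m$strand, matches = m$matches
    )
  })
}

#' Choose the reference strand for a read pair
#'
#' The strand of the reference read carrying the strictly larger number of
#' raw k-mer matches wins; a tie goes to forward so that results are
#' deterministic.
#'
#' @param fwd_count,rev_count Non-negative match counts; at least one must
#'   be positive.
#' @return `"forward"` or `"reverse"`.
#' @examples
#' choose_strand(10, 3)
#' choose_strand(5, 5)
#' @export
choose_strand <- function(fwd_count, rev_count) {
  stopifnot(fwd_count >= 0, rev_count >= 0)
  if (fwd_count + rev_count < 1) {
    stop("at least one strand must have a match", call. = FALSE)
  }
  if (rev_count > fwd_count) "reverse" else "forward"
}
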