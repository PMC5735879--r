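#' Maximum alignment bounds under the indel tolerance
#'
#' Projects the seed bounds of the selected cluster outward, allowing for
#' the maximum amount of indel drift: each overhang on one read is scaled
#' by `1 + max_shift` when projected onto the other. For the dovetail
#' configuration where the query right end runs past the reference this
#' gives `queryStart = q_l - (1 + maxShift) * r_l` and
#' `refEnd = r_r + (1 + maxShift) * (querySize - q_r)`; the mirror
#' formulas cover the opposite overhang. All values are clamped to the
#' read extents.
#'
#' @param q_l,r_l Leftmost k-mer starts on query / oriented reference.
#' @param q_r,r_r Rightmost k-mer ends.
#' @param query_size,ref_size Read lengths.
#' @param max_shift Relative indel tolerance.
#' @return List with `query_start`, `query_end`, `ref_start`, `ref_end`
#'   (0-based, half-open window).
#' @examples
#' compute_max_bounds(1000, 500, 2000, 1500, 6000, 5000, 0.2)
#' @export
compute_max_bounds <- function(q_l, r_l, q_r, r_r, query_size, ref_size,
                               max_shift = 0.2) {
  .cpp_max_bounds(
    as.integer(q_l), as.integer(r_l), as.integer(q_r), as.integer(r_r),
    as.integer(query_size), as.integer(ref_size), max_shift
  )
}

#' Extend a seed cluster with k'-mer matches
#'
#' Starting from the selected cluster's bounds, k'-mer matches inside the
#' maximum-bound window are consumed in order of proximity to the current
#' boundary, on each side. A candidate that violates the adjacent drift
#' bound is skipped; after each accepted candidate the accumulated k'-mer
#' hits on that side must satisfy the mu-3sigma criterion (with `p`
#' computed from `small_k` and `L` the span covered so far), otherwise
#' extension on that side stops.
#'
#' @param query Query sequence (character, forward strand).
#' @param ref_oriented Reference sequence on the chosen strand (pass the
#'   reverse complement for reverse-strand pairs).
#' @param cluster_matches Data frame of the selected cluster's seed
#'   matches (`qpos`, `rpos`, 0-based starts on the two oriented reads).
#' @param params An [extension_params()] or [overlap_config()] list.
#' @return List with the extension window (`window`), the extended bounds
#'   `q_start`, `q_end`, `r_start`, `r_end` (on the oriented reference),
#'   and `total_hits`, the deduplicated k'-mer matches inside the final
#'   region.
#' @export
extend_alignment <- function(query, ref_oriented, cluster_matches,
                             params = extension_params()) {
  res <- pair_stage(query, ref_oriented, cluster_matches, params)
  res[c(
    "window", "q_start", "q_end", "r_start", "r_end", "total_hits"
  )]
}

#' Validate an extended overlap and emit its record
#'
#' Counts every k'-mer match across the final region (initial cluster plus
#' extensions, deduplicated by position) and applies the mu-3sigma
#' criterion with `p = (1 - e)^(2 k')` and `L` the final region length.
#' On success the overlap record is returned with 0-based half-open
#' coordinates on the oriented reference strand; on failure the pair is
#' rejected.
#'
#' @inheritParams extend_alignment
#' @return A one-row data frame (`q_start`, `q_end`, `r_start`, `r_end`,
#'   `total_hits`, `score`, `identity`, `threshold`) or `NULL` when the
#'   criterion fails.
#' @export
validate_overlap <- function(query, ref_oriented, cluster_matches,
                             params = extension_params()) {
  res <- pair_stage(query, ref_oriented, cluster_matches, params)
  if (!res$found) {
    return(NULL)
  }
  data.frame(
    q_start = res$q_start, q_end = res$q_end,
    r_start = res$r_start, r_end = res$r_end,
    total_hits = res$total_hits, score = res$score,
    identity = res$identity, threshold = res$final_threshold
  )
}

# internal: run the C++ pair pipeline on explicit matches
pair_stage <- function(query, ref_oriented, matches, params) {
  params <- as_pipeline_params(params)
  .cpp_pair_overlap(
    as.character(query)[[1L]], as.character(ref_oriented)[[1L]],
    as.integer(matches$qpos), as.integer(matches$rpos), params
  )
}

# internal: accept overlap_config / extension_params interchangeably
as_pipeline_params <- function(p) {
  k <- if (!is.null(p$k)) p$k else p$kmer_size
  list(
    k = as.integer(k), small_k = as.integer(p$small_k),
    max_shift = p$max_shift, error_rate = p$error_rate,
    max_kmer_count = as.integer(
      if (!is.null(p$max_kmer_count)) p$max_kmer_count else 10000L
    )
  )
}

#' Overlap a single read pair
#'
#' Runs the complete per-pair pipeline — seed matching with strand
#' choice, clustering, significance filtering, k'-mer extension and final
#' validation — for two reads given in forward orientation. Mostly a
#' debugging and testing surface; [find_overlaps()] is the production
#' driver.
#'
#' @param query,ref Sequences (character, forward strands).
#' @param config An [overlap_config()] list.
#' @return A one-row overlap record data frame (reference coordinates on
#'   its forward strand; `strand` 1 means the reference was
#'   reverse-complemented), or `NULL` when the pair does not overlap.
#' @export
overlap_pair <- function(query, ref, config = overlap_config()) {
  df <- .cpp_overlap_all(
    ref_seqs = as.character(ref)[[1L]],
    query_seqs = as.character(query)[[1L]], self_mode = FALSE,
    par = pair_params(config), min_kmer_count = 1L,
    min_olap_len = config$min_olap_len
  )
  if (nrow(df) == 0) NULL else df
}
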