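#' Partition seed matches into consistent clusters
#'
#' Greedy left-to-right partition of a sorted match array into maximal
#' consistent runs. Two consecutive matches `(q1, r1)`, `(q2, r2)` are
#' consistent when both coordinates are non-decreasing and the diagonal
#' drift `|(q2 - q1) - (r2 - r1)|` is at most
#' `max_shift * max(q2 - q1, r2 - r1)` — the relative indel tolerance. A
#' new cluster starts at the first match inconsistent with its
#' predecessor, so the clusters partition the array.
#'
#' @param V Data frame of seed matches with 0-based columns `qpos`,
#'   `rpos`. `cluster_matches()` expects (and enforces) the
#'   query-major sort order `(qpos, rpos)`; `recluster_on_failure()`
#'   re-sorts reference-major `(rpos, qpos)` and re-runs the same
#'   partition, the fallback used when the first pass yields no cluster
#'   that survives the significance filter.
#' @param params A [chain_params()] list.
#' @return A data frame with one row per cluster: `left_idx`, `right_idx`
#'   (1-based index range into the sorted `V`), `matched_bp` (query bases
#'   covered by the union of member k-mers) and `hit_count`.
#'   `recluster_on_failure()` returns `list(V = re-sorted matches,
#'   clusters = ...)` since the index ranges refer to the new order.
#' @examples
#' V <- data.frame(qpos = c(0, 20, 40), rpos = c(0, 20, 40))
#' cluster_matches(V, chain_params(kmer_size = 16))
#' @export
cluster_matches <- function(V, params = chain_params()) {
  V <- as.data.frame(V)
  if (nrow(V) == 0) {
    return(data.frame(
      left_idx = integer(), right_idx = integer(),
      matched_bp = integer(), hit_count = integer()
    ))
  }
  ord <- order(V$qpos, V$rpos)
  V <- V[ord, , drop = FALSE]
  .cpp_cluster_matches(
    as.integer(V$qpos), as.integer(V$rpos),
    params$kmer_size, params$max_shift
  )
}

#' @rdname cluster_matches
#' @export
recluster_on_failure <- function(V, params = chain_params()) {
  V <- as.data.frame(V)
  ord <- order(V$rpos, V$qpos)
  V <- V[ord, , drop = FALSE]
  rownames(V) <- NULL
  clusters <- if (nrow(V) == 0) {
    cluster_matches(V, params)
  } else {
    .cpp_cluster_matches(
      as.integer(V$qpos), as.integer(V$rpos),
      params$kmer_size, params$max_shift
    )
  }
  list(V = V, clusters = clusters)
}

#' Select the cluster to carry forward
#'
#' The cluster with the maximum number of matching base pairs wins; ties
#' go to the larger hit count, then to the leftmost cluster on the query.
#'
#' @param clusters Cluster data frame from [cluster_matches()].
#' @param V The sorted match data frame the index ranges refer to (only
#'   needed to resolve the leftmost-on-query tie-break; optional).
#' @return The selected cluster as a one-row data frame, or `NULL` for an
#'   empty input (the no-overlap signal).
#' @export
select_best_cluster <- function(clusters, V = NULL) {
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(NULL)
  }
  q_left <- if (!is.null(V)) V$qpos[clusters$left_idx] else clusters$left_idx
  ord <- order(-clusters$matched_bp, -clusters$hit_count, q_left)
  clusters[ord[1L], , drop = FALSE]
}

#' Binomial significance floor on seed counts
#'
#' The number of seed hits in a genuine overlap of length `L` is modelled
#' as binomial with `L` trials and per-position seed survival probability
#' `p = (1 - e)^(2k)` (each of the `2k` bases involved in a k-mer pair
#' must be error-free). Overlaps with fewer hits than
#' `mu - 3 sigma = L p - 3 sqrt(L p (1 - p))` are eliminated as too
#' dissimilar. A non-positive value means no floor applies.
#'
#' @param L Alignment length estimate(s) in bases (trials).
#' @param e Per-base error rate in `(0, 1)` (0 is allowed: the threshold
#'   degenerates to `L`).
#' @param k Seed length in bases.
#' @return Numeric vector of thresholds, one per `L`.
#' @examples
#' binomial_threshold(5000, 0.15, 16) # ~11.9, so >= 12 hits required
#' @export
binomial_threshold <- function(L, e, k) {
  stopifnot(all(L >= 1), e >= 0, e < 1, k >= 1)
  .cpp_binomial_threshold(as.numeric(L), e, as.integer(k))
}

#' Seed-bound statistics for a selected cluster
#'
#' Computes the seed bounds of a cluster (leftmost k-mer starts `q_L`,
#' `r_L`; rightmost k-mer ends `q_R`, `r_R`), the alignment length
#' estimate `L`, the seed survival probability `p`, and the mu-3sigma hit
#' floor. `L` is the chained span plus, on each side, the shorter of the
#' two read overhangs — the projection of a dovetail overlap that reduces
#' to `r_R + querySize - q_R` when the query right end runs past the
#' reference.
#'
#' @param cluster One-row cluster data frame (from
#'   [select_best_cluster()]).
#' @param V The sorted match data frame the cluster indexes.
#' @param query_size,ref_size Read lengths in bases.
#' @param params A [chain_params()] list.
#' @return A list with `q_l`, `q_r`, `r_l`, `r_r`, `L`, `p` and
#'   `threshold`.
#' @export
overlap_stats <- function(cluster, V, query_size, ref_size,
                          params = chain_params()) {
  stopifnot(nrow(cluster) == 1)
  k <- params$kmer_size
  idx <- seq.int(cluster$left_idx, cluster$right_idx)
  q_l <- min(V$qpos[idx])
  r_l <- min(V$rpos[idx])
  q_r <- max(V$qpos[idx]) + k
  r_r <- max(V$rpos[idx]) + k
  span <- max(q_r - q_l, r_r - r_l)
  L <- span + min(q_l, r_l) + min(query_size - q_r, ref_size - r_r)
  list(
    q_l = q_l, q_r = q_r, r_l = r_l, r_r = r_r, L = L,
    p = (1 - params$error_rate)^(2 * k),
    threshold = binomial_threshold(L, params$error_rate, k)
  )
}

#' Apply the mu-3sigma filter to a cluster
#'
#' @param cluster One-row cluster data frame.
#' @param stats Output of [overlap_stats()] for that cluster.
#' @return `TRUE` (pass) when the hit count reaches the floor, else
#'   `FALSE`.
#' @export
binomial_filter <- function(cluster, stats) {
  stopifnot(nrow(cluster) == 1)
  cluster$hit_count >= stats$threshold
}
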