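#' Parameter sets for the overlap pipeline
#'
#' Constructors for the parameter groups used by the pipeline stages.
#' `index_params()` controls k-mer indexing of the reference set,
#' `chain_params()` the clustering / significance stage, and
#' `extension_params()` the second-pass k'-mer extension.
#' `overlap_config()` bundles everything a full run needs.
#'
#' @param k Integer k-mer length for the first seeding pass (default 16;
#'   must be in `[1, 32]` so a k-mer fits one machine word).
#' @param max_kmer_count Occurrence ceiling: k-mer values occurring more
#'   than this many times across both strands of the reference set are
#'   ignored (default 10000).
#' @param min_kmer_count Occurrence floor: k-mer values occurring fewer
#'   than this many times are ignored (default 2). In two-set mode
#'   [find_overlaps()] lowers the effective floor to 1, because a k-mer
#'   supporting a true cross-set match need not recur within the reference
#'   set alone.
#' @param kmer_size Integer k used when clustering (equals the index `k`).
#' @param max_shift Relative indel-drift tolerance, in `(0, 1)`
#'   (default 0.2): adjacent seed matches are consistent when the
#'   difference of their query and reference gaps is at most
#'   `max_shift * max(gap_q, gap_r)`.
#' @param error_rate Expected per-base error rate `e` used in the seed
#'   survival probability `p = (1 - e)^(2k)` (default 0.15).
#' @param small_k Integer k' for the extension pass (default 12; must be
#'   smaller than `k`).
#' @param min_olap_len Minimum reported overlap span in bases (default 100).
#' @param threads Reserved; the pipeline is a pure function of its inputs
#'   and computes identical output for any value.
#'
#' @return A named list of validated parameters with class
#'   `"seedoverlap_params"`.
#' @examples
#' overlap_config(k = 16, small_k = 12)
#' @name parameters
NULL

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (if (lo_open) x <= lo else x < lo) ||
    (if (hi_open) x >= hi else x > hi)
  if (bad) {
    stop(sprintf(
      "`%s` must be a single number in %s%s, %s%s", name,
      if (lo_open) "(" else "[", format(lo), format(hi),
      if (hi_open) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

#' @rdname parameters
#' @export
index_params <- function(k = 16L, max_kmer_count = 10000L,
                         min_kmer_count = 2L) {
  check_range(k, "k", 1, 32)
  check_range(max_kmer_count, "max_kmer_count", 1, Inf)
  check_range(min_kmer_count, "min_kmer_count", 1, max_kmer_count)
  structure(
    list(
      k = as.integer(k),
      max_kmer_count = as.integer(max_kmer_count),
      min_kmer_count = as.integer(min_kmer_count)
    ),
    class = "seedoverlap_params"
  )
}

#' @rdname parameters
#' @export
chain_params <- function(kmer_size = 16L, max_shift = 0.2,
                         error_rate = 0.15) {
  check_range(kmer_size, "kmer_size", 1, 32)
  check_range(max_shift, "max_shift", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range(error_rate, "error_rate", 0, 1, lo_open = TRUE, hi_open = TRUE)
  structure(
    list(
      kmer_size = as.integer(kmer_size),
      max_shift = max_shift,
      error_rate = error_rate
    ),
    class = "seedoverlap_params"
  )
}

#' @rdname parameters
#' @export
extension_params <- function(small_k = 12L, kmer_size = 16L, max_shift = 0.2,
                             error_rate = 0.15) {
  check_range(small_k, "small_k", 1, kmer_size - 1)
  chain <- chain_params(kmer_size, max_shift, error_rate)
  structure(c(list(small_k = as.integer(small_k)), unclass(chain)),
    class = "seedoverlap_params"
  )
}

#' @rdname parameters
#' @export
overlap_config <- function(k = 16L, small_k = 12L, max_shift = 0.2,
                           error_rate = 0.15, max_kmer_count = 10000L,
                           min_kmer_count = 2L, min_olap_len = 100L,
                           threads = 1L) {
  idx <- index_params(k, max_kmer_count, min_kmer_count)
  ext <- extension_params(small_k, k, max_shift, error_rate)
  check_range(min_olap_len, "min_olap_len", 0, Inf)
  check_range(threads, "threads", 1, Inf)
  structure(
    list(
      k = idx$k, small_k = ext$small_k, max_shift = ext$max_shift,
      error_rate = ext$error_rate, max_kmer_count = idx$max_kmer_count,
      min_kmer_count = idx$min_kmer_count,
      min_olap_len = as.integer(min_olap_len), threads = as.integer(threads)
    ),
    class = "seedoverlap_params"
  )
}

#' @export
print.seedoverlap_params <- function(x, ...) {
  cat("<seedoverlap parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# internal: the parameter list handed to the C++ pair pipeline
pair_params <- function(config) {
  list(
    k = config$k, small_k = config$small_k, max_shift = config$max_shift,
    error_rate = config$error_rate, max_kmer_count = config$max_kmer_count
  )
}
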