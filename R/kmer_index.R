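#' Build the reference k-mer occurrence index
#'
#' Indexes every k-mer of both strands of every reference read, then drops
#' k-mer values whose total occurrence count (summed over strands and
#' reads) exceeds `max_kmer_count` or falls below `min_kmer_count`.
#' High-frequency k-mers carry repeat noise; singleton k-mers cannot
#' support an overlap in self mode, where every genuinely shared k-mer is
#' present at least twice.
#'
#' @param reads A `"packed_reads"` object (the reference set), or a
#'   character vector of sequences.
#' @param params An [index_params()] list.
#' @return An object of class `"kmer_index"` holding the occurrence map
#'   (in memory only), the parameters, and per-build statistics.
#' @examples
#' idx <- build_kmer_index(c(r1 = "ACGTACGTACGTACGTACGT"),
#'   params = index_params(k = 4, min_kmer_count = 1)
#' )
#' kmer_lookup(idx, "ACGT")
#' @export
build_kmer_index <- function(reads, params = index_params()) {
  seqs <- if (inherits(reads, "packed_reads")) sequences(reads) else
    as.character(reads)
  ptr <- .cpp_build_index(
    unname(seqs), params$k, params$max_kmer_count, params$min_kmer_count
  )
  structure(
    list(
      ptr = ptr, params = params, n_reads = length(seqs),
      read_names = if (is.null(names(seqs))) {
        sprintf("read%d", seq_along(seqs))
      } else {
        names(seqs)
      },
      read_lengths = unname(nchar(seqs)),
      stats = .cpp_index_stats(ptr)
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    paste0(
      "<kmer_index> k=%d over %d read(s)\n",
      "  %.0f retained k-mer values, %.0f occurrences\n",
      "  filtered: %.0f high-frequency, %.0f low-frequency values\n"
    ),
    s$k, s$n_reads, s$n_kmer_values, s$n_occurrences,
    s$n_filtered_high, s$n_filtered_low
  ))
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index A `"kmer_index"`.
#' @param kmer A base string of length `params$k`.
#' @return A data frame with one row per retained occurrence: `read_id`
#'   (1-based), `pos` (0-based start on the annotated strand) and `strand`
#'   (0 forward, 1 reverse complement), ordered by
#'   (`read_id`, `strand`, `pos`). Filtered or absent k-mers give zero
#'   rows.
#' @export
kmer_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  kmer <- toupper(as.character(kmer)[[1L]])
  if (nchar(kmer) != index$params$k) {
    stop("k-mer length ", nchar(kmer), " does not match index k = ",
      index$params$k,
      call. = FALSE
    )
  }
  .cpp_index_lookup(index$ptr, kmer)
}
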