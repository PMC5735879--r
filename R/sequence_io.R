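#' Load reads into packed two-bit form
#'
#' Parses a FASTA or FASTQ file (plain or gzip) and stores every read two
#' bits per base, together with its materialized reverse complement, so both
#' strands can be scanned without re-complementing. Sequence names are kept
#' verbatim up to the first whitespace. FASTQ qualities are read and
#' discarded; the overlap method never uses them.
#'
#' Non-ACGT handling: lowercase is uppercased; any other character (N,
#' IUPAC ambiguity codes, ...) is deterministically replaced by `A` and
#' counted in a per-read tally, reported once as a warning. The two-bit
#' alphabet has no fifth symbol, and a deterministic replacement keeps runs
#' reproducible.
#'
#' @param path Path to the read file.
#' @param format `"auto"` (default, by file extension), `"fasta"` or
#'   `"fastq"`.
#' @return An object of class `"packed_reads"`: a list with elements
#'   `name`, `length`, `forward` and `reverse` (lists of packed raw
#'   vectors), and `n_replaced` (non-ACGT characters replaced per read).
#'   Read ids are the 1-based file ordinals.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "TTTTACGT"), fa)
#' reads <- load_reads(fa)
#' sequences(reads)
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub("\\.(gz|bgz)$", "", basename(path)))
    format <- if (grepl("\\.(fq|fastq)$", ext)) "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  pack_reads(seqs)
}

# internal: pack a named character vector of sequences
pack_reads <- function(seqs) {
  if (length(seqs) && any(!nzchar(seqs))) {
    stop("zero-length sequence in record ",
      which(!nzchar(seqs))[1L],
      call. = FALSE
    )
  }
  fwd <- vector("list", length(seqs))
  rev <- vector("list", length(seqs))
  n_replaced <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    code <- .cpp_encode_2bit(seqs[[i]])
    n_replaced[i] <- attr(code, "n_replaced")
    fwd[[i]] <- code
    rev[[i]] <- .cpp_encode_2bit(.cpp_revcomp(.cpp_decode_2bit(
      code, nchar(seqs[[i]])
    )))
  }
  if (any(n_replaced > 0L)) {
    warning(
      sum(n_replaced), " non-ACGT character(s) replaced by 'A' in ",
      sum(n_replaced > 0L), " read(s)",
      call. = FALSE
    )
  }
  structure(
    list(
      name = if (is.null(names(seqs))) {
        sprintf("read%d", seq_along(seqs))
      } else {
        unname(names(seqs))
      },
      length = unname(nchar(seqs)),
      forward = fwd,
      reverse = rev,
      n_replaced = n_replaced
    ),
    class = "packed_reads"
  )
}

#' @export
length.packed_reads <- function(x) length(x$name)

#' @export
print.packed_reads <- function(x, ...) {
  cat(sprintf(
    "<packed_reads> %d read(s), %.0f bases total\n",
    length(x), sum(as.numeric(x$length))
  ))
  invisible(x)
}

#' Decode packed reads back to base strings
#'
#' @param reads A `"packed_reads"` object.
#' @param strand `"forward"` or `"reverse"` (the reverse complement).
#' @param ids Read ids to decode (default all).
#' @return Named character vector of sequences.
#' @export
sequences <- function(reads, strand = c("forward", "reverse"),
                      ids = seq_len(length(reads))) {
  stopifnot(inherits(reads, "packed_reads"))
  strand <- match.arg(strand)
  src <- if (strand == "forward") reads$forward else reads$reverse
  out <- vapply(
    ids, function(i) .cpp_decode_2bit(src[[i]], reads$length[i]), ""
  )
  names(out) <- reads$name[ids]
  out
}

#' Watson-Crick reverse complement
#'
#' @param seq Character vector of ACGT sequences (non-ACGT characters are
#'   complemented as if they were `A`).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  vapply(as.character(seq), .cpp_revcomp, "", USE.NAMES = FALSE)
}

#' Two-bit encoding primitives
#'
#' `encode_2bit()` packs an ACGT string four bases per byte (A=0, C=1,
#' G=2, T=3, so that complement equals `3 - code`); non-ACGT characters
#' are encoded as `A` and counted in the `n_replaced` attribute.
#' `decode_2bit()` is the exact inverse for the stored length.
#'
#' @param seq A single base string.
#' @param code A raw vector produced by `encode_2bit()`.
#' @param length Number of bases to decode; must not exceed the stored
#'   capacity of `code`.
#' @return `encode_2bit()`: raw vector with attributes `n_bases` and
#'   `n_replaced`; `decode_2bit()`: the base string.
#' @examples
#' decode_2bit(encode_2bit("ACGT"), 4)
#' @export
encode_2bit <- function(seq) .cpp_encode_2bit(as.character(seq)[[1L]])

#' @rdname encode_2bit
#' @export
decode_2bit <- function(code, length) {
  .cpp_decode_2bit(code, as.integer(length))
}
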