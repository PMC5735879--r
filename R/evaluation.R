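#' Evaluation configuration
#'
#' Settings for the alignment-validated evaluation of an overlap record
#' set: minimum alignment length (analysis floor), number of sampled
#' trials, the relative tolerance used when comparing lengths and bounds,
#' the correctness mode, the Smith-Waterman scoring scheme and the
#' "good alignment" identity floor for the optimal alignment.
#'
#' @param min_align_len Minimum alignment length considered (default
#'   2000 bases).
#' @param trials Maximum number of sampled pairs per estimate (default
#'   50000).
#' @param bound_tolerance Relative slack when comparing lengths/bounds
#'   against the optimal alignment (default 0.2).
#' @param mode Correctness mode: `"presence"` (the pair was reported),
#'   `"length"` (also length and direction agree with the optimal
#'   alignment) or `"bounds"` (additionally all four boundary endpoints
#'   agree) — strictly nested criteria.
#' @param seed RNG seed for the pair sampling.
#' @param good_identity Identity floor over the optimal aligned interval
#'   for it to count as a good alignment (default 0.6).
#' @param match,mismatch,gap Smith-Waterman scores (defaults +2/-3/-5).
#' @return A validated list of class `"seedoverlap_params"`.
#' @export
eval_config <- function(min_align_len = 2000L, trials = 50000L,
                        bound_tolerance = 0.2,
                        mode = c("bounds", "length", "presence"),
                        seed = 1L, good_identity = 0.6, match = 2L,
                        mismatch = -3L, gap = -5L) {
  mode <- match.arg(mode)
  check_range(trials, "trials", 1, Inf)
  check_range(bound_tolerance, "bound_tolerance", 0, 1, hi_open = TRUE)
  structure(
    list(
      min_align_len = as.integer(min_align_len),
      trials = as.integer(trials), bound_tolerance = bound_tolerance,
      mode = mode, seed = as.integer(seed), good_identity = good_identity,
      match = as.integer(match), mismatch = as.integer(mismatch),
      gap = as.integer(gap)
    ),
    class = "seedoverlap_params"
  )
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Exact local alignment under linear gap penalties. Ties on the score
#' are broken towards the smallest end coordinates. Memory stays linear
#' in the read lengths: the end is found score-only, the start by a
#' score-only pass on the reversed prefixes, and only the optimal span is
#' traced back.
#'
#' @param a,b Base strings.
#' @param match,mismatch,gap Scoring scheme (defaults +2/-3/-5).
#' @return List with `score`, 0-based half-open intervals `a_start`,
#'   `a_end`, `b_start`, `b_end`, and `matches`, `columns`, `gaps`,
#'   `identity` over the aligned interval. A best score of 0 yields an
#'   empty alignment.
#' @examples
#' smith_waterman("ACGT", "ACGT")$score # 8
#' @export
smith_waterman <- function(a, b, match = 2L, mismatch = -3L, gap = -5L) {
  .cpp_smith_waterman(
    as.character(a)[[1L]], as.character(b)[[1L]],
    as.integer(match), as.integer(mismatch), as.integer(gap)
  )
}

# internal: best-direction optimal alignment; the direction is chosen on
# score-only passes and only the winner is completed; reverse coordinates
# are flipped back to the target's forward strand
align_best_direction <- function(a, b, config) {
  brc <- .cpp_revcomp(b)
  sf <- .cpp_sw_score(a, b, config$match, config$mismatch, config$gap)
  sr <- .cpp_sw_score(a, brc, config$match, config$mismatch, config$gap)
  if (sr$score > sf$score) {
    rev <- .cpp_sw_finish(
      a, brc, sr$score, sr$a_end, sr$b_end,
      config$match, config$mismatch, config$gap
    )
    n <- nchar(b)
    flip <- rev
    flip$b_start <- n - rev$b_end
    flip$b_end <- n - rev$b_start
    flip$direction <- 1L
    flip
  } else {
    fwd <- .cpp_sw_finish(
      a, b, sf$score, sf$a_end, sf$b_end,
      config$match, config$mismatch, config$gap
    )
    fwd$direction <- 0L
    fwd
  }
}

#' Validate one reported overlap against the optimal alignment
#'
#' Re-implements the alignment check used throughout the evaluation: the
#' optimal local alignment between the two reads is computed (both
#' directions, best score kept) and must be a good alignment — span at
#' least `min_align_len` and identity at least `good_identity`. The
#' reported record is then compared with the optimal one under the three
#' nested modes: presence (nothing further), length (span within
#' `bound_tolerance` of the optimal span, same direction) and bounds
#' (every boundary endpoint within `bound_tolerance * optimal span`).
#'
#' @param query_seq,ref_seq Read sequences (forward strands).
#' @param record One-row overlap record (needs `strand`, `q_start`,
#'   `q_end`, `r_start`, `r_end`).
#' @param config An [eval_config()] list.
#' @return List with logical `presence`, `length`, `bounds`, `correct`
#'   (the configured mode), and the optimal alignment `opt`.
#' @export
compute_dp <- function(query_seq, ref_seq, record, config = eval_config()) {
  opt <- align_best_direction(query_seq, ref_seq, config)
  opt_len <- max(opt$a_end - opt$a_start, opt$b_end - opt$b_start)
  good <- opt$score > 0 && opt_len >= config$min_align_len &&
    !is.na(opt$identity) && opt$identity >= config$good_identity
  tol <- config$bound_tolerance * opt_len
  rep_len <- max(
    record$q_end - record$q_start,
    record$r_end - record$r_start
  )
  len_ok <- good && record$strand == opt$direction &&
    abs(rep_len - opt_len) <= tol
  bounds_ok <- len_ok &&
    abs(record$q_start - opt$a_start) <= tol &&
    abs(record$q_end - opt$a_end) <= tol &&
    abs(record$r_start - opt$b_start) <= tol &&
    abs(record$r_end - opt$b_end) <= tol
  out <- list(
    presence = good, length = len_ok, bounds = bounds_ok,
    opt = opt
  )
  out$correct <- out[[config$mode]]
  out
}

# internal: unordered pair keys for membership tests
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# internal: look up the record for an unordered pair of read names
find_record <- function(records, name1, name2) {
  hit <- which(
    (records$query_name == name1 & records$ref_name == name2) |
      (records$query_name == name2 & records$ref_name == name1)
  )
  if (!length(hit)) {
    return(NULL)
  }
  records[hit[1L], , drop = FALSE]
}

# internal: orient a record so that its query is `name1`
orient_record <- function(record, name1) {
  if (record$query_name[1L] == name1) {
    return(record)
  }
  data.frame(
    query_name = record$ref_name, ref_name = record$query_name,
    strand = record$strand,
    q_start = if (record$strand == 1) {
      record$r_len - record$r_end
    } else {
      record$r_start
    },
    q_end = if (record$strand == 1) {
      record$r_len - record$r_start
    } else {
      record$r_end
    },
    q_len = record$r_len,
    r_start = if (record$strand == 1) {
      record$q_len - record$q_end
    } else {
      record$q_start
    },
    r_end = if (record$strand == 1) {
      record$q_len - record$q_start
    } else {
      record$q_end
    },
    r_len = record$q_len
  )
}

#' Estimate sensitivity over ground-truth pairs
#'
#' Samples up to `trials` truly overlapping pairs (genomic intersection
#' at least `min_align_len`) uniformly without replacement under the
#' configured seed; sensitivity is the fraction that was reported and
#' judged correct by [compute_dp()] under the configured mode.
#'
#' @param records Overlap record data frame (from [find_overlaps()] or
#'   [read_m4()]; needs name-based columns).
#' @param truth Placement table from [simulate_reads()].
#' @param reads Named character vector of read sequences (or a
#'   `"packed_reads"` object).
#' @param config An [eval_config()] list.
#' @return The sensitivity as a single number in `[0, 1]`. Attribute `n`
#'   carries the number of sampled pairs and attribute `by_mode` the
#'   fractions under all three nested modes for the same sample (they
#'   come for free from one validation pass). `NA` when no pair is
#'   eligible.
#' @export
estimate_sensitivity <- function(records, truth, reads,
                                 config = eval_config()) {
  seqs <- as_seq_vector(reads)
  eligible <- true_overlaps(truth, min_len = config$min_align_len)
  if (nrow(eligible) == 0) {
    warning("no eligible true-overlap pairs; sensitivity undefined")
    return(structure(NA_real_, n = 0L))
  }
  take <- with_seed(
    config$seed,
    sample.int(nrow(eligible), min(config$trials, nrow(eligible)))
  )
  ok <- vapply(take, function(i) {
    rec <- find_record(records, eligible$read1[i], eligible$read2[i])
    if (is.null(rec)) {
      return(c(presence = FALSE, length = FALSE, bounds = FALSE))
    }
    rec <- orient_record(rec, eligible$read1[i])
    dp <- compute_dp(
      seqs[[eligible$read1[i]]], seqs[[eligible$read2[i]]], rec, config
    )
    c(
      presence = dp$presence, length = dp$length,
      bounds = dp$bounds
    )
  }, logical(3))
  by_mode <- rowMeans(ok)
  structure(unname(by_mode[config$mode]),
    n = length(take),
    by_mode = by_mode
  )
}

#' Estimate specificity over non-overlapping pairs
#'
#' Samples up to `trials` read pairs whose placements do not intersect at
#' all; specificity is the fraction not reported.
#'
#' @inheritParams estimate_sensitivity
#' @return Specificity in `[0, 1]` with attribute `n`, or `NA` if every
#'   pair truly overlaps.
#' @export
estimate_specificity <- function(records, truth, config = eval_config()) {
  n <- nrow(truth)
  overlapping <- true_overlaps(truth, min_len = 1L)
  truly <- pair_key(overlapping$read1, overlapping$read2)
  reported <- pair_key(records$query_name, records$ref_name)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keys <- pair_key(truth$read[idx[, 1L]], truth$read[idx[, 2L]])
  non <- keys[!(keys %in% truly)]
  if (!length(non)) {
    warning("no non-overlapping pairs; specificity undefined")
    return(structure(NA_real_, n = 0L))
  }
  take <- with_seed(
    config$seed,
    sample.int(length(non), min(config$trials, length(non)))
  )
  structure(mean(!(non[take] %in% reported)), n = length(take))
}

#' Estimate precision over reported records
#'
#' Samples up to `trials` reported records with span at least
#' `min_align_len` (the analysis floor) and judges each by
#' [compute_dp()] — truth-free: only the reads themselves and the
#' optimal alignment are consulted.
#'
#' @inheritParams estimate_sensitivity
#' @return Precision in `[0, 1]` with attribute `n`, or `NA` when
#'   nothing was reported at the analysis floor.
#' @export
estimate_precision <- function(records, reads, config = eval_config()) {
  seqs <- as_seq_vector(reads)
  span <- pmax(
    records$q_end - records$q_start,
    records$r_end - records$r_start
  )
  cand <- which(span >= config$min_align_len)
  if (!length(cand)) {
    warning("no reported records at the analysis floor; precision undefined")
    return(structure(NA_real_, n = 0L))
  }
  take <- cand[with_seed(
    config$seed,
    sample.int(length(cand), min(config$trials, length(cand)))
  )]
  ok <- vapply(take, function(i) {
    rec <- records[i, , drop = FALSE]
    dp <- compute_dp(
      seqs[[rec$query_name]], seqs[[rec$ref_name]], rec, config
    )
    c(presence = dp$presence, length = dp$length, bounds = dp$bounds)
  }, logical(3))
  by_mode <- rowMeans(ok)
  structure(unname(by_mode[config$mode]),
    n = length(take),
    by_mode = by_mode
  )
}

#' Harmonic mean of sensitivity and precision
#'
#' @param sensitivity,precision Fractions in `[0, 1]`.
#' @return The F1 score; 0 when both inputs are 0.
#' @examples
#' f1_score(0.8, 0.6)
#' @export
f1_score <- function(sensitivity, precision) {
  ifelse(sensitivity + precision == 0, 0,
    2 * sensitivity * precision / (sensitivity + precision)
  )
}

#' Full evaluation report
#'
#' Convenience wrapper computing sensitivity, specificity, precision and
#' F1 for a record set against simulator ground truth.
#'
#' @inheritParams estimate_sensitivity
#' @return List with the four estimates (each carrying its sample size
#'   as attribute `n`) and the configuration used.
#' @export
evaluate_overlaps <- function(records, truth, reads,
                              config = eval_config()) {
  sens <- estimate_sensitivity(records, truth, reads, config)
  spec <- estimate_specificity(records, truth, config)
  prec <- estimate_precision(records, reads, config)
  list(
    sensitivity = sens, specificity = spec, precision = prec,
    f1 = f1_score(as.numeric(sens), as.numeric(prec)),
    config = config
  )
}

as_seq_vector <- function(reads) {
  if (inherits(reads, "packed_reads")) {
    return(sequences(reads))
  }
  out <- as.character(reads)
  names(out) <- names(reads)
  out
}
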