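# shared fixtures and small independent oracles, built in code

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
    collapse = ""
  )
  if (is.null(seed)) draw() else seedoverlap:::with_seed(seed, draw())
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(
    paste0("@", names(seqs)), seqs, "+", strrep("I", nchar(seqs))
  )), path)
  path
}

# naive all-strand k-mer scan: the independent oracle for index lookups
naive_lookup <- function(seqs, kmer, max_count = Inf, min_count = 1) {
  k <- nchar(kmer)
  hits <- list()
  total <- 0L
  count_of <- function(seq, km) {
    n <- nchar(seq) - k + 1
    if (n < 1) {
      return(integer())
    }
    starts <- which(vapply(
      seq_len(n), function(i) substr(seq, i, i + k - 1) == km, logical(1)
    ))
    starts - 1L
  }
  rows <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    fw <- count_of(seqs[[i]], kmer)
    rv <- count_of(seedoverlap::reverse_complement(seqs[[i]]), kmer)
    rbind(
      if (length(fw)) data.frame(read_id = i, pos = fw, strand = 0L),
      if (length(rv)) data.frame(read_id = i, pos = rv, strand = 1L)
    )
  }))
  if (is.null(rows)) rows <- data.frame(
    read_id = integer(), pos = integer(), strand = integer()
  )
  # the frequency filters act on the total count over reads and strands
  if (nrow(rows) > max_count || nrow(rows) < min_count) {
    rows <- rows[0, , drop = FALSE]
  }
  rows <- rows[order(rows$read_id, rows$strand, rows$pos), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# exhaustive adjacent-consistency partition: oracle for cluster_matches
oracle_clusters <- function(V, k, max_shift) {
  n <- nrow(V)
  if (n == 0) {
    return(data.frame(
      left_idx = integer(), right_idx = integer(),
      matched_bp = integer(), hit_count = integer()
    ))
  }
  consistent <- function(i, j) {
    dq <- V$qpos[j] - V$qpos[i]
    dr <- V$rpos[j] - V$rpos[i]
    dq >= 0 && dr >= 0 && abs(dq - dr) <= max_shift * max(dq, dr)
  }
  breaks <- c(
    1L,
    1L + which(!vapply(
      seq_len(n - 1), function(i) consistent(i, i + 1), logical(1)
    ))
  )
  ends <- c(breaks[-1] - 1L, n)
  bp <- mapply(function(l, r) {
    covered <- unique(unlist(lapply(l:r, function(i) {
      V$qpos[i] + seq_len(k) - 1L
    })))
    length(covered)
  }, breaks, ends)
  data.frame(
    left_idx = breaks, right_idx = ends,
    matched_bp = as.integer(bp), hit_count = ends - breaks + 1L
  )
}

# quadratic score-only Smith-Waterman in plain R: oracle for the C++ DP
oracle_sw_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  n <- length(av)
  m <- length(bv)
  prev <- numeric(m + 1)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      cur[j + 1] <- max(0, prev[j] + sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# small deterministic simulated data set shared by several tests
small_sim <- function(genome_len = 30000, coverage = 10, error_rate = 0,
                      seed = 421) {
  genome <- simulate_genome(genome_len, seed = seed)
  sim <- simulate_reads(genome, sim_config(
    genome_length = genome_len, coverage = coverage,
    error_rate = error_rate, read_length_mean = 4000,
    read_length_min = 800, read_length_max = 12000, seed = seed + 1
  ))
  list(genome = genome, sim = sim)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
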