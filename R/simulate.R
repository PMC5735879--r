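#' Simulation configuration
#'
#' Parameters of the synthetic long-read generator. Defaults emulate a
#' PacBio-style single-molecule run: per-base error rate 0.12 (within the
#' technology's typical 10-15%), an indel-dominant error mix (50%
#' insertions, 35% deletions, 15% substitutions), and log-normal read
#' lengths with mean 8 kb truncated to `[1000, 40000]`.
#'
#' @param genome_length Genome size in bases.
#' @param coverage Target fold coverage; reads are drawn until the summed
#'   read length reaches `coverage * genome_length`.
#' @param read_length_mean Mean read length in bases.
#' @param read_length_min,read_length_max Truncation bounds.
#' @param read_length_sdlog Log-scale standard deviation of the
#'   log-normal length distribution.
#' @param error_rate Total per-base error probability in `[0, 0.5)`.
#' @param error_mix Named fractions (`insertion`, `deletion`,
#'   `substitution`) summing to 1.
#' @param seed Integer RNG seed; every random choice derives from it.
#' @return A validated list of class `"seedoverlap_params"`.
#' @export
sim_config <- function(genome_length = 200000L, coverage = 30,
                       read_length_mean = 8000, read_length_min = 1000,
                       read_length_max = 40000, read_length_sdlog = 0.35,
                       error_rate = 0.12,
                       error_mix = c(
                         insertion = 0.5, deletion = 0.35,
                         substitution = 0.15
                       ),
                       seed = 1L) {
  check_range(genome_length, "genome_length", 100, Inf)
  check_range(coverage, "coverage", 0, Inf, lo_open = TRUE)
  check_range(error_rate, "error_rate", 0, 0.5, hi_open = TRUE)
  check_range(read_length_min, "read_length_min", 1, read_length_max)
  stopifnot(
    length(error_mix) == 3,
    all(c("insertion", "deletion", "substitution") %in% names(error_mix)),
    abs(sum(error_mix) - 1) < 1e-8
  )
  structure(
    list(
      genome_length = as.integer(genome_length), coverage = coverage,
      read_length_mean = read_length_mean,
      read_length_min = read_length_min,
      read_length_max = read_length_max,
      read_length_sdlog = read_length_sdlog,
      error_rate = error_rate,
      error_mix = error_mix[c("insertion", "deletion", "substitution")],
      seed = as.integer(seed)
    ),
    class = "seedoverlap_params"
  )
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  expr
}

#' Simulate a random genome
#'
#' I.i.d. uniform ACGT sequence; repeat structure beyond what random
#' chance produces is deliberately absent.
#'
#' @param length Genome length in bases.
#' @param seed Integer RNG seed.
#' @return A single base string.
#' @examples
#' nchar(simulate_genome(1000, seed = 7))
#' @export
simulate_genome <- function(length, seed = 1L) {
  check_range(length, "length", 1, Inf)
  with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE),
    collapse = ""
  ))
}

#' Simulate noisy long reads with exact ground truth
#'
#' Reads are placed uniformly over the genome on random strands until the
#' target coverage is met. The error-free template of each read is the
#' exact genomic substring of its placement (reverse-complemented for
#' minus-strand reads); errors are then applied i.i.d. per base with the
#' configured indel-dominant mix. Placements are recorded before errors,
#' so pairwise true overlaps are exact interval intersections.
#'
#' @param genome Base string (e.g. from [simulate_genome()]).
#' @param config A [sim_config()] list.
#' @return A list of class `"sim_output"`: `reads` (named character
#'   vector), `truth` (data frame `read`, `contig`, `start`, `end`,
#'   `strand` with 0-based half-open forward-strand placements),
#'   `error_counts` (per-read insertion/deletion/substitution tallies)
#'   and `config`.
#' @export
simulate_reads <- function(genome, config = sim_config()) {
  genome_len <- nchar(genome)
  if (config$read_length_min > genome_len) {
    stop("read_length_min exceeds the genome length", call. = FALSE)
  }
  with_seed(config$seed, {
    target <- config$coverage * genome_len
    meanlog <- log(config$read_length_mean) - config$read_length_sdlog^2 / 2
    lens <- integer()
    while (sum(as.numeric(lens)) < target) {
      draw <- rlnorm(64, meanlog, config$read_length_sdlog)
      draw <- pmin(
        pmax(round(draw), config$read_length_min),
        min(config$read_length_max, genome_len)
      )
      need <- cumsum(as.numeric(draw)) < target - sum(as.numeric(lens))
      keep <- c(TRUE, need[-length(need)])
      lens <- c(lens, as.integer(draw[keep]))
    }
    n <- length(lens)
    start <- floor(runif(n, 0, genome_len - lens + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gbases <- strsplit(genome, "", fixed = TRUE)[[1L]]
    reads <- character(n)
    err <- matrix(0L, n, 3,
      dimnames = list(NULL, c("insertion", "deletion", "substitution"))
    )
    for (i in seq_len(n)) {
      tmpl <- gbases[(start[i] + 1):(start[i] + lens[i])]
      if (strand[i] == "-") tmpl <- rev(c(T = "A", G = "C", C = "G", A = "T")[tmpl])
      mut <- mutate_read(tmpl, config$error_rate, config$error_mix)
      reads[i] <- paste(mut$seq, collapse = "")
      err[i, ] <- mut$counts
    }
    names(reads) <- sprintf("read%05d", seq_len(n))
    structure(
      list(
        reads = reads,
        truth = data.frame(
          read = names(reads), contig = "genome",
          start = as.integer(start), end = as.integer(start + lens),
          strand = strand
        ),
        error_counts = err,
        config = config
      ),
      class = "sim_output"
    )
  })
}

# internal: apply iid per-base errors to a character vector of bases
mutate_read <- function(tmpl, error_rate, mix) {
  n <- length(tmpl)
  bases <- c("A", "C", "G", "T")
  if (error_rate <= 0) {
    return(list(seq = tmpl, counts = c(0L, 0L, 0L)))
  }
  ev <- sample.int(4L, n,
    replace = TRUE,
    prob = c(1 - error_rate, error_rate * mix)
  ) - 1L # 0 none, 1 ins, 2 del, 3 sub
  sub_at <- which(ev == 3L)
  if (length(sub_at)) {
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, length(sub_at), replace = TRUE)
    cur <- match(tmpl[sub_at], bases)
    tmpl[sub_at] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  reps <- ifelse(ev == 2L, 0L, ifelse(ev == 1L, 2L, 1L))
  out <- rep(tmpl, reps)
  ins_at <- cumsum(reps)[ev == 1L] # position of the inserted copy
  if (length(ins_at)) {
    out[ins_at] <- sample(bases, length(ins_at), replace = TRUE)
  }
  list(
    seq = out,
    counts = c(sum(ev == 1L), sum(ev == 2L), sum(ev == 3L))
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d reads, %.1fx coverage of %d bp genome, error rate %g\n",
    length(x$reads),
    sum(nchar(x$reads)) / x$config$genome_length,
    x$config$genome_length, x$config$error_rate
  ))
  invisible(x)
}

#' Enumerate true overlaps from ground-truth placements
#'
#' Two reads truly overlap when their genomic placements intersect; the
#' expected overlap bounds are the intersection projected into each
#' read's own coordinates (error-free approximation: indel drift inside a
#' read shifts real bounds by an amount the evaluation tolerance
#' absorbs). Pairs are unordered, reported once with `id1 < id2`.
#'
#' @param truth Placement data frame (`read`, `contig`, `start`, `end`,
#'   `strand`) as produced by [simulate_reads()].
#' @param min_len Minimum genomic intersection length to report.
#' @return Data frame with `id1`, `id2`, `read1`, `read2`, `glen`
#'   (genomic intersection length), projected bounds `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open in each read's forward
#'   coordinates) and `strand` (0 same placement strand, 1 opposite).
#' @export
true_overlaps <- function(truth, min_len = 1L) {
  n <- nrow(truth)
  if (n < 2) {
    return(data.frame(
      id1 = integer(), id2 = integer(), read1 = character(),
      read2 = character(), glen = integer(), a_start = integer(),
      a_end = integer(), b_start = integer(), b_end = integer(),
      strand = integer()
    ))
  }
  ord <- order(truth$start, truth$end)
  pairs_a <- integer()
  pairs_b <- integer()
  for (ii in seq_len(n - 1)) {
    i <- ord[ii]
    jj <- ii + 1L
    while (jj <= n && truth$start[ord[jj]] < truth$end[i]) {
      j <- ord[jj]
      if (truth$contig[i] == truth$contig[j]) {
        pairs_a <- c(pairs_a, min(i, j))
        pairs_b <- c(pairs_b, max(i, j))
      }
      jj <- jj + 1L
    }
  }
  if (!length(pairs_a)) {
    return(true_overlaps(truth[0, , drop = FALSE], min_len))
  }
  s <- pmax(truth$start[pairs_a], truth$start[pairs_b])
  e <- pmin(truth$end[pairs_a], truth$end[pairs_b])
  keep <- (e - s) >= min_len
  pairs_a <- pairs_a[keep]
  pairs_b <- pairs_b[keep]
  s <- s[keep]
  e <- e[keep]
  project <- function(idx, lo, hi) {
    st <- truth$start[idx]
    en <- truth$end[idx]
    plus <- truth$strand[idx] == "+"
    data.frame(
      start = ifelse(plus, lo - st, en - hi),
      end = ifelse(plus, hi - st, en - lo)
    )
  }
  pa <- project(pairs_a, s, e)
  pb <- project(pairs_b, s, e)
  data.frame(
    id1 = pairs_a, id2 = pairs_b,
    read1 = truth$read[pairs_a], read2 = truth$read[pairs_b],
    glen = as.integer(e - s),
    a_start = as.integer(pa$start), a_end = as.integer(pa$end),
    b_start = as.integer(pb$start), b_end = as.integer(pb$end),
    strand = as.integer(truth$strand[pairs_a] != truth$strand[pairs_b])
  )
}

#' Write simulator output to disk
#'
#' Emits the genome as FASTA, the reads as FASTQ (dummy `I` qualities)
#' and the truth table as TSV into a directory.
#'
#' @param sim A `"sim_output"` object.
#' @param dir Output directory (created if needed).
#' @param genome Optional genome string to include as `genome.fasta`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_output <- function(sim, dir, genome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(dir, "reads.fastq"),
    truth = file.path(dir, "truth.tsv")
  )
  con <- file(paths[["reads"]], open = "wt")
  for (i in seq_along(sim$reads)) {
    writeLines(c(
      paste0("@", names(sim$reads)[i]), sim$reads[[i]], "+",
      strrep("I", nchar(sim$reads[[i]]))
    ), con)
  }
  close(con)
  write.table(sim$truth, paths[["truth"]],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(genome)) {
    paths <- c(paths, genome = file.path(dir, "genome.fasta"))
    writeLines(c(">genome", genome), paths[["genome"]])
  }
  invisible(paths)
}
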