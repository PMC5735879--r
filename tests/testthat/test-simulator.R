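test_that("genome simulation is deterministic with balanced composition", {
  g1 <- simulate_genome(1000, seed = 81)
  g2 <- simulate_genome(1000, seed = 81)
  expect_identical(g1, g2)
  expect_identical(nchar(g1), 1000L)
  expect_false(identical(g1, simulate_genome(1000, seed = 82)))

  big <- simulate_genome(1e5, seed = 83)
  gc_frac <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.5), 0.05)
})

test_that("error-free reads are exact substrings at their placements", {
  g <- simulate_genome(20000, seed = 84)
  sim <- simulate_reads(g, sim_config(
    genome_length = 20000, coverage = 5, error_rate = 0,
    read_length_mean = 3000, read_length_min = 500, seed = 85
  ))
  for (i in seq_along(sim$reads)) {
    t <- sim$truth[i, ]
    template <- substr(g, t$start + 1, t$end)
    if (t$strand == "-") template <- reverse_complement(template)
    expect_identical(sim$reads[[i]], template)
  }
  # realized coverage close to target
  expect_lt(abs(sum(nchar(sim$reads)) / 20000 - 5) / 5, 0.15)
})

test_that("error decomposition follows the configured mix", {
  g <- simulate_genome(50000, seed = 86)
  sim <- simulate_reads(g, sim_config(
    genome_length = 50000, coverage = 20, error_rate = 0.12, seed = 87
  ))
  counts <- colSums(sim$error_counts)
  total <- sum(counts)
  bases <- sum(sim$truth$end - sim$truth$start)
  # total error rate within Monte-Carlo slack
  expect_lt(abs(total / bases - 0.12), 0.01)
  expect_lt(abs(counts[["insertion"]] / total - 0.50), 0.03)
  expect_lt(abs(counts[["deletion"]] / total - 0.35), 0.03)
  expect_lt(abs(counts[["substitution"]] / total - 0.15), 0.03)
  # edit distance to the template is bounded by the applied error count:
  # spot-check a few reads with the package's own DP on short reads
  idx <- which(nchar(sim$reads) < 3000)[1:3]
  for (i in idx[!is.na(idx)]) {
    t <- sim$truth[i, ]
    template <- substr(g, t$start + 1, t$end)
    if (t$strand == "-") template <- reverse_complement(template)
    applied <- sum(sim$error_counts[i, ])
    aln <- smith_waterman(sim$reads[[i]], template, 1L, -1L, -1L)
    # unit-cost score >= matched - errors implies at least this similarity
    expect_gt(aln$score, nchar(template) - 3 * applied)
  }
})

test_that("reads are deterministic under the seed and differ across seeds", {
  g <- simulate_genome(20000, seed = 88)
  cfg <- sim_config(genome_length = 20000, coverage = 3, seed = 89)
  s1 <- simulate_reads(g, cfg)
  s2 <- simulate_reads(g, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("true overlap enumeration matches interval arithmetic", {
  truth <- data.frame(
    read = c("a", "b", "c", "d"), contig = "genome",
    start = c(0L, 3000L, 10000L, 1000L),
    end = c(5000L, 8000L, 12000L, 2000L),
    strand = c("+", "-", "+", "+")
  )
  to <- true_overlaps(truth, min_len = 1)
  keys <- paste(to$read1, to$read2)
  expect_setequal(keys, c("a b", "a d"))
  ab <- to[to$read1 == "a" & to$read2 == "b", ]
  expect_identical(ab$glen, 2000L)
  expect_identical(c(ab$a_start, ab$a_end), c(3000L, 5000L))
  # b is minus strand: genome [3000,5000) maps to read-end coordinates
  expect_identical(c(ab$b_start, ab$b_end), c(3000L, 5000L))
  expect_identical(ab$strand, 1L)
  # nested placement: overlap is the shorter read's full span
  ad <- to[to$read1 == "a" & to$read2 == "d", ]
  expect_identical(ad$glen, 1000L)
  expect_identical(c(ad$b_start, ad$b_end), c(0L, 1000L))

  expect_identical(nrow(true_overlaps(truth, min_len = 1500)), 1L)
  # tiling reads with 2 kb steps: only adjacent pairs reach 2 kb
  tiling <- data.frame(
    read = c("x", "y", "z"), contig = "genome",
    start = c(0L, 2000L, 4000L), end = c(4000L, 6000L, 8000L),
    strand = "+"
  )
  tz <- true_overlaps(tiling, min_len = 2000)
  expect_setequal(paste(tz$read1, tz$read2), c("x y", "y z"))
})

test_that("simulator files round-trip through the package readers", {
  g <- simulate_genome(10000, seed = 90)
  sim <- simulate_reads(g, sim_config(
    genome_length = 10000, coverage = 2, read_length_mean = 2000,
    read_length_min = 500, seed = 91
  ))
  dir <- tempfile()
  paths <- write_sim_output(sim, dir, genome = g)
  reads <- load_reads(paths[["reads"]])
  expect_identical(unname(sequences(reads)), unname(sim$reads))
  truth <- read.table(paths[["truth"]], header = TRUE, sep = "\t")
  expect_identical(nrow(truth), nrow(sim$truth))
  expect_identical(
    unname(sequences(load_reads(paths[["genome"]]))), g
  )
})
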