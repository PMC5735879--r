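test_that("maximum bounds follow the projection formulas with clamping", {
  b <- compute_max_bounds(1000, 500, 5500, 4000, 6000, 8000, 0.2)
  expect_identical(b$query_start, 400L) # 1000 - 1.2*500
  expect_identical(b$ref_end, 4600L) # 4000 + 1.2*(6000-5500)
  # mirror forms
  expect_identical(b$ref_start, 0L) # 500 - 1.2*1000 clamps at 0
  expect_identical(b$query_end, 6000L) # 5500 + 1.2*4000 clamps at qlen

  # no reference overhang to project
  b2 <- compute_max_bounds(1000, 0, 2000, 1000, 6000, 8000, 0.2)
  expect_identical(b2$query_start, 1000L)
})

test_that("identical error-free reads extend to the full read span", {
  r <- random_dna(3000, seed = 41)
  rec <- overlap_pair(r, r, overlap_config(min_kmer_count = 1))
  expect_identical(
    c(rec$q_start, rec$q_end, rec$r_start, rec$r_end),
    c(0L, 3000L, 0L, 3000L)
  )
  expect_identical(rec$strand, 0L)
  expect_gt(rec$identity, 0.999)
})

test_that("k'-mers recover overlap ends whose k-mers were destroyed", {
  # a planted dovetail overlap whose outer stretches carry a substitution
  # every 14 bp: 16-mers cannot survive there but 12-mers can
  seedoverlap:::with_seed(43, {
    genome <- random_dna(9000)
    a_t <- substr(genome, 1, 5000)
    b_t <- substr(genome, 2001, 9000) # true overlap 3000 bp
    mutate_every <- function(s, at) {
      v <- strsplit(s, "")[[1]]
      for (i in at) {
        v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[sample.int(3, 1)]
      }
      paste(v, collapse = "")
    }
    # damage the first 600 bp of b's overlap as seen from a's side
    a <- mutate_every(a_t, seq(2001, 2600, by = 14))
    b <- b_t
  })
  rec <- overlap_pair(a, b, overlap_config(min_kmer_count = 1))
  expect_false(is.null(rec))
  # truth: a[2000..5000) vs b[0..3000); tolerance max_shift * 3000
  tol <- 0.2 * 3000
  expect_lt(abs(rec$q_start - 2000), tol)
  expect_identical(rec$q_end, 5000L)
  expect_lt(rec$r_start, 50L)
  expect_identical(rec$r_end, 3000L)
})

test_that("extension stops near cluster bounds on unrelated flanks", {
  # shared 1 kb core with unrelated 2 kb flanks on both sides
  seedoverlap:::with_seed(44, {
    core <- random_dna(1000)
    a <- paste0(random_dna(2000), core, random_dna(2000))
    b <- paste0(random_dna(2000), core, random_dna(2000))
  })
  rec <- overlap_pair(a, b, overlap_config(min_kmer_count = 1))
  expect_false(is.null(rec))
  # reported region must not creep far into the unrelated flanks
  expect_lt(abs(rec$q_start - 2000), 100)
  expect_lt(abs(rec$q_end - 3000), 100)
  expect_lt(abs(rec$r_start - 2000), 100)
  expect_lt(abs(rec$r_end - 3000), 100)
})

test_that("validation rejects pairs whose k'-mer support is spurious", {
  # unrelated reads sharing nothing except one planted 16-mer
  seedoverlap:::with_seed(45, {
    shared <- random_dna(16)
    a <- paste0(random_dna(2500), shared, random_dna(2500))
    b <- paste0(random_dna(2500), shared, random_dna(2500))
  })
  rec <- overlap_pair(a, b, overlap_config(min_kmer_count = 1))
  expect_null(rec)
})

test_that("reported bounds stay inside the projection window", {
  s <- small_sim(genome_len = 20000, coverage = 8, error_rate = 0.1, seed = 46)
  rec <- find_overlaps(s$sim$reads, overlap_config())
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$q_start >= 0 & rec$q_end <= rec$q_len))
  expect_true(all(rec$r_start >= 0 & rec$r_end <= rec$r_len))
  expect_true(all(rec$q_start < rec$q_end))
  expect_true(all(rec$r_start < rec$r_end))
})

test_that("raising the assumed error rate never shrinks the reported set", {
  s <- small_sim(genome_len = 15000, coverage = 6, error_rate = 0.12, seed = 47)
  keys <- lapply(c(0.10, 0.15, 0.20), function(e) {
    r <- find_overlaps(s$sim$reads, overlap_config(error_rate = e))
    pair_key(r$query_name, r$ref_name)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})
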