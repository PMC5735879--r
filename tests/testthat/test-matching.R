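test_that("a query identical to a reference read matches along the diagonal", {
  r <- random_dna(80, seed = 5)
  idx <- build_kmer_index(c(ref = r), index_params(k = 16, min_kmer_count = 1))
  ml <- collect_matches(r, idx)
  expect_length(ml, 1L)
  expect_identical(ml[[1]]$strand, 0L)
  expect_identical(ml[[1]]$matches$qpos, 0:(80 - 16))
  expect_identical(ml[[1]]$matches$rpos, 0:(80 - 16))
})

test_that("a reverse-complement query picks the reverse strand", {
  r <- random_dna(80, seed = 6)
  idx <- build_kmer_index(c(ref = r), index_params(k = 16, min_kmer_count = 1))
  ml <- collect_matches(reverse_complement(r), idx)
  expect_length(ml, 1L)
  expect_identical(ml[[1]]$strand, 1L)
  expect_identical(nrow(ml[[1]]$matches), 80L - 16L + 1L)
  # positions on the reverse strand are again the diagonal
  expect_identical(ml[[1]]$matches$qpos, ml[[1]]$matches$rpos)
})

test_that("an embedded exact copy yields exactly the expected seed matches", {
  seedoverlap:::with_seed(8, {
    query <- random_dna(60)
    ref <- paste0(random_dna(40), substr(query, 11, 40), random_dna(40))
  })
  idx <- build_kmer_index(c(ref = ref), index_params(k = 16, min_kmer_count = 1))
  ml <- collect_matches(query, idx)
  expect_length(ml, 1L)
  m <- ml[[1]]$matches
  # a 30 bp shared block holds 30 - 16 + 1 = 15 k-mers
  expect_identical(nrow(m), 15L)
  expect_identical(m$qpos, 10:24)
  expect_identical(m$rpos, 40:54)
})

test_that("matches equal a brute-force k-mer intersection on small instances", {
  seedoverlap:::with_seed(91, {
    for (trial in 1:3) {
      seqs <- vapply(1:4, function(i) random_dna(sample(40:90, 1)), "")
      names(seqs) <- sprintf("r%d", 1:4)
      k <- 5L
      idx <- build_kmer_index(seqs, index_params(k = k, min_kmer_count = 1))
      q <- random_dna(50)
      ml <- collect_matches(q, idx)
      got <- do.call(rbind, lapply(ml, function(x) {
        data.frame(
          ref_id = x$ref_id, strand = x$strand,
          qpos = x$matches$qpos, rpos = x$matches$rpos
        )
      }))
      # oracle: enumerate every query k-mer against every strand of each read
      kmers <- vapply(
        seq_len(nchar(q) - k + 1),
        function(i) substr(q, i, i + k - 1), ""
      )
      want <- do.call(rbind, lapply(seq_along(seqs), function(ri) {
        strands <- c(seqs[[ri]], reverse_complement(seqs[[ri]]))
        per_strand <- lapply(0:1, function(s) {
          hit <- do.call(rbind, lapply(seq_along(kmers), function(qi) {
            at <- gregexpr(kmers[qi], strands[s + 1], fixed = TRUE)[[1]]
            at <- at[at > 0]
            # overlapping occurrences: rescan manually
            n <- nchar(strands[s + 1]) - k + 1
            at <- which(vapply(seq_len(n), function(p) {
              substr(strands[s + 1], p, p + k - 1) == kmers[qi]
            }, logical(1)))
            if (length(at)) data.frame(qpos = qi - 1L, rpos = at - 1L)
          }))
          if (is.null(hit)) data.frame(qpos = integer(), rpos = integer()) else hit
        })
        counts <- vapply(per_strand, nrow, 0L)
        if (sum(counts) == 0) {
          return(NULL)
        }
        s <- if (counts[2] > counts[1]) 1L else 0L
        m <- unique(per_strand[[s + 1]])
        m <- m[order(m$qpos, m$rpos), ]
        data.frame(ref_id = ri, strand = s, qpos = m$qpos, rpos = m$rpos)
      }))
      if (is.null(got)) got <- want[0, ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, ignore_attr = TRUE)
    }
  })
})

test_that("strand choice takes the larger count with forward tie-break", {
  expect_identical(choose_strand(10, 3), "forward")
  expect_identical(choose_strand(2, 7), "reverse")
  expect_identical(choose_strand(5, 5), "forward")
  expect_error(choose_strand(0, 0), "at least one")
})

test_that("self mode skips the identity pair and lower-ordered pairs", {
  r <- random_dna(60, seed = 77)
  seqs <- c(a = r, b = r, c = r)
  idx <- build_kmer_index(seqs, index_params(k = 16))
  ml <- collect_matches(seqs[["b"]], idx, query_id = 2L, self = TRUE)
  expect_identical(vapply(ml, `[[`, 0L, "ref_id"), 3L)
})
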