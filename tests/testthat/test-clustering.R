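cp <- chain_params(kmer_size = 16, max_shift = 0.2, error_rate = 0.15)

test_that("clustering keeps co-diagonal runs together and splits drifts", {
  V <- data.frame(qpos = c(0, 20, 40), rpos = c(0, 20, 40))
  cl <- cluster_matches(V, cp)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$hit_count, 3L)
  expect_identical(cl$matched_bp, 48L) # three disjoint 16-mers

  V2 <- data.frame(qpos = c(0, 20, 40, 60), rpos = c(0, 20, 40, 500))
  cl2 <- cluster_matches(V2, cp)
  expect_identical(nrow(cl2), 2L)
  expect_identical(cl2$hit_count, c(3L, 1L))

  # reference positions not ascending: two singletons
  V3 <- data.frame(qpos = c(0, 100), rpos = c(100, 0))
  cl3 <- cluster_matches(V3, cp)
  expect_identical(cl3$hit_count, c(1L, 1L))

  expect_identical(nrow(cluster_matches(V3[0, ], cp)), 0L)
})

test_that("greedy partition equals the exhaustive adjacent-consistency oracle", {
  seedoverlap:::with_seed(17, {
    for (trial in 1:300) {
      n <- sample(1:12, 1)
      V <- data.frame(
        qpos = sort(sample(0:300, n, replace = TRUE)),
        rpos = sample(0:300, n, replace = TRUE)
      )
      V <- V[order(V$qpos, V$rpos), , drop = FALSE]
      rownames(V) <- NULL
      ms <- sample(c(0.1, 0.2, 0.4), 1)
      k <- sample(c(8L, 16L), 1)
      got <- cluster_matches(V, chain_params(k, ms, 0.15))
      want <- oracle_clusters(V, k, ms)
      expect_equal(got, want, ignore_attr = TRUE)
      # partition property: index ranges tile V exactly
      expect_identical(got$left_idx[1], 1L)
      expect_identical(got$right_idx[nrow(got)], nrow(V))
      if (nrow(got) > 1) {
        expect_identical(got$left_idx[-1], got$right_idx[-nrow(got)] + 1L)
      }
    }
  })
})

test_that("reference-major resort can rescue interleaved chains", {
  # two chains interleave under query-major order but separate under
  # reference-major order
  V <- data.frame(
    qpos = c(0, 10, 20, 30, 40, 50),
    rpos = c(0, 500, 20, 520, 40, 540)
  )
  first <- cluster_matches(V, cp)
  expect_gt(nrow(first), 2L) # fragmented
  second <- recluster_on_failure(V, cp)
  expect_identical(second$V$rpos, sort(V$rpos))
  expect_identical(nrow(second$clusters), 2L)
  expect_identical(second$clusters$hit_count, c(3L, 3L))
})

test_that("best cluster maximizes matched bp with documented tie-breaks", {
  cl <- data.frame(
    left_idx = c(1L, 4L), right_idx = c(3L, 8L),
    matched_bp = c(48L, 32L), hit_count = c(3L, 5L)
  )
  expect_identical(select_best_cluster(cl)$matched_bp, 48L)
  cl$matched_bp <- c(48L, 48L)
  expect_identical(select_best_cluster(cl)$hit_count, 5L)
  expect_null(select_best_cluster(cl[0, ]))
})

test_that("binomial threshold matches direct arithmetic and its limits", {
  # printed-formula example: L=5000, e=0.15, k=16 -> ~11.9
  thr <- binomial_threshold(5000, 0.15, 16)
  p <- (1 - 0.15)^32
  expect_equal(thr, 5000 * p - 3 * sqrt(5000 * p * (1 - p)), tolerance = 1e-12)
  expect_equal(thr, 11.858565, tolerance = 1e-5)
  # e = 0: sigma vanishes and the floor equals L
  expect_identical(binomial_threshold(300, 0, 16), 300)
  # small L: the floor goes non-positive, nothing is eliminated
  expect_lte(binomial_threshold(10, 0.15, 16), 0)
})

test_that("binomial filter passes and fails on the documented examples", {
  V <- data.frame(qpos = seq(0, 29 * 150, by = 150))
  V$rpos <- V$qpos
  cl <- cluster_matches(V, cp)
  st <- overlap_stats(cl, V, query_size = 5000, ref_size = 5000, params = cp)
  expect_equal(st$p, (1 - 0.15)^32, tolerance = 1e-12)
  expect_true(binomial_filter(cl, st)) # 30 hits over ~5000 bp
  st_small <- st
  st_small$threshold <- binomial_threshold(5000, 0.15, 16)
  low <- cl
  low$hit_count <- 5L
  expect_false(binomial_filter(low, st_small))
  # non-positive floor: anything with >= 1 hit passes
  one <- cl
  one$hit_count <- 1L
  st0 <- st
  st0$threshold <- -2
  expect_true(binomial_filter(one, st0))
})
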