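# a compact deterministic scenario used throughout: error-free reads so
# the optimal alignments are unambiguous and fast
eval_fixture <- function() {
  s <- small_sim(genome_len = 30000, coverage = 8, error_rate = 0, seed = 71)
  rec <- find_overlaps(s$sim$reads, overlap_config())
  cfg <- eval_config(
    min_align_len = 1500, trials = 12, seed = 3, mode = "bounds"
  )
  list(sim = s$sim, rec = rec, cfg = cfg)
}

test_that("compute_dp validates a faithful record and rejects distortions", {
  seedoverlap:::with_seed(72, {
    g <- random_dna(7000)
    a <- substr(g, 1, 5000)
    b <- substr(g, 2001, 7000)
  })
  cfg <- eval_config(min_align_len = 2000, bound_tolerance = 0.2)
  faithful <- data.frame(
    strand = 0L, q_start = 2000L, q_end = 5000L, q_len = 5000L,
    r_start = 0L, r_end = 3000L, r_len = 5000L
  )
  dp <- compute_dp(a, b, faithful, cfg)
  expect_true(dp$presence)
  expect_true(dp$length)
  expect_true(dp$bounds)

  # wrong direction: fails length and bounds, not presence
  flipped <- faithful
  flipped$strand <- 1L
  dp2 <- compute_dp(a, b, flipped, cfg)
  expect_true(dp2$presence)
  expect_false(dp2$length)
  expect_false(dp2$bounds)

  # whole window shifted by twice the tolerance: lengths survive, bounds
  # fail
  shifted <- faithful
  shift <- as.integer(2 * 0.2 * 3000)
  shifted$q_start <- shifted$q_start - shift
  shifted$q_end <- shifted$q_end - shift
  shifted$r_start <- shifted$r_start + shift
  shifted$r_end <- shifted$r_end + shift
  dp3 <- compute_dp(a, b, shifted, cfg)
  expect_true(dp3$length)
  expect_false(dp3$bounds)

  # too-short optimal alignment is not "good": everything fails
  dp4 <- compute_dp(
    substr(a, 1, 2500), substr(b, 2500, 5000),
    faithful, cfg
  )
  expect_false(dp4$presence)
})

test_that("sensitivity, specificity and precision behave on edge sets", {
  fx <- eval_fixture()
  truth <- fx$sim$truth
  reads <- fx$sim$reads

  sens <- estimate_sensitivity(fx$rec, truth, reads, fx$cfg)
  expect_gte(as.numeric(sens), 0)
  expect_lte(as.numeric(sens), 1)
  expect_identical(attr(sens, "n"), 12L)

  # empty record set: sensitivity 0, specificity 1
  empty <- fx$rec[0, ]
  expect_identical(
    as.numeric(estimate_sensitivity(empty, truth, reads, fx$cfg)), 0
  )
  expect_identical(
    as.numeric(estimate_specificity(empty, truth, fx$cfg)), 1
  )

  spec <- estimate_specificity(fx$rec, truth, eval_config(
    trials = 500, seed = 4
  ))
  expect_gte(as.numeric(spec), 0.9)

  prec <- estimate_precision(fx$rec, reads, fx$cfg)
  expect_gte(as.numeric(prec), 0)
  expect_lte(as.numeric(prec), 1)

  # undefined estimates warn and return NA
  expect_warning(
    p0 <- estimate_precision(empty, reads, fx$cfg),
    "undefined"
  )
  expect_true(is.na(p0))
})

test_that("estimates are reproducible under a fixed sampling seed", {
  fx <- eval_fixture()
  s1 <- estimate_sensitivity(fx$rec, fx$sim$truth, fx$sim$reads, fx$cfg)
  s2 <- estimate_sensitivity(fx$rec, fx$sim$truth, fx$sim$reads, fx$cfg)
  expect_identical(s1, s2)
})

test_that("correctness modes are strictly nested on the same sample", {
  fx <- eval_fixture()
  s <- estimate_sensitivity(fx$rec, fx$sim$truth, fx$sim$reads, fx$cfg)
  modes <- attr(s, "by_mode")
  expect_lte(modes[["bounds"]], modes[["length"]])
  expect_lte(modes[["length"]], modes[["presence"]])
  p <- estimate_precision(fx$rec, fx$sim$reads, fx$cfg)
  pm <- attr(p, "by_mode")
  expect_lte(pm[["bounds"]], pm[["length"]])
  expect_lte(pm[["length"]], pm[["presence"]])
})

test_that("F1 is the harmonic mean with the degenerate case at zero", {
  expect_identical(f1_score(1, 1), 1)
  expect_identical(f1_score(0, 0.7), 0)
  expect_identical(f1_score(0, 0), 0)
  expect_equal(f1_score(0.8, 0.6), 0.685714285714286, tolerance = 1e-12)
})
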