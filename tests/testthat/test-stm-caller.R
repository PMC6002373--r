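toy_stms <- function() {
  stm_set(list(c("A", "B", "C"), c("D", "E", "F"), c("A", "D", "E")),
          ids = c("abc", "def", "ade"))
}

test_that("an STM is detected only when every member is supported", {
  stms <- toy_stms()
  d1 <- detect_stms(c(A = 100, B = 90, C = 110, D = 0, E = 0, F = 0), stms)
  expect_equal(d1$stm_id, "abc")
  expect_equal(d1$cumulative, 300)

  d2 <- detect_stms(c(A = 100, B = 90, C = 110, D = 10, E = 12, F = 0),
                    stms)
  expect_equal(d2$stm_id, c("abc", "ade"))   # def lacks F
  expect_equal(d2$cumulative, c(300, 122))

  expect_equal(nrow(detect_stms(c(A = 0, B = 0, C = 0), stms)), 0)
  expect_error(detect_stms(c(A = 1), stm_set(list("A"))[0]), "empty")
})

test_that("raising min_reads never adds a detected STM", {
  stms <- enumerate_stms(LETTERS[1:8], 3)
  set.seed(4)
  for (i in 1:20) {
    counts <- setNames(rpois(8, lambda = sample(0:5, 8, TRUE)), LETTERS[1:8])
    prev <- detect_stms(counts, stms, min_reads = 1)$stm_id
    for (mr in 2:4) {
      cur <- detect_stms(counts, stms, min_reads = mr)$stm_id
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("majority is the highest cumulative STM; ties break by id", {
  stms <- toy_stms()
  cl <- call_sample(c(A = 100, B = 90, C = 110, D = 10, E = 12, F = 0),
                    stms, sample_id = "s1")
  expect_equal(cl$majority_stm, "abc")
  expect_equal(cl$minority_stms, "ade")
  expect_false(cl$flags$ambiguous_majority)

  one <- call_sample(c(A = 100, B = 90, C = 110), stms)
  expect_equal(one$majority_stm, "abc")
  expect_length(one$minority_stms, 0)   # single STM: uncontaminated

  tie <- call_sample(c(A = 100, B = 100, C = 100,
                       D = 100, E = 100, F = 100),
                     stm_set(list(c("A", "B", "C"), c("D", "E", "F")),
                             ids = c("abc", "def")))
  expect_equal(tie$majority_stm, "abc") # lexicographic tie-break
  expect_true(tie$flags$ambiguous_majority)

  none <- call_sample(c(A = 0, B = 0), stms)
  expect_true(none$flags$no_stm)
  expect_true(is.na(none$majority_stm))
})

test_that("screening defaults to the design's STMs, not the panel", {
  stms <- toy_stms()
  design <- experiment_design(
    data.frame(sample_id = "x", expected_stm_id = "abc"), stms)
  cnt <- c(A = 100, B = 90, C = 110, D = 1, E = 1, F = 0)
  # "ade" is a composite of the majority's A plus two stray reads: it is
  # screened out under the design set but surfaces when widened
  narrow <- call_sample(cnt, design, sample_id = "x")
  expect_equal(narrow$detected$stm_id, "abc")
  wide <- call_sample(cnt, design, sample_id = "x", candidates = "panel")
  expect_setequal(wide$detected$stm_id, c("abc", "ade"))
  expect_equal(narrow$total_spikein_reads, wide$total_spikein_reads)
})

test_that("single stray reads never fake an STM in unspiked samples", {
  stms <- toy_stms()
  cl <- call_sample(c(A = 1, B = 0, C = 0, D = 0, E = 0, F = 0), stms)
  expect_true(cl$flags$no_stm)
  expect_equal(cl$total_spikein_reads, 1) # the stray read is still reported
})

test_that("low-support majorities are called but flagged", {
  stms <- toy_stms()
  cl <- call_sample(c(A = 1, B = 1, C = 1), stms)
  expect_equal(cl$majority_stm, "abc")
  expect_true(cl$flags$low_support)
})

test_that("simulated uncontaminated samples are called 100% correctly", {
  design <- make_design(96)
  cfg <- sim_config(design, depth_per_sample = 2e4, crosstalk_rate = 0,
                    seed = 21)
  sim <- simulate_experiment(cfg)
  calls <- call_samples(sim$table, design)
  hit <- vapply(calls, function(cl) {
    cl$majority_stm == sim$truth$true_stm[cl$sample_id] &&
      length(cl$minority_stms) == 0
  }, logical(1))
  expect_true(all(hit))
})

test_that("verify_and_resolve recovers an 8-of-16 sample swap exactly", {
  design <- make_design(16)
  perm <- setNames(design$samples$sample_id, design$samples$sample_id)
  perm[c("s01", "s02", "s03", "s04", "s05", "s06", "s07", "s08")] <-
    c("s02", "s01", "s04", "s03", "s06", "s05", "s08", "s07")
  cfg <- sim_config(design, depth_per_sample = 2e4, crosstalk_rate = 0,
                    swap_permutation = perm, seed = 8)
  sim <- simulate_experiment(cfg)
  report <- verify_and_resolve(call_samples(sim$table, design), design)
  expect_equal(sum(report$status == "ok"), 8)
  expect_equal(sum(report$status == "swapped"), 8)
  swapped <- report[report$status == "swapped", ]
  # proposals invert the applied label permutation
  inv <- setNames(names(perm), unname(perm))
  expect_equal(swapped$proposed_relabel,
               unname(inv[swapped$sample_id]))
  # and are mutually consistent (a partial permutation)
  expect_equal(anyDuplicated(swapped$proposed_relabel), 0)
})

test_that("any simulated label permutation is inverted by the resolver", {
  design <- make_design(12)
  set.seed(31)
  for (rep in 1:5) {
    ids <- design$samples$sample_id
    perm <- setNames(sample(ids), ids)
    cfg <- sim_config(design, depth_per_sample = 2e4,
                      swap_permutation = perm, seed = 100 + rep)
    sim <- simulate_experiment(cfg)
    report <- verify_and_resolve(call_samples(sim$table, design), design)
    inv <- setNames(names(perm), unname(perm))
    proposed <- ifelse(is.na(report$proposed_relabel), report$sample_id,
                       report$proposed_relabel)
    expect_equal(proposed, unname(inv[report$sample_id]))
  }
})

test_that("unexpected and duplicate-design situations are handled", {
  stms <- toy_stms()
  design <- experiment_design(
    data.frame(sample_id = c("x", "y"),
               expected_stm_id = c("abc", "def")), stms)
  # majority not expected for any sample
  cl <- call_sample(c(A = 50, D = 60, E = 70), stms, sample_id = "x")
  report <- verify_and_resolve(list(cl), design)
  expect_equal(report$status, "unexpected_stm")
  expect_true(is.na(report$proposed_relabel))

  dup <- experiment_design(
    data.frame(sample_id = c("x", "y"),
               expected_stm_id = c("abc", "abc")), stms)
  expect_error(verify_and_resolve(list(cl), dup), "invalid design")

  # unspiked sample carrying a full STM is flagged
  ntc_design <- experiment_design(
    data.frame(sample_id = c("x", "ntc"),
               expected_stm_id = c("abc", NA)), stms)
  ntc_call <- call_sample(c(A = 5, B = 5, C = 5), stms, sample_id = "ntc")
  rep2 <- verify_and_resolve(list(ntc_call), ntc_design)
  expect_equal(rep2$status, "unexpected_stm")
})

test_that("within-STM shares and their GC correlation are summarised", {
  stms <- stm_set(list(c("sp01", "sp02", "sp03")), ids = c("m1"))
  design <- experiment_design(
    data.frame(sample_id = "s1", expected_stm_id = "m1"), stms)
  tab <- matrix(c(100, 100, 200), 3, 1,
                dimnames = list(c("sp01", "sp02", "sp03"), "s1"))
  panel <- spikein_panel(c("sp01", "sp02", "sp03"), c(0.45, 0.50, 0.55))
  s <- spikein_bias_summary(tab, design, panel)
  expect_equal(s$mean_share, c(0.25, 0.25, 0.50))

  empty <- matrix(0L, 3, 1,
                  dimnames = list(c("sp01", "sp02", "sp03"), "s1"))
  expect_error(spikein_bias_summary(empty, design, panel), "no spike-in")
})

test_that("bias summary is flat without GC bias and negative with it", {
  design <- make_design(96)
  panel <- default_spikein_panel()
  flat <- simulate_experiment(
    sim_config(design, panel, depth_per_sample = 3e4,
               gc_bias_strength = 0, seed = 5))
  s0 <- spikein_bias_summary(flat$table, design, panel)
  # shares sit at the unbiased 1/3 within multinomial error; the residual
  # correlation of pure noise with GC carries no systematic trend
  expect_true(all(abs(s0$mean_share - 1 / 3) < 0.02))
  expect_lt(abs(attr(s0, "pearson_r")), 0.9)

  biased <- simulate_experiment(
    sim_config(design, panel, depth_per_sample = 3e4, seed = 5))
  s1 <- spikein_bias_summary(biased$table, design, panel)
  expect_lt(attr(s1, "pearson_r"), 0)
  expect_gt(max(s1$mean_share), 0.38)
  expect_lt(min(s1$mean_share), 0.27)
})
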