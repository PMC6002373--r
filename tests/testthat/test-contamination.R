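test_that("carry-over excludes shared members from both sides", {
  cnt <- c(A = 1000, B = 900, C = 1100, D = 10, E = 12)
  est <- estimate_carryover(cnt, c("A", "B", "C"), c("C", "D", "E"))
  expect_equal(est, 22 / 1922)
  # disjoint STMs with zero minority reads
  expect_equal(
    estimate_carryover(c(A = 10, B = 10, C = 10, D = 0, E = 0, F = 0),
                       c("A", "B", "C"), c("D", "E", "F")), 0)
  expect_error(
    estimate_carryover(cnt, c("A", "B", "C"), c("A", "B", "C")),
    "identical")
  expect_error(
    estimate_carryover(cnt, c("A", "B", "C"), c("A", "B")),
    "undefined")
})

test_that("carry-over is invariant to uniform count rescaling", {
  set.seed(9)
  for (i in 1:10) {
    cnt <- setNames(rpois(6, c(500, 450, 550, 6, 8, 4)) + 1, LETTERS[1:6])
    base <- estimate_carryover(cnt, c("A", "B", "C"), c("C", "D", "E"))
    for (f in c(2, 10, 0.5)) {
      expect_equal(
        estimate_carryover(cnt * f, c("A", "B", "C"), c("C", "D", "E")),
        base)
    }
  }
})

test_that("STM ids resolve against a supplied stm_set", {
  stms <- stm_set(list(c("A", "B", "C"), c("C", "D", "E")),
                  ids = c("maj", "mino"))
  cnt <- c(A = 1000, B = 900, C = 1100, D = 10, E = 12)
  expect_equal(estimate_carryover(cnt, "maj", "mino", stms = stms),
               22 / 1922)
  expect_equal(raw_minority_fraction(cnt, "maj", "mino", stms = stms),
               22 / sum(cnt))
})

test_that("minority STMs trace to design samples", {
  stms <- stm_set(list(c("A", "B", "C"), c("D", "E", "F")),
                  ids = c("stm88", "stm89"))
  design <- experiment_design(
    data.frame(sample_id = c("sewage", "soil"),
               expected_stm_id = c("stm88", "stm89")), stms)
  expect_equal(trace_sources("stm89", design), "soil")
  expect_equal(trace_sources("stm77", design), character(0))
  # same STM on two plates -> both samples listed
  multi <- structure(list(
    samples = data.frame(sample_id = c("p1A1", "p2A1"),
                         well = c("A1", "A1"),
                         expected_stm_id = c("stm88", "stm88"),
                         stringsAsFactors = FALSE),
    stms = stms), class = "experiment_design")
  expect_equal(trace_sources("stm88", multi), c("p1A1", "p2A1"))
})

test_that("candidate sources are the STMs explaining the observed set", {
  s3 <- stm_set(list(c("A", "B", "C"), c("D", "E", "F"), c("A", "D", "E")),
                ids = c("abc", "def", "ade"))
  expect_equal(
    candidate_sources_for("abc", c("A", "B", "C", "D", "E", "F"), s3),
    "def")
  s4 <- stm_set(list(c("A", "B", "C"), c("D", "E", "F"),
                     c("A", "D", "E"), c("C", "D", "E")),
                ids = c("abc", "def", "ade", "cde"))
  expect_setequal(
    candidate_sources_for("abc", c("A", "B", "C", "D", "E"), s4),
    c("ade", "cde"))
  expect_equal(candidate_sources_for("abc", c("A", "B", "C"), s4),
               character(0))
  expect_error(candidate_sources_for("abc", c("A", "B"), s4),
               "must contain")
  expect_error(candidate_sources_for("zzz", c("A", "B", "C"), s4),
               "not in the STM set")
})

test_that("resolvability on hand-checked toy sets", {
  # three mutually distinguishable STMs: every pairwise event is unique
  s3 <- stm_set(list(c("A", "B", "C"), c("D", "E", "F"), c("A", "D", "E")),
                ids = c("abc", "def", "ade"))
  r <- resolvability_analysis(s3, order = 2)
  expect_equal(r$mean_unique, 1)
  expect_equal(r$sd_unique, 0)

  # adding cde makes two of abc's three events two-candidate
  s4 <- stm_set(list(c("A", "B", "C"), c("D", "E", "F"),
                     c("A", "D", "E"), c("C", "D", "E")),
                ids = c("abc", "def", "ade", "cde"))
  r4 <- resolvability_analysis(s4, order = 2)
  expect_equal(r4$per_target$unique_frac[r4$per_target$stm_id == "abc"],
               1 / 3)
  expect_error(resolvability_analysis(s4, order = 4), "order")
})

test_that("disjoint ternary STMs give uniquely resolvable pair events", {
  # when no other member fits inside the 6 observed spike-ins the true
  # source is the only candidate
  stms <- stm_set(list(c("A", "B", "C"), c("D", "E", "F"),
                       c("G", "H", "I"), c("J", "K", "L")))
  r <- resolvability_analysis(stms, order = 2)
  expect_equal(r$mean_unique, 1)
  expect_equal(r$pooled_unique, 1)
})

test_that("resolvability matches the brute-force oracle on random sets", {
  set.seed(17)
  for (i in 1:8) {
    members <- random_stm_members(sample(4:10, 1), n_spike = 9)
    stms <- stm_set(members, ids = names(members))
    for (ord in 2:3) {
      mine <- resolvability_analysis(stms, order = ord)
      oracle <- oracle_resolvability(members, order = ord)
      expect_equal(mine$per_target$unique_frac, oracle$unique_frac,
                   info = paste("order", ord, "iter", i))
      expect_equal(mine$per_target$two_frac, oracle$two_frac,
                   info = paste("order", ord, "iter", i))
    }
  }
})

test_that("a designed 96-STM plate is mostly uniquely resolvable", {
  stms <- enumerate_stms(default_spikein_panel(), 3)
  layout <- design_layout(stms, 8, 12, seed = 2026)
  used <- unique(layout$wells[!is.na(layout$wells)])
  r <- resolvability_analysis(stms[used], order = 2)
  # per-target fractions partition the event space
  sums <- with(r$per_target, unique_frac + two_frac + other_frac)
  expect_equal(sums, rep(1, 96))
  # a majority of pairwise events trace to a single source; a sizeable
  # minority remain two-candidate ambiguous
  expect_gt(r$mean_unique, 0.4)
  expect_lt(r$mean_unique, 0.8)
  expect_gt(r$mean_two, 0.1)
})

test_that("simulated admixtures recover the mixing fraction", {
  adm <- admixture_experiment(c(0.5, 0.1, 0.05, 0.01), depth = 1e5,
                              spikein_fraction = 0.005, seed = 23,
                              replicates = 2)
  stms <- adm$stms
  ests <- vapply(seq_along(adm$mix_ids), function(i) {
    s <- adm$mix_ids[i]
    estimate_carryover(setNames(adm$sim$table[, s],
                                rownames(adm$sim$table)),
                       "stmA", "stmB", stms = stms)
  }, numeric(1))
  truth <- rep(adm$proportions, times = adm$replicates)
  ratio <- ests / truth
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("contamination events carry members, sources and confidence", {
  stms <- stm_set(list(c("A", "B", "C"), c("C", "D", "E")),
                  ids = c("stm88", "stm89"))
  design <- experiment_design(
    data.frame(sample_id = c("sewage", "soil"),
               expected_stm_id = c("stm88", "stm89")), stms)
  counts <- matrix(c(1000, 900, 1100, 10, 12,
                     2, 1, 1200, 1000, 1100), 5, 2,
                   dimnames = list(c("A", "B", "C", "D", "E"),
                                   c("sewage", "soil")))
  calls <- call_samples(counts, design)
  ev <- contamination_events(calls, design, counts)
  expect_equal(nrow(ev), 2)
  sew <- ev[ev$sample_id == "sewage", ]
  expect_equal(sew$minority_stm, "stm89")
  expect_equal(sew$shared_members, "C")
  expect_equal(sew$exclusive_members, "D;E")
  expect_equal(sew$support_reads, 22)
  expect_equal(sew$carryover_estimate, 22 / 1922)
  expect_equal(sew$candidate_sources, "soil")
  expect_equal(sew$confidence, "ok")
  soil <- ev[ev$sample_id == "soil", ]
  expect_equal(soil$support_reads, 3)   # A:2 + B:1
  expect_equal(soil$confidence, "ok")
  # below min_support -> low confidence
  ev2 <- contamination_events(calls, design, counts, min_support = 5)
  expect_equal(ev2$confidence[ev2$sample_id == "soil"], "low")
  # no minorities -> zero-row frame with the full schema
  clean <- call_samples(counts[1:3, "sewage", drop = FALSE], design)
  expect_equal(nrow(contamination_events(clean, design,
                                         counts[1:3, , drop = FALSE])), 0)
})
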