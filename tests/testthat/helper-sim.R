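# shared fixtures for simulation-based tests

# design spiking the first n layout/enumeration STMs into n samples
make_design <- function(n, stms = NULL, n_unspiked = 0) {
  if (is.null(stms)) stms <- enumerate_stms(default_spikein_panel(), 3)
  spiked <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                       expected_stm_id = names(stms)[seq_len(n)],
                       stringsAsFactors = FALSE)
  if (n_unspiked > 0) {
    spiked <- rbind(spiked, data.frame(
      sample_id = sprintf("ntc%02d", seq_len(n_unspiked)),
      expected_stm_id = NA_character_, stringsAsFactors = FALSE))
  }
  experiment_design(spiked, stms)
}

# two far-apart source STMs plus duplicate admixture libraries per mixing
# proportion; the sink's own STM is stm_a, the contaminating one stm_b
admixture_experiment <- function(proportions, depth = 5e5,
                                 spikein_fraction = 0.005, seed = 1,
                                 replicates = 2, gc_bias_strength = 3.25) {
  stms <- stm_set(list(c("sp01", "sp03", "sp05"),
                       c("sp08", "sp10", "sp12")),
                  ids = c("stmA", "stmB"))
  mix_ids <- as.vector(outer(seq_along(proportions), seq_len(replicates),
                             function(i, r) sprintf("mix%02d_r%d", i, r)))
  samples <- data.frame(
    sample_id = c("srcA", "srcB", mix_ids),
    expected_stm_id = c("stmA", "stmB", rep("stmA", length(mix_ids))),
    stringsAsFactors = FALSE)
  # every mix sample carries stmA; a fraction p of its template is srcB
  contam <- data.frame(
    source = "srcB",
    sink = mix_ids,
    fraction = rep(proportions, times = replicates),
    stringsAsFactors = FALSE)
  # distinct expected STMs are required by verify_and_resolve but not by
  # detection; reuse stmA across mixes is fine for detection tests
  design <- structure(list(
    samples = data.frame(sample_id = samples$sample_id,
                         well = NA_character_,
                         expected_stm_id = samples$expected_stm_id,
                         stringsAsFactors = FALSE),
    stms = stms), class = "experiment_design")
  cfg <- sim_config(design, depth_per_sample = depth,
                    spikein_fraction = spikein_fraction,
                    gc_bias_strength = gc_bias_strength,
                    contamination = contam, seed = seed)
  sim <- simulate_experiment(cfg)
  list(sim = sim, design = design, stms = stms, mix_ids = mix_ids,
       proportions = proportions, replicates = replicates)
}

# smallest proportion whose minority STM is detected in every replicate,
# scanning from the largest down and stopping at the first failure
detection_limit <- function(adm, min_reads = 1) {
  props <- sort(unique(adm$proportions), decreasing = TRUE)
  limit <- NA_real_
  for (p in props) {
    ids <- adm$mix_ids[rep(adm$proportions, times = adm$replicates) == p]
    hit <- vapply(ids, function(s) {
      det <- detect_stms(setNames(adm$sim$table[, s],
                                  rownames(adm$sim$table)),
                         adm$stms, min_reads = min_reads)
      "stmB" %in% det$stm_id
    }, logical(1))
    if (all(hit)) limit <- p else break
  }
  limit
}
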