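# stmtrack

Combinatorial spike-in sample tracking for 16S rRNA amplicon sequencing.

Large multiplexed 16S studies are exposed to two silent failure modes:
**sample swaps** (mislabelled tubes or wells, plate rotations) and
**between-sample cross-contamination** (liquid-handling carry-over, index
hopping). Neither leaves a fingerprint that downstream bioinformatics can
detect, because a community profile carries no intrinsic label. The fix is
molecular: spike every sample, before any processing, with a unique
**sample tracking mix (STM)** — an equimolar pool of *k* synthetic 16S
spike-in controls (typically *k* = 3) drawn from a small panel. A panel of
*n* controls yields C(*n*, *k*) distinct mixes: 12 controls give 220
ternary STMs; 16 controls at *k* = 7 give more than 10,000.

After sequencing, each library's recovered spike-in combination identifies
its sample. An STM *S* is detected when **every** member has ≥ `min_reads`
reads (default 1); among detected STMs, the **majority** (highest
cumulative read count) assigns identity, and any **minority** STM is
contamination evidence. Carry-over from a contaminating sample is
estimated, after symmetric exclusion of spike-ins shared by both mixes, as

    p̂ = (minority-exclusive reads) / (majority-exclusive + minority-exclusive reads)

`stmtrack` is aimed at groups running plate-scale amplicon workflows who
want to design spike-in plates, analyse the resulting counts, and vet the
whole procedure *in silico* first. It covers:

- **Design** — `enumerate_stms()`, `design_layout()` (plates where
  row/column-adjacent wells share no controls), `validate_layout()`
- **Calling** — `classify_reads()` (global-identity read assignment at
  ≥ 97%), `call_samples()`, `verify_and_resolve()` (swap resolution)
- **Contamination** — `contamination_events()`, `estimate_carryover()`,
  `trace_sources()`, `resolvability_analysis()`
- **Simulation** — `simulate_experiment()`: multinomial counts with
  GC-dependent PCR bias, template admixtures, label swaps and index
  cross-talk, with full ground truth

## Worked example

Design a plate, spike 16 samples, then simulate a run in which two samples
were swapped and 5% of sample s01's template leaked into s12:

```r
library(stmtrack)

stms   <- enumerate_stms(default_spikein_panel(), 3)      # 220 ternary STMs
layout <- design_layout(stms, 8, 12, seed = 1)            # 96-well plate
design <- experiment_design(
  data.frame(sample_id = sprintf("s%02d", 1:16),
             expected_stm_id = layout$wells[1:16]), stms)

perm <- setNames(design$samples$sample_id, design$samples$sample_id)
perm[c("s03", "s07")] <- c("s07", "s03")                  # blinded swap
sim <- simulate_experiment(sim_config(
  design, depth_per_sample = 2e5, spikein_fraction = 0.001,
  swap_permutation = perm,
  contamination = data.frame(source = "s01", sink = "s12", fraction = 0.05),
  seed = 11))

calls  <- call_samples(sim$table, design)
report <- verify_and_resolve(calls, design)
report[report$status != "ok", ]
#>    sample_id   expected_stm   majority_stm       status proposed_relabel
#> 3        s03 sp02-sp08-sp10 sp01-sp04-sp07      swapped              s07
#> 7        s07 sp01-sp04-sp07 sp02-sp08-sp10      swapped              s03
#> 12       s12 sp05-sp06-sp10 sp05-sp06-sp10 contaminated             <NA>

contamination_events(calls, design, sim$table)[,
  c("sample_id", "minority_stm", "support_reads",
    "carryover_estimate", "candidate_sources")]
#>   sample_id   minority_stm support_reads carryover_estimate candidate_sources
#> 1       s12 sp02-sp08-sp10             9         0.06818182               s03
#> 2       s12 sp02-sp04-sp08            14         0.07486631               s01
```

The two swapped samples are detected and relabelled exactly (the proposals
invert the applied permutation). The contaminated well s12 keeps its
correct majority STM and shows the contaminant's mix `sp02-sp04-sp08`,
traced to s01, with carry-over estimated at ≈ 7% against a true 5% — GC
bias among the exclusive members skews the simple ratio, which is why the
estimate should be read as order-of-magnitude. The first event illustrates
inherent combinatorial ambiguity: `sp02-sp08-sp10` can be assembled from
the contaminant's members plus the majority's own `sp10`, so a second
candidate source is reported rather than silently dropped —
`resolvability_analysis()` quantifies how often a designed STM set leaves
such events ambiguous (on this package's default 96-STM plates, roughly
60% of pairwise events are uniquely traceable and ~28% have two
candidates).

Planning numbers come from the dosing arithmetic:

```r
expected_spikein_fraction(5e3, 2e5)   # 0.025  -> ~2.5% spike-in reads
expected_reads_per_stm(30000, 0.01, 3)
#>     per_stm per_spikein
#>         300         100
```

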