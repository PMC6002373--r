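---
title: "Combinatorial spike-in sample tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial spike-in sample tracking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmtrack)
```

## The problem

Multiplexed 16S rRNA gene amplicon studies routinely process dozens to
hundreds of samples through plate-based DNA extraction, two rounds of PCR
and pooled sequencing. Two failure modes are essentially invisible to
downstream bioinformatics: *sample swaps* (tube or well mislabelling, plate
rotations) and *between-sample cross-contamination* (well-to-well carry-over
during liquid handling, index hopping on patterned flow cells). Both corrupt
study conclusions silently, because a microbial community profile carries no
intrinsic label.

The remedy implemented here is molecular: each sample receives, before any
processing, a unique **sample tracking mix (STM)** — an equimolar pool of
*k* synthetic 16S spike-in controls drawn from a small panel. The controls
are near-full-length 16S genes with artificial variable regions, so they
amplify with the universal primers yet match nothing in nature. After
sequencing, the combination of spike-ins recovered in each library
identifies the sample; a wrong combination exposes a swap, and a second,
low-abundance combination exposes and quantifies contamination.

Combinatorics is what makes this cheap: a panel of $n$ controls yields
$\binom{n}{k}$ distinct mixes. With $n = 12$ and ternary mixes ($k = 3$)
there are 220; $k = 6$ gives 924; and 16 controls at $k = 7$ already exceed
10,000 mixes.

## STM calling model

For a library with feature counts $c_f$, an STM $S$ (member set $M_S$) is
**detected** iff every member is supported:
$\min_{m \in M_S} c_m \ge$ `min_reads` (default 1). Its cumulative count is
$\sum_{m \in M_S} c_m$. Among detected STMs the **majority** is the one with
the highest cumulative count and assigns the sample's identity; all others
are **minorities**, i.e. contamination evidence. Exact ties are broken
lexicographically on the STM id and flagged `ambiguous_majority` — a
convention, since real data essentially never ties.

The screening set is the STMs *used in the experiment* (the design), not
the full combinatorial panel. This is deliberate: with heavily overlapping
member sets, a full-panel screen can assemble spurious composite STMs from
the members of the majority plus a stray read. A flag to widen the screen is
available via passing a larger `stm_set` to `call_samples()`.

Requiring *all* $k$ members jointly is the package's noise floor: index
cross-talk at realistic rates (about $1.4 \times 10^{-5}$ per read) deposits
isolated single reads of individual controls in other libraries, which never
constitute a full mix. Such stray reads are carried in
`total_spikein_reads` but cause no detection. A majority resting on very few
reads (below `low_support_reads`, default 10) is reported as a valid call
with a `low_support` flag rather than suppressed — there is no principled
read cutoff above the per-member rule, so judgement is deferred to the
analyst.

**Swap resolution.** If the majority STM differs from the design's
expectation, the sample whose *expected* STM equals the observed majority is
proposed as the true label. Because expected STMs are unique within an
experiment, the proposals form a partial permutation; if two libraries ever
claim the same relabel, both are downgraded to `ambiguous` rather than
guessed at.

## Carry-over quantification

For a majority STM $A$ and minority STM $B$, reads on shared members
$A \cap B$ cannot be attributed to either sample, so they are excluded
symmetrically, and

$$\widehat{p} \;=\;
\frac{\sum_{m \in B \setminus A} c_m}
     {\sum_{m \in A \setminus B} c_m + \sum_{m \in B \setminus A} c_m}.$$

Excluding shared members from *both* sides cancels the $k/(k-s)$ scaling
that would otherwise bias the ratio when $s$ members are shared. With equal
spike-in dosing and no amplification bias, $\widehat{p}$ estimates the
template mixing fraction directly; the simulator-based tests verify
recovery within a factor of two down to 1% mixing at realistic depths. The
wording "proportion of spike-in reads assigned to the minority STM" is
ambiguous about its denominator, so the package also reports
`raw_minority_fraction` (minority-exclusive reads over all spike-in reads)
for comparability with headline percentages quoted that way. Events with
fewer than 3 minority-exclusive reads are flagged low-confidence.

## Source tracing and resolvability

A minority STM traces to the design sample(s) expected to carry it
(`trace_sources()`). The subtler question is ambiguity: given the observed
spike-in *superset* of a contaminated library, which single STMs could
explain it? `candidate_sources_for()` returns every STM $T \neq$ target with
$(\text{observed} \setminus \text{target}) \subseteq T \subseteq
\text{observed}$.

`resolvability_analysis()` brute-forces the event space. For order 2, every
ordered (target, source) pair is an event; it is *uniquely resolvable* when
exactly one candidate exists (necessarily the true source) and
*two-candidate* when two do. For order 3, events are (target, unordered
source pair) and candidates are unordered STM pairs covering the non-target
observed members without exceeding the observed set; the event space for
three-sample contamination is not canonically defined anywhere, so this
definition is stated explicitly and the implementation is tested against an
independently written exhaustive oracle on random STM sets. Fractions are
computed per target STM, then averaged (mean ± SD across STMs, matching the
convention of quoting variability across mixes); pooled fractions over all
events are exposed alongside.

On a 96-STM plate designed by this package from the default 12-control
panel, order-2 resolvability lands around 60% uniquely resolvable and 28%
two-candidate (the test suite bounds these; run the chunk to reproduce):

```{r resolvability, eval = FALSE}
stms <- enumerate_stms(default_spikein_panel(), 3)
layout <- design_layout(stms, 8, 12, seed = 2026)
resolvability_analysis(stms[unique(na.omit(c(layout$wells)))], order = 2)
```

Order-3 unique resolvability collapses to well under a percent for such
sets — with nine observed spike-ins, many STM pairs cover the six non-target
members — which is why contamination involving three or more samples should
be treated as detectable but rarely traceable.

## Plate layout design

`design_layout()` arranges STMs on a plate so that row- and column-adjacent
wells share **no** spike-in controls; diagonal neighbours are deliberately
unconstrained (the guarded failure modes — single-neighbour pipetting
carry-over and row/column shifts — act along rows and columns). The solver
is a seeded randomized greedy fill in row-major order with backtracking and
restarts. Any complete solver satisfying the constraint is acceptable;
randomized greedy was chosen because the constraint graph is loose (220
candidates for 96 wells) and it finds a valid plate in milliseconds while
remaining reproducible from its seed. Infeasibility (or budget exhaustion)
raises an explicit `stmtrack_no_layout` error; a partial plate is never
returned silently. Each STM is used at most once per plate by default;
`allow_reuse = TRUE` permits repetition for multi-plate designs where the
same plate pattern is reused.

## The simulator

`simulate_experiment()` generates count tables with ground truth, composing
the rates a spike-in experiment actually exhibits. Per sample, expected
feature weights are a Dirichlet-distributed dummy-taxa background (default
50 taxa, concentration 0.5 — pure diluent, no biological meaning) plus the
sample's STM members weighted by GC-dependent efficiency and summing to the
spike-in read fraction. Effects apply in physical order:

1. **GC bias** — efficiency $\exp(-\beta\,(\text{GC} - 0.5))$. Only the
   negative monotone relationship between detection rate and amplicon G+C
   is empirically established; the exponential form is an implementation
   choice. The default $\beta = 3.25$ with the default panel (11 controls
   spanning GC 0.45–0.61 plus one GC-rich control at 0.67) was set
   analytically so that mean within-STM shares across all ternary STMs span
   roughly 24–41% around the unbiased 33.3%, the spread observed in
   practice for a 12-control panel.
2. **Contamination** — template mixing: a sink's expected composition
   becomes $(1-\sum_i p_i)\,w_{\text{sink}} + \sum_i p_i\,w_{\text{source},i}$.
3. **Sequencing** — multinomial draws at fixed per-sample depth. No
   overdispersion is assumed (none is established for this design); a
   negative-binomial depth jitter exists behind `depth_dispersion` and
   defaults off.
4. **Index cross-talk** — each read moves to a uniformly chosen other
   sample with probability `crosstalk_rate`, default $1.4\times10^{-5}$,
   the scale estimated from unused index combinations in real runs.
5. **Label swaps** — a permutation relabels finished libraries last.

Dosing arithmetic is exposed directly: `expected_spikein_fraction(5e3, 2e5)`
= 0.025 (dosing $5\times10^3$ spike-in copies per ng into DNA with
$2\times10^5$ amplifiable 16S copies per ng yields ~2.5% spike-in reads),
and `expected_reads_per_stm(30000, 0.01, 3)` = 300 reads per STM / 100 per
control, the planning numbers for a typical 30k-read sample at a 1%
spike-in level.

**What the simulator does not emulate:** read-level errors and chimeras,
PhiX, run-to-run instrument carry-over, taxon-specific amplification bias
in the background, and the unexplained depression of realized spike-in
fractions sometimes seen in practice (the spike-in fraction is therefore a
direct parameter, not derived from a mechanistic model). Passing simulation
tests demonstrates the *logic* of calling, tracing and quantification under
the stated generative assumptions — not robustness to every artefact of
real libraries.

## Read classification

`classify_reads()` is a desk-scale stand-in for the reference-mapping step:
global (end-to-end) alignment against each spike-in reference, assignment
to the unique best hit at ≥ 97% identity. Identity is defined as matched
columns over *all* alignment columns, terminal gaps included — external
tools differ on this, so the convention is fixed and documented here rather
than inherited. IUPAC ambiguity codes match compatibly (N matches
anything), since merged reads may retain ambiguous calls; exact ties are
left unassigned and flagged. Chimera detection is intentionally out of
scope; inputs are assumed chimera-filtered upstream. Alignment is delegated
to Biostrings; the identity computation over aligned columns is the
package's own, so the convention cannot drift with a library default.

## Numerical and scale choices

Tests and the acceptance script run entirely on simulated data at sizes
chosen to keep the whole suite in minutes while leaving comfortable
statistical margins: swap experiments use 16 samples at depth $2\times10^5$
and a 0.1% spike-in fraction (a few hundred spike-in reads per sample —
tens of reads per control suffice for calling); admixture series use
duplicate libraries at $5\times10^5$ reads and 0.5% spike-in fraction over
mixing fractions 50% down to 0.1%, where the 1% mixtures leave ~25 minority
reads (comfortably detected) and 0.1% leaves ~2.5 (below the
all-members-in-both-replicates rule — the intended detection limit);
resolvability oracle checks use random STM sets of up to 12 mixes, where
exhaustive enumeration is instant. Seeds are fixed throughout; every
simulation is reproducible from `(config, seed)`.

## Known limitations

- Carry-over estimates inherit amplification bias: if the minority STM's
  members amplify poorly, mixing is underestimated. The estimator is
  intentionally simple; no bias correction is attempted.
- Multi-source deconvolution beyond listing candidate pairs (order 3) is
  out of scope, as is correcting taxa counts for estimated carry-over.
- `resolvability_analysis(order = 3)` is exhaustive and scales as
  $O(m^5)$ in the number of STMs; it is instant for tens of mixes but slow
  for a full 96-STM plate. Order 2 on 96 STMs takes a few seconds.
- The layout solver optimizes nothing beyond feasibility (no edge-effect
  or evaporation balancing).
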