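---
title: "Methods: from expression matrix to prioritized lncRNAs"
author: "lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from expression matrix to prioritized lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

## The problem

Transcriptome profiling of case versus control cohorts (for example PBMC
microarrays of fibromyalgia patients against healthy donors) produces
thousands of modulated features. Most downstream biology, however, hangs on
a much smaller object: the handful of regulatory long non-coding RNAs
(lncRNAs) whose targets — reached either by direct interaction or by
sequestering microRNAs — concentrate in the densely interacting regions of
the differentially-expressed-gene (DEG) network. `lncnet` implements that
funnel as a reusable, fully tested pipeline:

1. call DEGs from a normalized log2 expression matrix;
2. induce a protein–protein interaction (PPI) network on the coding DEGs;
3. detect dense gene modules with a seeded, MCODE-style clustering;
4. test gene lists for over-representation against gene-set collections;
5. resolve lncRNA→miRNA→gene chains against the DEG set and prioritize the
   lncRNAs whose targets reach **every** detected module.

Because studies of this design rarely deposit raw data, the package ships a
synthetic-data generator that emulates all pipeline inputs with planted
ground truth, so every stage is testable by recovery.

## Differential expression

Each feature is tested with Welch's two-sample *t*-test on log2 values;
`log2fc = mean(case) − mean(control)` and the signed linear fold change is
`sign(log2fc) · 2^|log2fc|`, so down-regulation appears as a negative
reciprocal (−4.52 means 4.52-fold down). The vendor software used in the
motivating study does not document its statistic; Welch's test is the
simplest defensible two-group test for normalized array intensities, and it
is isolated behind `compute_differential()` so a moderated-variance test
could be substituted without touching the rest of the pipeline.

Multiplicity is controlled by Benjamini–Hochberg across **all** features —
coding and lncRNA in one family — which is the conservative reading when
the same filter is applied to both classes. Selection uses
`|FC| ≥ 1.5` and `q ≤ 0.01`, both boundaries inclusive ("at least" / "≤").
Features that are constant in both groups get `p = 1`; zero-variance
features whose means differ exactly (the noiseless limit) get `p = 0`.

## Module detection

The detector re-implements the published MCODE scheme. Every node is
weighted by the highest k-core of its closed neighborhood: if that core has
order `k` and edge density `d` (density `2m/(n(n−1))`, 0 for `n < 2`), the
weight is `k·d`. The highest-weight unused node seeds a candidate, which
grows breadth-first through neighbors whose weight strictly exceeds
`seed_weight · (1 − cutoff)` with cutoff 0.2; every included node is marked
used, so modules are disjoint and runs are order-independent.

Candidates are post-processed in three steps:

* **haircut** (default on, matching the plugin default): iteratively remove
  members with within-candidate degree < 2;
* **coherence**: remove candidate edges that close no triangle within the
  candidate and split the candidate into connected components. A single
  bridge edge between two dense regions has no triangle support and is
  severed, so it cannot fuse two modules, while edges inside a near-clique
  always survive (two members of a dense region share neighbors). This step
  is this package's design choice: with core-based weights a bridge's
  endpoints weigh as much as interior nodes, so threshold expansion alone
  would walk across the bridge and merge both regions;
* **core filter**: discard components that do not contain a non-empty
  k-core at `k = 4` (the "k-core = 4" parameter of the plugin, read as a
  containment requirement).

Modules are scored `density × size` and labeled `M1, M2, …` in descending
score; ties break by larger size, then lexicographically smallest member.
The fluff stage exists (`fluff = TRUE`) but defaults off because it breaks
module disjointness.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
`P[X ≥ n_overlap]` — only enrichment, never depletion, is reported in this
design. Two regimes are exposed: uncorrected `p < 0.05` (strict, the GO
biological-process convention) and Bonferroni `p ≤ 0.05` (the pathway
convention); both comparators follow the conventions as printed and are
configurable. The universe defaults to the full feature annotation supplied
to the run — standard ORA practice — not the DEG list. Query and set members
outside the universe are dropped at test time with a logged count.

## The lncRNA cascade

Modulated lncRNAs pass four gates, and all records are returned with their
pass flags so the funnel is auditable:

1. `passed_fc`: `|FC| ≥ 4`, inclusive ("above or equal to four");
2. `passed_mirna`: at least one experimentally validated lncRNA–miRNA pair;
3. `passed_deg`: a non-empty targeted-DEG set, where targets are the union
   of direct lncRNA→gene partners and the genes of all targeted miRNAs,
   intersected with the **coding** DEG set (module genes are proteins; a
   flagged record reached both ways counts once);
4. `prioritized`: the covered-module set — labels of modules whose members
   intersect the targeted DEGs — equals the full label set of all detected
   modules. Full coverage, not a majority.

The gates commute (each is a row filter), so composing them in the
published order equals intersecting their individual pass sets; the tests
assert this.

## The synthetic study

`generator_config()` defaults define the reference conditions: 2000 coding
and 300 lncRNA features, 10 cases vs 10 controls, 5% planted DE with linear
|FC| uniform in [1.8, 6], i.i.d. Gaussian log2 noise with sd 0.3 (log-normal
intensities, the standard microarray approximation), baseline log2 means
uniform in [5, 12] (inert to the statistics; keeps intensities in array
range), six planted 8-gene modules, background edge probability 0.01, two
driver lncRNAs and four decoys. One root seed (default 17) feeds every
stage through a documented splitting rule (`child_seed()`; streams 1–4 for
cohort, network, annotation, gene sets), so identical configs produce
byte-identical fixtures.

Design choices that deserve justification:

* **Driver fold changes.** Drivers are planted at
  `|FC| = max(driver_fc_min, max(fc_range)) = 6`. The FC ≥ 4 gate is applied
  to *estimated* fold changes whose log2 standard error at the default
  noise is `0.3·√(2/10) ≈ 0.134`; planting drivers at the gate's edge would
  make recovery a coin flip per seed, which would test sampling noise, not
  the cascade. The threshold-adjacent regime is exercised deliberately by
  the low-FC decoy, planted at |FC| 2.5 — five standard errors *below* the
  gate.
* **Decoy taxonomy.** One decoy per failure mode: (a) |FC| < 4 with
  otherwise complete chains into every module; (b) no miRNA annotation but
  direct DEG targets; (c) miRNA and direct targets that all miss the DEG
  set; (d) complete chains into all modules except the last. Each cascade
  gate is therefore falsifiable by exactly one planted record.
* **Module dropout.** Dropout removes a random *matching* — at most 10% of
  clique edges, and no member loses more than one within-module edge — so
  every member keeps within-module degree ≥ size − 2 (≥ 4 for the minimum
  size 6). Independent per-edge dropout concentrates losses on unlucky
  members, depresses their neighborhood-core weights below the expansion
  threshold, and makes whole planted modules undetectable at the pinned
  cutoff; matching dropout preserves the spec of the planted object —
  "a near-clique that the detector must recover" — without touching any
  detector parameter.
* **Background edges** connect DE genes and a 50-gene margin of non-DE
  coding genes, but never two module members: member–member shortcuts
  between different modules would make the planted module partition
  ambiguous as ground truth (any MCODE-style expansion would merge them).
* **Null cohorts.** `frac_de = 0` (with `module_count = 0`) generates a
  no-signal cohort used to check the DEG caller's false-selection rate.

What the generator does **not** emulate: probe-level effects, batch
effects, correlated noise between features, sample covariates, and the
hub-dominated degree distribution of real PPI networks. Passing recovery
tests therefore demonstrates algorithmic correctness under the stated
noise model, not robustness to the full messiness of real array data.

## Numerical and determinism notes

* Estimated fold changes at the default noise are unbiased with log2
  standard error ≈ 0.134; about 70% of planted features land within ±10% of
  their planted linear FC, and the tests assert that calibrated figure
  rather than a tighter one.
* All character tie-breaks (edge canonicalization, seed choice, labels) use
  locale-independent radix ordering; two runs of one config are
  byte-identical, which the suite checks file-by-file.
* k-core extraction is iterative peeling; on graphs of ≤ 12 nodes it is
  tested against an exhaustive subset-search oracle (the k-core is the
  unique maximum subset with induced minimum degree ≥ k, since feasible
  subsets are closed under union).
* BH q-values are tested against a brute-force step-up oracle; the
  hypergeometric tail against complete enumeration of draws on universes
  ≤ 12.

## Problem sizes used by the test suite

The recovery suite runs the full pipeline at the default generator
conditions (2300 features, 20 samples, 6 modules) across seeds 1–20, the
null-rate check across 50 seeded replicates, and the k-core oracle
equivalence on 200 random graphs of ≤ 12 nodes — sizes at which the
exhaustive oracles are exact and the whole suite stays inside a couple of
minutes on one CPU.

## Known limitations

* The Welch/BH choice is a documented default, not a claim about the
  vendor pipeline that motivated it; with two samples per group at minimum
  it is valid but underpowered.
* Enrichment replicates neither a specific GO release nor a pathway
  database; collections are inputs.
* Identifiers are opaque case-sensitive strings: no symbol aliasing or ID
  mapping is attempted.
* With no detected modules, module coverage is undefined and the cascade
  raises an error rather than prioritizing nothing silently.
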