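---
title: "poolscreen: models and methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

This vignette documents the statistical model behind `poolscreen`: what
the screen simulator emulates and deliberately does not, how genes are
scored and classified, which parameter defaults were chosen and why, and
the numerical conventions that make results exactly reproducible.

# The screening model

## Library

An `SgRNALibrary` holds guides with a fixed number of guides per gene
plus non-targeting controls (NTCs). The reference design used throughout
the package's study-scale checks is 2610 genes × 4 guides + 1000 NTCs =
11,440 guides. NTCs carry no `gene_id` and never enter gene scores; they
exist solely to build the empirical null.

## Generative simulator

The simulator (`simulateFitnessScreen()`, `simulateFacsScreen()`)
composes the following stages, each seeded independently (see
*Reproducibility* below):

1. **Plasmid pool.** True guide abundances are i.i.d. log-normal with
   mean 1 and coefficient of variation `plasmid_dispersion`
   (`sdlog = sqrt(log(1 + CV^2))`), normalized to sum to one. The
   sequenced plasmid sample is a multinomial draw of
   `plasmid_depth × n_guides` reads.
2. **Transduction.** Each of `n_cells` cells receives a
   Poisson(`moi`) number of integrations; uninfected cells are removed
   (puromycin selection), so integration counts among survivors are
   zero-truncated Poisson. Cells with several integrations
   (*multiplets*) are retained, as they are in real screens at low MOI.
   Each integration is independently "edited" with probability
   `edit_efficiency`; unedited integrations confer no phenotype.
3. **Selection.** A clone carrying an edited integration of a gene with
   selection coefficient *s* multiplies its relative weight by
   `(1 + s)` per passage; effects of multiple edited integrations in one
   clone multiply. With a finite `bottleneck`, each passage resamples
   clones multinomially to the bottleneck size, adding genetic drift;
   with `bottleneck = Inf` the dynamics are deterministic expectations.
4. **Expectation mode.** With `n_cells = Inf` the population is
   represented by exactly two clones per guide — an edited clone with
   weight `edit_efficiency` and an unedited one with the remainder — and
   propagated deterministically. This is a first-order approximation
   that ignores multiplets (a cell carrying two guides contributes to
   both), trading a small bias for exact, fast dynamics; it is the mode
   used for large-scale calibration runs.
5. **Sequencing.** Each sample is an independent multinomial draw of
   `seq_depth` reads proportional to current guide abundance.
6. **FACS sorting** (reporter arm). Every clone has a probability of
   appearing in the reporter-low gate,
   `p_low = 1 − (1 − p_bg) × Π (1 − p_loss(g))` over its edited
   integrations, where `p_bg` is the background (reporter-silencing)
   rate. The sorted sample draws cells proportional to
   `weight × p_low`, capped at `sort_fraction` of the population, and is
   then sequenced. Note that because `p_low` compounds `p_bg` with
   `p_loss`, setting `p_loss = p_bg` is *not* a null configuration —
   only `p_loss = 0` sorts a gene's clones at exactly background rate.

### What the simulator does not emulate

- PCR amplification bias and jackpotting (sequencing is a single
  multinomial).
- Guide-specific cutting efficiency or off-target effects
  (`edit_efficiency` is a single global Bernoulli rate).
- In-frame repair producing partial alleles; editing is binary.
- Time-varying selection, cell-cycle structure, or lineage correlations
  beyond the clone bottleneck.
- In expectation mode, multiplets (see above); finite-cell mode does
  model them.

## Scoring

For samples *initial* and *final*, each guide's log2 fold-change is
computed on reads-per-million plus a pseudocount of 1:

`lfc = log2( (rpm_final + 1) / (rpm_initial + 1) )`-style, implemented
as RPM on `counts + pseudocount`. The pseudocount bounds the statistic
for dropout guides (a guide going from hundreds of reads to zero yields
a large but finite negative value) at the cost of shrinking fold-changes
of low-abundance guides toward zero.

The **CRISPR Score** of a gene is the unweighted arithmetic mean of its
guides' log2 fold-changes. No variance weighting or guide filtering is
applied: the mean over a fixed panel of 4 guides is transparent,
linear, and directly comparable across genes.

## The NTC pseudo-gene null and classification

`buildNtcNull()` draws `n_pseudo` (default 10,000) pseudo-genes, each
the mean of `guides_per_pseudo` (default 4, matching the library design)
NTC log2 fold-changes sampled without replacement within a pseudo-gene.
This null captures everything a neutral gene experiences — sequencing
noise, drift, and compositional shifts from renormalization — because
NTC guides ride through the same pipeline.

`classifyGenes()` computes one-sided empirical tail p-values with the
add-one convention `p = (r + 1) / (n + 1)` (so p is never zero and is
valid under the null), applies Benjamini–Hochberg within each tail
across genes, and labels a gene `essential` (lower tail) or
`growth_restricting` (upper tail) when its tail q-value is at most `fdr`
(default 0.05). `classVsNtcTest()` provides a Welch two-sample t-test of
a class's scores against the pseudo-gene null as an effect summary.

A consequence worth noting: normalization is compositional, so strong
dropout of part of the library shifts every other guide's fold-change
slightly upward. The NTC null shifts identically, which is exactly why
classification is performed against it rather than against zero.

## Dual-screen intersection

`rankAndIntersect()` takes the top *k* (default 20) genes per screen by
CS — most negative for `"depleted"`, most positive for `"enriched"` —
with ties broken lexicographically by gene id, and returns the
intersection ordered by mean rank (ties again by gene id). The
deterministic tie rule guarantees identical output for identical input;
its cost is that at very low sequencing depth, tied scores resolve the
same way in both screens and can correlate otherwise independent
rankings.

# Regulatory integration

Peaks are exchanged as BED (0-based, half-open) and held as `GRanges`
(1-based, closed); conversions happen only at I/O boundaries. Promoter
windows are symmetric `[tss − 1000, tss + 1000)` around the annotated
TSS; strand affects only where the TSS sits.

- `annotatePeaks()`: each peak gets exactly one category with precedence
  **promoter > gene body > intergenic**, using any-overlap (≥ 1 bp).
- `overlapFraction()`: fraction of set A peaks overlapping set B by at
  least `min_bp` (default 1).
- `callCREs()`: an *active promoter* is an open-chromatin region
  carrying H3K4me3 that overlaps a TSS window (linked to the gene(s)
  whose window it hits); an *active enhancer* is an open region with
  H3K4me1 and H3K27ac that is not a promoter. Promoter precedence makes
  the sets disjoint by construction.
- `defineTargets()`: a TF target gene must have a TF-bound promoter CRE
  and show `log2fc < −1` with `p < 0.05` in *both* the knockout and the
  differentiation differential-expression tables.

`makeRegulatoryFixtures()` generates small synthetic landscapes with
planted truth for exactly these rules, which the test suite recovers
exactly.

# Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| `guides_per_gene` | 4 | Standard compact-library design; matches pseudo-gene size |
| `plasmid_depth` | 500 | 500× per-guide coverage, a common sequencing budget |
| `plasmid_dispersion` | 0.5 | Moderate log-normal skew typical of cloned pools |
| `moi` | 0.3 | Low-MOI regime: ~14 % of infected cells are multiplets; mostly single integrations without discarding too many cells |
| `edit_efficiency` | 0.8 | High-activity Cas9; leaves a visible unedited floor in dropout dynamics |
| `n_passages` | 10 | Enough doublings for `(1+s)^t` to separate moderate effects from noise |
| `bottleneck` | `Inf` | Drift off by default; finite values opt into stochastic passaging |
| `seq_depth` | 500 × guides | Matches plasmid coverage so sampling noise is balanced across samples |
| `p_bg` | 0.02 | Small background reporter-silencing rate; sets the floor of FACS enrichment (max enrichment ≈ `p_loss/p_bg`) |
| `sort_fraction` | 0.05 | Typical low-gate sort stringency |
| `pseudocount` | 1 | Bounds dropout log-ratios; standard RPM convention |
| `n_pseudo` | 10,000 | Null resolution of 1e-4 in p; add-one keeps p ≥ 1/(n+1) |
| `fdr` | 0.05 | Conventional discovery threshold |
| `promoter_halfwidth` | 1000 | TSS ± 1 kb promoter definition |
| `lfc_cut`, `p_cut` | 1, 0.05 | Two-fold change at nominal significance for target calling |

These defaults are the package's study conditions; analyses in the test
suite and acceptance script run at these values unless a property
specifically requires otherwise (e.g. finite bottlenecks for drift
properties).

# Numerical choices and reproducibility

- **Stage seeding.** Every stochastic stage derives its seed as
  `stageSeed(seed, stage) = (seed × 48271 + stage × 10007) mod
  2147483629` and runs under `withr::with_seed()`, so stages are
  independently reproducible and the global RNG state is never touched.
- **Zero-truncated Poisson** integration counts are drawn by inverse
  CDF: `qpois(runif(n, ppois(0, m), 1), m)`.
- **Exact selection dynamics.** Clone weights are propagated
  unnormalized, so after *t* passages an edited clone's relative weight
  is exactly `(1 + s)^t` (verified to 1e-15 in the tests).
- **Canonical serialization.** Tables are written with full-precision
  `%.17g` formatting; reruns of one configuration are byte-identical,
  and run manifests record an MD5 of the configuration file.
- **Empirical p-values** use `findInterval()` on the sorted null for
  O(log n) tail counts, with the add-one convention.

# Open design decisions and limitations

- **Expectation-mode multiplets.** The two-clone-per-guide expectation
  representation ignores multiplet co-occurrence; a second-order mode
  tracking guide pairs would remove this bias at considerable cost.
- **Global edit efficiency.** Per-guide efficiencies drawn from a
  distribution would make recall estimates more conservative; the
  current single rate keeps closed-form checks exact.
- **Normalization.** RPM with pseudocount is compositional; median-of-
  NTC normalization would de-shift neutral guides directly but couples
  samples. The package instead keeps raw RPM and accounts for
  composition via the NTC null.
- **Per-tail BH.** FDR is controlled within each direction separately;
  a joint two-sided procedure would be slightly more conservative.
- **Regulatory rules are deliberately rule-based** (any-overlap,
  fixed windows, hard DE cutoffs), prioritizing auditability over
  statistical modeling of peak signal; `promoterSignal()` provides the
  length-weighted signal summarization used for continuous tracks.

# Session info

```{r}
sessionInfo()
```
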