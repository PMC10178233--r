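---
title: "Structure-partitioned GC evolution of ITS2: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-partitioned GC evolution of ITS2: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2gc)
```

## The question

The internal transcribed spacer 2 (ITS2) of nuclear ribosomal DNA is a
multicopy marker that evolves under two intertwined forces. Concerted
evolution — unequal crossing over and gene conversion within the rDNA
array — homogenizes the hundreds of tandem copies within a genome. GC-biased
gene conversion (gBGC) rides on the same recombination events: when a
heteroduplex forms between divergent copies, mismatch repair prefers the
G/C-carrying strand. If both act, homogeneous ITS2 families should also be
GC-rich, and the substitution process in the base-paired stems of the
conserved ITS2 secondary structure should show an excess of changes *into*
GC pairs.

`its2gc` implements the full analysis chain needed to test this on aligned
sequence–structure allele sets: structure-aware partitioning, composition
and diversity statistics, base-pair (doublet) substitution models, and the
derived GC-evolution statistics — plus a synthetic allele-family generator
so the whole chain runs, and is tested, without any external data.

## Data model and partitioning

Input is the Vienna-triplet dialect (`read_seqstruct()`): per allele a
header (optionally `count=N` for its copy number), the aligned RNA
sequence, and a dot-bracket structure of the same length. Alleles
supported by a single copy are treated as probable
sequencing/assembly artifacts and removed (`filter_singleton_alleles()`)
before anything else.

A consensus structure retains each base pair (i, j) present in at least a
fraction `threshold` (default 0.70) of the alleles' individual structures;
the retained set is made non-crossing greedily in decreasing support, ties
to the smaller opening position (`consensus_structure()`). Columns then
split into *paired* (stem) and *unpaired* (loop/linker) regions
(`partition_columns()`), and each consensus pair becomes one 16-state
doublet site per allele, with a gap or N on either side treated as missing
(`encode_doublets()`). The 0.70 consistency setting is taken over from
common sequence–structure alignment practice; whether that tool's
"consistency" is per-pair support or whole-structure identity is not
documented, so per-pair support is the definition used here. All
coordinates are 1-based, matching R indexing; reports print the same
coordinates.

## Composition statistics

- `gc_content()`: per-allele GC percent over a column selection, gaps/N
  excluded; the species value is the unweighted mean over distinct
  alleles. Copy counts are deliberately ignored — the analysis treats
  variants, not reads, as units, and the output metadata records this.
- `gc_homogeneity()`: sample SD (n − 1) of per-allele GC, the "how much do
  copies disagree in GC" measure.
- `avg_nucleotide_differences()`: K, the mean count of differing positions
  over all unordered allele pairs, with pairwise deletion of gaps/N (the
  DnaSP convention). Unweighted for the same reason as GC.
- `spearman_correlation()` and `shapiro_wilk()` wrap the standard R tests
  (t-approximation p for Spearman, average ranks for ties);
  `base_frequency_profile()` is the tabular stand-in for a sequence logo.

## Substitution models

Unpaired columns evolve under a 4-state model: HKY85 (κ plus free base
frequencies) or REV/GTR. Paired sites evolve under a doublet model on the
16 ordered pairs with the defining constraint that both nucleotides never
change at once: rates exist only between doublets differing at one
position, so pair turnover must pass through intermediates such as
GC–GU–AU. All models are reversible by construction (q_ij = s_ij π_j) and
normalized to one expected substitution per unit time; the transition vs
transversion identity of the changing nucleotide gives a two-class
exchangeability (κ).

The fitted family is a parameterized stand-in for the classical RNA model
zoo, whose exact parameter counts are not published in a recoverable form:

- `pair16_free` — 16 free doublet frequencies + κ (the default, closest to
  a "general 16-state, no double substitutions" model);
- `pair16_prod` — doublet frequencies constrained to products of 4
  nucleotide frequencies + κ;
- `pair7_free` / `pair7_fixmm` — the 7-state space (AU, GU, GC, UA, UG,
  CG, MM) lumping the ten non-canonical doublets into MM, with free or
  empirically fixed MM frequency;
- DNA-only — every column, paired included, under the 4-state model.

Three choices make fits comparable across these spaces. First, the AICc
sample size is the number of *sites*: one per consensus pair plus one per
unpaired column, identically for every candidate. Second, a 7-state fit is
scored on the 16-state observation space by adding log(1/10) per observed
mismatch token (a uniform identity distribution given MM) — without this,
coarser state spaces get a spurious likelihood subsidy. Third, every
mixed candidate carries a free paired-partition rate multiplier
(`pair_rate`): branch lengths are estimated in per-column units while the
doublet model is normalized per pair site, and the stem clock genuinely
differs from the loop clock, so forcing a shared rate distorts the
nucleotide parameters (empirically, κ was biased upward by ~15% without
it).

Likelihoods come from Felsenstein pruning over each partition, with
missing symbols marginalized, site patterns compressed, and transition
probabilities from the symmetrized eigendecomposition (a Padé
scaling-and-squaring exponential serves the non-reversible simulation
generators). Trees default to neighbor joining on Jukes–Cantor-corrected,
pairwise-deletion distances with negative branches clamped to zero;
branch-length optimization is opt-in (`optimize_branch_lengths = TRUE`)
and is used wherever parameter values, not just rankings, matter. ML
optimization is bounded quasi-Newton (L-BFGS-B) on log rates and
reference-cell softmax frequency coordinates.

`mcmc_sample()` provides a random-walk Metropolis–Hastings alternative
with iid standard-normal priors on the transformed coordinates (so
prior-only runs are exactly checkable), a step size adapted toward ~30%
acceptance during burn-in, and an equilibrium rule that re-runs the chain
at doubled length and declares convergence when no posterior-mean
parameter moves by more than 1% — the "more iterations change nothing"
criterion operationalized.

## GC-evolution statistics

*Equilibrium GC.* For a nucleotide model, GC\* = 100·u/(u + v), where u is
the stationary per-AT rate into G/C and v the per-GC rate into A/T; for a
reversible model this provably equals the stationary GC mass (a property
test asserts it to 1e−10 on random models). For a doublet model, GC\* is
the stationary GC fraction of the chain, 100·Σ π_d g(d) with g(d) the
fraction of G/C in doublet d. `gc_trend()` classifies each region as
increasing/decreasing/stable against current GC with a 0.1-point band.

*Formation rates.* Each target pair (GC, CG, AU, UA) has exactly six
single-change source doublets; `formation_rates()` reads those rate-matrix
entries (relative rates under unit-mean normalization, matching how such
matrices are conventionally displayed), totals them by destination type,
and reports the GC:AU ratio alongside the stationary GC-type and AU-type
pair frequencies. *Plain ratios* are reported throughout; the package
never rephrases them as "X% higher", a phrasing that is ambiguous between
ratio and ratio − 1.

*Mismatch conversion.* The four repairable mismatches A·G, A·C, C·U, G·U
each map to two ordered doublets, and one-side repair takes each to one
GC-type and one AU-type Watson–Crick pair (A·G → CG or AU, A·C → GC or
AU, C·U → CG or AU, G·U → GC or AU): eight route groups. Rates are means
over the two orderings; the aggregate GC:AU ratio is the conversion-bias
summary. Under the κ-class exchangeabilities the formation and mismatch
ratios coincide algebraically (both reduce to the stationary GC-type:AU-type
frequency ratio); they would differ under a free exchangeability matrix,
and both are reported for that reason.

G·U is deliberately on both lists: as a wobble pair it is the intermediate
of the GC–GU–AU pathway, and in a recombination heteroduplex it is also a
repairable mismatch.

## The synthetic generator

`simulate_family()` is a forward model of the assumed biology, not a
convenience fixture, and its defaults are the study conditions every test
runs under:

- 29 species-level families, 260 aligned columns (ITS2-like 240–277
  range), four stems covering 46% of columns with the structure drawn once
  per family (`simulate_structure()`);
- loops under HKY85 with κ = 4 and base frequencies (0.18, 0.32, 0.32,
  0.18) — loop GC ≈ 64%;
- stems under the 16-state no-double-substitution model whose stationary
  weights favor canonical pairs (`stem_pairing_bias = 10`, wobble √10):
  structural selection keeps ~90% of stationary mass Watson–Crick paired.
  The weight is symmetric between GC and AU, so it does not by itself
  bias GC — with symmetric base frequencies and no gBGC, stem GC sits at
  50%;
- gBGC as a multiplier λ (default 3) on rates into GC and CG, renormalized;
  the effective per-species bias is λ_s = 1 + (λ − 1)h_s, because the same
  conversion events that homogenize the array are the gBGC opportunities;
- homogenization h per species (default an even 0.35–0.95 gradient across
  species, as real families differ in it); alleles sit on a star tree of
  depth (1 − h_s) × 0.04, giving within-species K from ~1 to ~13;
- a per-species "conversion history": the terminal lineage's stems
  additionally churn for 1.5·h_s expected substitutions under the species'
  own biased process, reflecting that array turnover runs much faster than
  the species clock. This term is what couples homogenization to stem GC;
  without it the bias acts only along short terminal branches and the K–GC
  signal drowns in composition sampling noise;
- a Yule species tree of depth 0.2, allele copy counts geometric with mean
  5 (so the singleton filter has work to do), and every random draw
  flowing from one seed (byte-identical reruns; the caller's RNG state is
  left untouched).

Under these defaults the generator reproduces the observable structure of
real ITS2 families: paired-region GC ≈ 84% vs unpaired ≈ 64%, paired GC
above unpaired in essentially every species, paired-region GC SD below the
unpaired SD, and — pooled over replicate families — a negative K vs
paired-GC Spearman correlation (ρ ≈ −0.3 to −0.4) with the unpaired
correlation near zero.

What it does *not* emulate: indels (the alignment is fixed-length),
pseudoknots, mechanistic unequal crossing over (homogenization is a
one-parameter stand-in), among-site rate heterogeneity, and base-level
selection differences between stems beyond the pairing weights. Tests
passing on this generator therefore certify the *method chain*, not any
claim about real sequences.

## Numerical choices and degenerate inputs

- Frequencies live on a reference-cell softmax with transformed
  coordinates bounded to ±20; rates on logs. Optimizer tolerance is
  `factr = 1e7` (≈1e−8 relative in logL); multistart jitter is seeded and
  defaults to a single start.
- Stationary distributions of non-reversible generators come from the SVD
  null space of t(Q), with reducibility detected by a degenerate null
  space, negative mass, or a residual in πQ = 0. Reversible models use
  their own frequencies (exact by detailed balance).
- Saturated distances (p ≥ 0.75) are an error naming the offending pair;
  all-identical alignments yield zero-length trees and finite likelihoods;
  all-singleton species are skipped by the pipeline with a warning, not an
  abort, since species are independent analyses.
- Consensus ties (equal support) break to the smaller opening position,
  making the greedy non-crossing selection deterministic.

## Pipeline and problem sizes

`run_pipeline()` chains the stages per species — filter, consensus at
0.70, partition, GC/K table, AICc selection over a candidate list, then
formation/mismatch/GC\* from the top-ranked 16-state fit (mismatch
identities need the full doublet space even when a 7-state or DNA-only
candidate ranks first) — and across species computes the K vs GC Spearman
correlations. Estimates feeding the GC dynamics can come from ML (default)
or from posterior means (`estimator = "mcmc"`). Everything is written as
TSV plus a JSON metadata file; outputs are bit-reproducible given a seed.

The numbered scripts under `analysis/` present the same chain as a
narrative: `01_simulate` (the 29-family study), `02_composition`,
`03_model_selection`, `04_gc_dynamics`, `05_gbgc_signature` (an h-gradient
study pooling 10 replicate families). The test suite and
`scripts/acceptance.R` run reduced problem sizes — families of 3–10
species, alignments of 80–2000 columns, 10-replicate grids — chosen so the
full chain, including ML recovery at 2000 columns and the pooled
signature run, completes in minutes on one CPU while leaving each check
statistically decisive.

## Known limitations

- The model family is a documented stand-in, not a reimplementation, of
  the classical RNA16/RNA7 parameterizations; parameter counts differ from
  the originals by construction.
- Branch lengths are fixed at NJ estimates unless optimization is
  requested; for shallow within-species matrices this is harmless, but
  parameter values quoted from deeper alignments should use
  `optimize_branch_lengths = TRUE`.
- Reversible fits estimate stationary frequencies from standing
  composition, so fitted GC\* tracks current GC closely on synthetic
  stationary data; detecting *non-equilibrium* trends (GC\* far from
  current GC) requires data whose composition genuinely lags its
  substitution process, which the generator can produce only via its
  non-reversible biased mode.
- With few alleles and shallow divergence the DNA-only candidate often
  wins AICc within species — few base-pair substitutions carry little
  information — while species-level alignments decisively favor the mixed
  models. Both outcomes are biologically expected and reported as-is.
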