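# its2gc

Structure-partitioned analysis of GC-content evolution in ITS2 allele
families.

## The problem

ITS2, the second internal transcribed spacer of nuclear ribosomal DNA, is
a multicopy marker whose tandem copies are homogenized by concerted
evolution (unequal crossing over and gene conversion). The same
recombination events that homogenize the array expose it to **GC-biased
gene conversion (gBGC)**: mismatch repair in the heteroduplex favors G/C
over A/T. Because ITS2 folds into a conserved secondary structure, the
base-paired stems and unpaired loops can be analyzed as separate
partitions — and gBGC plus structural selection make concrete,
quantitative predictions about each:

- species with homogeneous allele sets (low K, the average number of
  pairwise nucleotide differences) should be GC-rich, especially in stems;
- the stem substitution process, modeled on the 16 ordered base-pair
  *doublets* with no simultaneous change of both nucleotides (pair
  turnover passes through intermediates, GC–GU–AU), should show higher
  total rates into GC-type pairs (GC, CG) than into AU-type pairs (AU,
  UA) across the six single-change routes into each target, and a
  repair bias toward GC for the four repairable mismatches
  (A·G, A·C, C·U, G·U);
- equilibrium GC,
  **GC\* = r(AT→GC) / (r(AT→GC) + r(GC→AT))**
  for a nucleotide process (the stationary GC fraction of the doublet
  chain for a pair process), tells each region where its composition is
  heading relative to where it is.

`its2gc` is for molecular evolution researchers who have per-species
aligned sequence–structure allele sets (Vienna dot-bracket triplets) and
want this whole chain — filtering, consensus-structure partitioning,
composition/diversity statistics, nucleotide + doublet substitution model
fitting with AICc selection (ML or MCMC), and the derived GC-evolution
statistics — as tested, scriptable functions. A synthetic ITS2-family
generator with tunable homogenization and GC bias makes every stage
runnable and testable offline.

## Worked example

Simulate a 29-species study under the default conditions (260-column
ITS2-like alignments, four stems covering 46% of columns, gBGC strength
λ = 3 coupled to a homogenization gradient), then analyze one species and
the cross-species pattern:

```r
library(its2gc)

fam <- simulate_family(synth_config(seed = 1))
mat <- fam$families[[5]]
recs <- filter_singleton_alleles(mat$records)
#> filter_singleton_alleles: kept 18, removed 5 singleton(s)
mat <- species_matrix(mat$species, recs)

cons <- consensus_structure(mat, threshold = 0.70)
part <- partition_columns(cons, mat$ncols)
part
#> <structure_partition> 260 columns: 60 base pairs (120 cols), 140 unpaired

gc_report(mat, part)
#>   species n_alleles gc_total gc_paired gc_unpaired sd_paired sd_unpaired        K
#> 1    sp05        18 73.82479  85.55556    63.76984 0.8574929    1.144053 7.647059

sel <- select_model(mat, part)
head(sel$table[, c("model", "logL", "k", "AICc")], 3)
#>               model      logL  k     AICc
#> 1 HKY85+pair16_free -672.1608 21 1391.513
#> 2 HKY85+pair16_prod -719.1206  9 1457.189
#> 6       REV+DNAonly -730.8840  8 1478.522

fit <- sel$best
formation_rates(fit$pair_model)
#> <transformation_summary> to GC: 21.5018, to AU: 2.0260, ratio = 10.613 (pi_GC = 0.770, pi_AU = 0.073)
mismatch_conversion(fit$pair_model)$aggregate_ratio
#> [1] 10.61304
gc_trend(85.556, gc_star_pair(fit$pair_model), region = "paired")$trend
#> [1] "decreasing"
```

The formation ratio says substitutions form GC-type pairs ~10.6 times
faster than AU-type pairs in this species' stems — the gBGC fingerprint —
and the mismatch table gives the same bias for one-sided heteroduplex
repair. (Under the κ-class models the two ratios coincide algebraically;
see the vignette.)

The numbered scripts under `analysis/` run the full study and print what
they find; from the repository root:

```sh
Rscript analysis/01_simulate.R         # 29 families -> results/synthetic_family/
Rscript analysis/02_composition.R      # GC/SD/K tables, Shapiro-Wilk, Spearman
Rscript analysis/03_model_selection.R  # AICc ranking per species
Rscript analysis/04_gc_dynamics.R      # formation/mismatch/GC* tables
Rscript analysis/05_gbgc_signature.R   # homogenization-gradient study
```

A run of `02`–`05` on the seed-1 study prints, among other things:

```
GC across 29 species: mean 73.36% (paired 83.64%, unpaired 64.55%)
GCp > GCup in 100% of species; SD paired 0.64 vs unpaired 0.86
mixed (DNA + base-pair) beats DNA-only in 100% of species
formation rate into GC vs AU pairs: mean ratio 8.83 (range 4.01-25.15)
  paired   K-GC Spearman rho = -0.380 (p = 9.6e-05)
  unpaired K-GC Spearman rho = +0.002 (p = 0.99)
```

i.e. stems are GC-rich and compositionally tight, structure-aware mixed
models beat DNA-only fits, pair formation is GC-biased, and homogenized
(low-K) species are GC-rich *in stems but not in loops* — the gBGC
signature. `run_pipeline(run_config(...))` chains the same stages
programmatically and writes the TSV/JSON bundle in one call.

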