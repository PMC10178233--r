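#!/usr/bin/env Rscript
# Homogenization-gradient study: is low allele diversity (high concerted
# evolution) coupled to high paired-region GC, as gBGC predicts? Pools
# per-species K and regional GC over replicate synthetic families spanning
# a homogenization grid and contrasts the paired and unpaired regions.
# Writes results/gbgc_signature/.

library(its2gc)

out <- "results/gbgc_signature"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hg <- simulate_h_grid(h_grid = seq(0.05, 0.95, by = 0.1), lambda = 3,
                      n_seeds = 10, seed = 1)
write.table(hg, file.path(out, "h_grid_species.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ok <- !is.na(hg$K)
paired <- spearman_correlation(hg$K[ok], hg$gc_paired[ok])
unpaired <- spearman_correlation(hg$K[ok], hg$gc_unpaired[ok])
res <- data.frame(region = c("paired", "unpaired"),
                  rho = c(paired$rho, unpaired$rho),
                  p_value = c(paired$p_value, unpaired$p_value),
                  n = sum(ok))
write.table(res, file.path(out, "k_gc_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("pooled over %d species-draws:", sum(ok)))
message(sprintf("  paired   K-GC Spearman rho = %+.3f (p = %.2g)",
                paired$rho, paired$p_value))
message(sprintf("  unpaired K-GC Spearman rho = %+.3f (p = %.2g)",
                unpaired$rho, unpaired$p_value))
message(if (paired$rho < 0 && paired$p_value < 0.05 &&
            abs(unpaired$rho) < abs(paired$rho))
  "gBGC signature: homogenized (low-K) species are GC-rich in stems, with no comparable trend in loops"
  else "gBGC signature not resolved in this run")
message("wrote results/gbgc_signature/{h_grid_species,k_gc_correlations}.tsv")
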