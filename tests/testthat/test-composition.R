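test_that("GC content ignores gaps and averages alleles unweighted", {
  one <- seqstruct("a", "GGCC", "....")
  expect_equal(gc_content(one), 100)
  gap <- seqstruct("a", "GC-AU", ".....")
  expect_equal(gc_content(gap), 50)
  expect_error(gc_content(seqstruct("a", "--NN", "....")),
               "no countable bases")
  # column subsets and unweighted mean across alleles
  two <- seqstruct(c("a", "b"), c("GGGG", "AAAA"), rep("....", 2),
                   copy_count = c(10L, 2L))
  expect_equal(gc_content(two), 50)   # copy counts ignored
  expect_equal(gc_content(two, columns = 1:2), 50)
})

test_that("per-allele GC is invariant under reversal and G<->C, A<->U swap", {
  set.seed(42)
  for (k in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
               collapse = "")
    rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    swp <- chartr("GCAU", "CGUA", s)
    g0 <- gc_content(seqstruct("x", s, strrep(".", 30)))
    expect_equal(gc_content(seqstruct("x", rev, strrep(".", 30))), g0)
    expect_equal(gc_content(seqstruct("x", swp, strrep(".", 30))), g0)
  }
})

test_that("GC homogeneity is the sample SD of per-allele GC", {
  same <- seqstruct(c("a", "b"), c("GGAA", "GGAA"), rep("....", 2))
  expect_equal(gc_homogeneity(same), 0)
  # alleles at GC 80% and 82% over 50 columns -> SD = sqrt(2)
  a <- paste(c(rep("G", 40), rep("A", 10)), collapse = "")
  b <- paste(c(rep("G", 41), rep("A", 9)), collapse = "")
  recs <- seqstruct(c("a", "b"), c(a, b), rep(strrep(".", 50), 2))
  expect_equal(gc_homogeneity(recs), sqrt(2), tolerance = 1e-10)
  expect_error(gc_homogeneity(same[1, ]), "at least two")
  # brute-force two-pass SD oracle on random inputs
  set.seed(7)
  for (k in 1:5) {
    seqs <- replicate(4, paste(sample(c("A", "C", "G", "U"), 40, TRUE),
                               collapse = ""))
    recs <- seqstruct(paste0("r", 1:4), seqs, rep(strrep(".", 40), 4))
    gcs <- gc_content(recs, per_allele = TRUE)
    mu <- sum(gcs) / 4
    oracle <- sqrt(sum((gcs - mu)^2) / 3)
    expect_equal(gc_homogeneity(recs), oracle, tolerance = 1e-12)
  }
})

test_that("K counts pairwise differences with pairwise deletion", {
  same <- seqstruct(c("a", "b"), c("GCAU", "GCAU"), rep("....", 2))
  expect_equal(avg_nucleotide_differences(same), 0)
  tri <- seqstruct(c("a", "b", "c"), c("AAAA", "AAAU", "AAUU"),
                   rep("....", 3))
  expect_equal(avg_nucleotide_differences(tri), 4 / 3, tolerance = 1e-12)
  # gaps excluded pair-by-pair
  gap <- seqstruct(c("a", "b"), c("A-AA", "AUAG"), rep("....", 2))
  expect_equal(avg_nucleotide_differences(gap), 1)
  # order invariance
  set.seed(5)
  fam <- simulate_family(synth_config(n_species = 1,
                                      alleles_per_species = 5,
                                      seq_length = 80, seed = 5))
  recs <- fam$families[[1]]$records
  k1 <- avg_nucleotide_differences(recs)
  k2 <- avg_nucleotide_differences(recs[sample(nrow(recs)), ])
  expect_equal(k1, k2)
})

test_that("Spearman correlation matches the rank formula and flags degeneracy", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:4, c(1, 3, 2, 4))$rho, 0.8,
               tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  # oracle: 1 - 6 sum d^2 / (n(n^2-1)) on tie-free vectors
  set.seed(9)
  for (k in 1:10) {
    x <- sample(1:50, 12); y <- sample(1:50, 12)
    d <- rank(x) - rank(y)
    oracle <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
    expect_equal(spearman_correlation(x, y)$rho, oracle, tolerance = 1e-12)
  }
})

test_that("Shapiro-Wilk separates normal from bimodal samples", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(1:2), "\\[3, 5000\\]")
  set.seed(31)
  normal_p <- replicate(100, shapiro_wilk(rnorm(29))$p_value)
  expect_gte(mean(normal_p > 0.05), 0.90)
  bimodal_p <- replicate(100, {
    x <- c(rnorm(15, 0, 0.5), rnorm(14, 8, 0.5))
    shapiro_wilk(x)$p_value
  })
  expect_gte(mean(bimodal_p < 0.05), 0.90)
})

test_that("base frequency profile normalizes per column", {
  recs <- seqstruct(c("a", "b", "c"), c("AAG", "AAG", "G-G"),
                    rep("...", 3))
  prof <- base_frequency_profile(recs)
  expect_equal(prof$A[1], 2 / 3, tolerance = 1e-12)
  expect_equal(prof$G[1], 1 / 3, tolerance = 1e-12)
  expect_equal(prof$gap[2], 1 / 3, tolerance = 1e-12)
  sums <- rowSums(prof[, c("A", "C", "G", "U")])
  expect_equal(sums, rep(1, 3))
})

test_that("gc_report assembles the per-species table", {
  fam <- simulate_family(synth_config(n_species = 1,
                                      alleles_per_species = 4,
                                      seq_length = 80, seed = 2))
  rep_ <- gc_report(fam$families[[1]], fam$partition)
  expect_equal(rep_$n_alleles, 4L)
  expect_true(all(c("gc_total", "gc_paired", "gc_unpaired", "K")
                  %in% names(rep_)))
  expect_true(rep_$gc_total >= 0 && rep_$gc_total <= 100)
})
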