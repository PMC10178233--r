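make_fit_fixture <- function(seed = 41, n_species = 8, seq_length = 400) {
  fam <- simulate_family(synth_config(n_species = n_species,
                                      alleles_per_species = 1,
                                      seq_length = seq_length,
                                      lambda = 1, kappa = 4, seed = seed))
  mat <- species_alignment(fam)
  list(fam = fam, mat = mat, part = fam$partition,
       tree = build_nj_tree(mat))
}

test_that("ML recovers the transition/transversion ratio it simulated under", {
  fx <- make_fit_fixture(seed = 41, n_species = 8, seq_length = 600)
  fit <- fit_ml(fx$mat, fx$part, model_family("HKY85", "pair16_prod"),
                tree = fx$tree)
  expect_true(fit$converged)
  expect_gt(fit$params["kappa"], 2.5)
  expect_lt(fit$params["kappa"], 6.5)
  expect_equal(sum(fit$params[paste0("pi_", NUC)]), 1, tolerance = 1e-8)
})

test_that("degenerate all-identical data fits without crashing", {
  recs <- seqstruct(paste0("r", 1:3), rep("GGAAUUCCGGAA", 3),
                    rep("((((....))))", 3))
  mat <- species_matrix("sp", recs)
  part <- partition_columns("((((....))))", 12)
  fit <- fit_ml(mat, part, model_family("HKY85", "pair16_prod"))
  expect_true(is.finite(fit$logL))
  expect_equal(sum(fit$tree$edge.length), 0)
})

test_that("multistart optimization lands on the same optimum", {
  fx <- make_fit_fixture(seed = 43, n_species = 6, seq_length = 200)
  fit <- fit_ml(fx$mat, fx$part, model_family("HKY85", "pair16_prod"),
                tree = fx$tree, n_starts = 5, seed = 7)
  fit1 <- fit_ml(fx$mat, fx$part, model_family("HKY85", "pair16_prod"),
                 tree = fx$tree, n_starts = 1, seed = 7)
  expect_equal(fit$logL, fit1$logL, tolerance = 1e-4)
})

test_that("AICc follows its definition and penalizes parameters", {
  expect_equal(its2gc:::aicc(-100, 4, 50),
               200 + 8 + 2 * 4 * 5 / (50 - 4 - 1), tolerance = 1e-12)
  expect_equal(its2gc:::aicc(-100, 49, 50), Inf)
})

test_that("model selection ranks candidates and finds nested truth", {
  # product-frequency stems (no structural skew): pair16_prod is the truth
  fam <- simulate_family(synth_config(n_species = 8,
                                      alleles_per_species = 1,
                                      seq_length = 400, lambda = 1,
                                      stem_pairing_bias = 1,
                                      kappa = 4, seed = 47))
  mat <- species_alignment(fam)
  fx <- list(mat = mat, part = fam$partition, tree = build_nj_tree(mat))
  # data simulated under the product-frequency doublet model (lambda = 1):
  # the 4-parameter pair16_prod should beat the 16-parameter pair16_free
  sel <- select_model(fx$mat, fx$part,
                      candidates = list(model_family("HKY85", "pair16_prod"),
                                        model_family("HKY85", "pair16_free")),
                      tree = fx$tree)
  expect_equal(sel$best$family$pair, "pair16_prod")
  expect_equal(nrow(sel$table), 2L)
  expect_true(all(diff(sel$table$AICc) >= 0))
  expect_equal(sel$table$delta_AICc[1], 0)
})

test_that("mixed models beat DNA-only models on pair-correlated data", {
  # gBGC-driven stem evolution produces a joint doublet distribution and a
  # stem clock a factorized single-model DNA fit cannot capture
  fam <- simulate_family(synth_config(n_species = 10,
                                      alleles_per_species = 1,
                                      seq_length = 300, lambda = 3,
                                      species_tree_depth = 0.4, seed = 53))
  mat <- species_alignment(fam)
  sel <- select_model(mat, fam$partition,
                      candidates = list(model_family("HKY85", "pair16_prod"),
                                        model_family("HKY85", NULL)),
                      tree = build_nj_tree(mat))
  expect_equal(sel$best$family$name, "HKY85+pair16_prod")
})

test_that("single candidate is returned as best", {
  fx <- make_fit_fixture(seed = 59, n_species = 5, seq_length = 150)
  sel <- select_model(fx$mat, fx$part,
                      candidates = list(model_family("HKY85", "pair7_free")),
                      tree = fx$tree)
  expect_equal(sel$best$family$pair, "pair7_free")
  expect_equal(nrow(sel$table), 1L)
})

test_that("branch-length optimization improves or matches the fixed-NJ fit", {
  fx <- make_fit_fixture(seed = 61, n_species = 5, seq_length = 200)
  f0 <- fit_ml(fx$mat, fx$part, model_family("HKY85", "pair16_prod"),
               tree = fx$tree)
  f1 <- fit_ml(fx$mat, fx$part, model_family("HKY85", "pair16_prod"),
               tree = fx$tree, optimize_branch_lengths = TRUE)
  expect_gte(f1$logL, f0$logL - 1e-6)
  expect_equal(f1$n_params, f0$n_params + length(fx$tree$edge.length))
})
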