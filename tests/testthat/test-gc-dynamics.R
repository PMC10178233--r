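test_that("nucleotide GC* follows the rate-ratio formula", {
  sym <- make_nuc_model("REV", freqs = rep(0.25, 4), rates = rep(1, 6))
  expect_equal(gc_star_nucleotide(sym), 50, tolerance = 1e-10)
  # u = 3v by construction: GC-rich equilibrium at 75%
  m <- make_nuc_model("HKY85", freqs = c(.125, .375, .375, .125), kappa = 1)
  expect_equal(gc_star_nucleotide(m), 75, tolerance = 1e-10)
})

test_that("GC* equals stationary GC mass for every reversible model", {
  set.seed(201)
  for (k in 1:200) {
    m <- random_nuc_model()
    expect_equal(gc_star_nucleotide(m),
                 100 * sum(m$freqs[c("G", "C")]), tolerance = 1e-10)
  }
})

test_that("pair GC* is the stationary GC fraction of the doublet chain", {
  uni <- make_pair_model("16", freqs = rep(1 / 16, 16), kappa = 1)
  expect_equal(gc_star_pair(uni), 50, tolerance = 1e-9)
  # mass concentrated on GC/CG pushes GC* to 100
  f <- rep(1e-9, 16); names(f) <- DOUBLETS
  f[c("GC", "CG")] <- 0.5
  conc <- make_pair_model("16", freqs = f, kappa = 1)
  expect_equal(gc_star_pair(conc), 100, tolerance = 1e-4)
})

test_that("pair GC* matches long-run forward simulation", {
  pm <- gbgc_bias_model(make_pair_model("16", kappa = 2), 2.5)
  star <- gc_star_pair(pm)
  set.seed(7)
  P <- transition_probabilities(pm, 50)   # effectively stationary
  start <- rep(1L, 10000)                 # all AA
  end <- its2gc:::evolve_states(start, P)
  gc_sim <- 100 * mean(its2gc:::gc_weight(DOUBLETS[end]))
  expect_lt(abs(gc_sim - star), 1)
})

test_that("trend classification respects the tolerance band", {
  expect_equal(gc_trend(63.79, 67.26)$trend, "increasing")
  expect_equal(gc_trend(83.48, 77.16)$trend, "decreasing")
  expect_equal(gc_trend(50.0, 50.05, tolerance = 0.1)$trend, "stable")
  expect_error(gc_trend(-1, 50), ">= 0")
})

test_that("formation routes enumerate exactly six sources per target", {
  pm <- make_pair_model("16", kappa = 2)
  fr <- formation_rates(pm)
  for (tg in c("GC", "CG", "AU", "UA"))
    expect_equal(sum(fr$routes$target == tg), 6L)
  expect_setequal(fr$routes$source[fr$routes$target == "GC"],
                  c("AC", "CC", "UC", "GA", "GG", "GU"))
  # every route is a single-position change
  adj <- doublet_adjacency()
  expect_true(all(adj[cbind(fr$routes$source, fr$routes$target)]))
})

test_that("formation ratio is 1 under symmetry and tracks the gBGC bias", {
  sym <- make_pair_model("16", freqs = rep(1 / 16, 16), kappa = 1)
  expect_equal(formation_rates(sym)$ratio, 1, tolerance = 1e-10)
  expect_equal(mismatch_conversion(sym)$aggregate_ratio, 1,
               tolerance = 1e-10)
  # doubling all rates into GC-type targets doubles both ratios
  biased <- gbgc_bias_model(sym, 2)
  expect_equal(formation_rates(biased)$ratio, 2, tolerance = 1e-10)
  expect_equal(mismatch_conversion(biased)$aggregate_ratio, 2,
               tolerance = 1e-10)
})

test_that("formation ratio is invariant under global rescaling of Q", {
  pm <- gbgc_bias_model(make_pair_model("16", kappa = 3), 1.7)
  scaled <- pm
  scaled$Q <- pm$Q * 7.3
  expect_equal(formation_rates(scaled)$ratio, formation_rates(pm)$ratio,
               tolerance = 1e-12)
})

test_that("mismatch table lists four mismatches with two destinations each", {
  pm <- make_pair_model("16", kappa = 2)
  mc <- mismatch_conversion(pm)
  expect_equal(nrow(mc$table), 4L)
  expect_setequal(mc$table$mismatch, c("A:G", "A:C", "C:U", "G:U"))
  expect_equal(ncol(mc$table) - 1L, 2L)   # 4 x 2 = 8 repair route groups
  expect_error(mismatch_conversion(make_pair_model("7")), "7-state")
})

test_that("7-state formation summary uses the lumped graph", {
  pm7 <- make_pair_model("7", freqs = rep(1 / 7, 7), alpha = 2, beta = 1)
  fr <- formation_rates(pm7)
  expect_equal(nrow(fr$routes), 8L)
  expect_true(all(fr$routes$source %in% c("GU", "UG", "MM")))
  expect_equal(fr$ratio, 1, tolerance = 1e-10)
})

test_that("synthetic gBGC leaves its fingerprint in fitted summaries", {
  # lambda > 1: formation ratio above 1 and paired GC above unpaired GC
  ratios <- numeric(0); gcdiff <- numeric(0)
  for (s in 1:10) {
    fam <- simulate_family(synth_config(n_species = 3, lambda = 3,
                                        seed = 300 + s))
    tr <- fam$truth$per_species
    gcdiff <- c(gcdiff, tr$gc_paired - tr$gc_unpaired)
    b <- gbgc_bias_model(make_pair_model("16", kappa = 4),
                         mean(tr$lambda_eff))
    ratios <- c(ratios, formation_rates(b)$ratio)
  }
  expect_true(all(ratios > 1))
  expect_gt(mean(gcdiff > 0), 0.9)
})
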