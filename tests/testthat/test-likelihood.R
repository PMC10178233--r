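test_that("pruning equals closed forms on one- and two-branch trees", {
  nm <- make_nuc_model("HKY85", c(.2, .3, .3, .2), kappa = 3)
  # two tips joined at a node: L = sum_i pi_i P_i,x(t1) P_i,y(t2)
  tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                       tip.label = c("x", "y"), Nnode = 1L,
                       edge.length = c(0.2, 0.4)), class = "phylo")
  states <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("x", "y"), NULL))
  P1 <- transition_probabilities(nm, 0.2)
  P2 <- transition_probabilities(nm, 0.4)
  direct <- log(sum(nm$freqs * P1[, 1] * P2[, 3]))
  expect_equal(its2gc:::prune_loglik_cp(
    its2gc:::compress_patterns(states, 4L), its2gc:::tree_traversal(tr),
    tr$edge.length, nm), direct, tolerance = 1e-12)
  # missing tip marginalizes: likelihood = pi of observed tip state
  states[2, 1] <- NA
  lone <- log(sum(nm$freqs * P1[, 1]))
  expect_equal(its2gc:::prune_loglik_cp(
    its2gc:::compress_patterns(states, 4L), its2gc:::tree_traversal(tr),
    tr$edge.length, nm), lone, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on random small trees", {
  set.seed(17)
  for (ntax in 2:4) {
    for (rep in 1:3) {
      tr <- ape::rtree(ntax)
      nm <- random_nuc_model()
      st <- random_tip_states(tr, 6, 4)
      expect_equal(its2gc:::prune_loglik_cp(
        its2gc:::compress_patterns(st, 4L), its2gc:::tree_traversal(tr),
        tr$edge.length, nm), enum_loglik(tr, st, nm), tolerance = 1e-8)
      pm <- random_pair_model("16")
      stp <- random_tip_states(tr, 4, 16)
      expect_equal(its2gc:::prune_loglik_cp(
        its2gc:::compress_patterns(stp, 16L), its2gc:::tree_traversal(tr),
        tr$edge.length, pm), enum_loglik(tr, stp, pm), tolerance = 1e-8)
    }
  }
})

test_that("mixed-partition likelihood adds its pieces and checks taxa", {
  fam <- simulate_family(synth_config(n_species = 4,
                                      alleles_per_species = 1,
                                      seq_length = 80, seed = 23))
  mat <- species_alignment(fam)
  part <- fam$partition
  tree <- build_nj_tree(mat)
  nm <- make_nuc_model("HKY85", c(.2, .3, .3, .2), kappa = 2)
  pm <- make_pair_model("16", kappa = 2)
  ll <- log_likelihood(mat, part, nm, pm, tree)
  expect_true(is.finite(ll) && ll < 0)
  bad <- tree; bad$tip.label[1] <- "nope"
  expect_error(log_likelihood(mat, part, nm, pm, bad), "disagree")
  # DNA-only scoring uses every column under the 4-state model
  ll_dna <- log_likelihood(mat, part, nm, NULL, tree)
  expect_true(is.finite(ll_dna))
})

test_that("likelihood is invariant under re-rooting a reversible model", {
  fam <- simulate_family(synth_config(n_species = 5,
                                      alleles_per_species = 1,
                                      seq_length = 100, seed = 29))
  mat <- species_alignment(fam)
  tree <- build_nj_tree(mat)
  nm <- make_nuc_model("REV", rdirichlet1(4), rates = rgamma(6, 2))
  pm <- make_pair_model("16", freqs = rdirichlet1(16), kappa = 3)
  ll1 <- log_likelihood(mat, fam$partition, nm, pm, tree)
  rerooted <- ape::root(tree, outgroup = tree$tip.label[1],
                        resolve.root = TRUE)
  ll2 <- log_likelihood(mat, fam$partition, nm, pm, rerooted)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("4-state pruning matches phangorn on a shared fit", {
  skip_if_not_installed("phangorn")
  fam <- simulate_family(synth_config(n_species = 6,
                                      alleles_per_species = 1,
                                      seq_length = 120, paired_fraction = 0.4,
                                      seed = 31))
  mat <- species_alignment(fam)
  part <- fam$partition
  tree <- build_nj_tree(mat)
  nm <- make_nuc_model("HKY85", c(.2, .3, .3, .2), kappa = 4)
  ll <- log_likelihood(mat, part, nm, NULL, tree)
  chars <- do.call(rbind, strsplit(chartr("U", "T", mat$records$sequence),
                                   ""))
  rownames(chars) <- mat$records$id
  pd <- phangorn::phyDat(chars)
  # phangorn's exchangeability order is AC, AG, AT, CG, CT, GT
  fitQ <- phangorn::pml(tree, pd, bf = unname(nm$freqs),
                        Q = c(1, 4, 1, 1, 4, 1))
  expect_equal(ll, as.numeric(fitQ$logLik), tolerance = 1e-6)
})
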