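test_that("constructed models satisfy the generator invariants", {
  set.seed(101)
  models <- c(replicate(5, random_nuc_model(), simplify = FALSE),
              replicate(5, random_pair_model("16"), simplify = FALSE),
              replicate(5, random_pair_model("7"), simplify = FALSE),
              list(make_nuc_model("HKY85", c(.1, .4, .3, .2), kappa = 5),
                   make_pair_model("16", kappa = 3),
                   make_pair_model("7", alpha = 3, beta = 0.5)))
  adj <- doublet_adjacency()
  for (m in models) {
    Q <- m$Q; pi <- m$freqs
    expect_lt(max(abs(rowSums(Q))), 1e-10)              # rows sum to 0
    expect_lt(max(abs(pi %*% Q)), 1e-10)                # stationarity
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-10)  # unit mean rate
    offdiag <- Q - diag(diag(Q))
    expect_true(all(offdiag >= 0))
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-10)      # detailed balance
    if (inherits(m, "pair_model") && m$state_space == "16")
      expect_true(all(Q[!adj & row(Q) != col(Q)] == 0)) # no double subs
  }
})

test_that("double substitutions are forbidden in the 16-state model", {
  pm <- make_pair_model("16", kappa = 3)
  expect_identical(pm$Q["AU", "GC"], 0)
  expect_identical(pm$Q["GC", "AU"], 0)
  expect_gt(pm$Q["AU", "GU"], 0)   # single change allowed
})

test_that("transition probabilities behave like a semigroup with limit pi", {
  pm <- make_pair_model("16", freqs = rdirichlet1(16), kappa = 2.5)
  expect_equal(transition_probabilities(pm, 0), diag(16))
  expect_error(transition_probabilities(pm, -1), ">= 0")
  set.seed(3)
  for (t1 in c(0.1, 0.7)) {
    t2 <- 0.35
    P12 <- transition_probabilities(pm, t1 + t2)
    Pprod <- transition_probabilities(pm, t1) %*%
      transition_probabilities(pm, t2)
    expect_lt(max(abs(P12 - Pprod)), 1e-9)
  }
  Pinf <- transition_probabilities(pm, 1e4)
  expect_lt(max(abs(sweep(Pinf, 2, pm$freqs))), 1e-6)
  expect_equal(unname(rowSums(transition_probabilities(pm, 0.42))),
               rep(1, 16))
})

test_that("Pade exponential agrees with the eigen route", {
  nm <- make_nuc_model("HKY85", c(.2, .3, .3, .2), kappa = 4)
  for (t in c(0.05, 0.5, 3)) {
    Pe <- transition_probabilities(nm, t)
    Pp <- its2gc:::expm_pade(nm$Q * t)
    expect_lt(max(abs(Pe - Pp)), 1e-9)
  }
})

test_that("stationary distribution solves pi Q = 0 for biased generators", {
  pm <- make_pair_model("16", kappa = 2)
  b <- gbgc_bias_model(pm, 3)
  expect_false(b$reversible)
  pi <- stationary_distribution(b$Q)
  expect_lt(max(abs(pi %*% b$Q)), 1e-10)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_equal(-sum(pi * diag(b$Q)), 1, tolerance = 1e-10)  # renormalized
  # the bias raises stationary GC-pair mass
  expect_gt(sum(pi[c("GC", "CG")]), sum(pm$freqs[c("GC", "CG")]))
})

test_that("NJ tree reproduces additive distances and clamps degeneracy", {
  # 2 taxa: one path of total length equal to the corrected distance
  two <- seqstruct(c("a", "b"),
                   c("AAAAAAAAAACCCCCCCCCC", "AAAAAAAAAACCCCCCCCGG"),
                   rep(strrep(".", 20), 2))
  tr <- build_nj_tree(two)
  d <- jc_distance(two)["a", "b"]
  expect_equal(sum(tr$edge.length), d, tolerance = 1e-12)

  # identical sequences: all branch lengths zero
  same <- seqstruct(c("a", "b", "c"), rep("GCAUGCAU", 3),
                    rep("........", 3))
  tr0 <- build_nj_tree(same)
  expect_equal(sum(tr0$edge.length), 0)

  # 4 taxa built by disjoint mutations along a known tree: the (a,b|c,d)
  # split is recovered and path lengths reproduce the corrected distances
  base <- rep("A", 400)
  mk <- function(sites) {
    s <- base; s[sites] <- "G"; paste(s, collapse = "")
  }
  seqs <- c(a = mk(c(1:6, 101:120)), b = mk(c(11:20, 101:120)),
            c = mk(31:38), d = mk(41:52))
  four <- seqstruct(names(seqs), seqs, rep(strrep(".", 400), 4))
  tr4 <- build_nj_tree(four)
  expect_true(ape::is.monophyletic(ape::root(tr4, "d"), c("a", "b")))
  pd <- ape::cophenetic.phylo(tr4)
  D <- jc_distance(four)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 5e-3)

  # saturation is an error naming the pair
  sat <- seqstruct(c("a", "b"), c("AAAACCCCGGGG", "CCCCGGGGUUUU"),
                   rep(strrep(".", 12), 2))
  expect_error(build_nj_tree(sat), "saturated.*'a'.*'b'")
})
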