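# Independent oracles and fixture builders shared across the suite.

# brute-force likelihood: sum over all internal-node state assignments
enum_loglik <- function(tree, states, model) {
  ns <- nrow(model$Q)
  Pm <- lapply(tree$edge.length,
               function(t) transition_probabilities(model, t))
  ntip <- length(tree$tip.label)
  states <- states[tree$tip.label, , drop = FALSE]
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), tree$Nnode)))
  ll <- 0
  for (site in seq_len(ncol(states))) {
    obs <- states[, site]
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      internal <- grid[g, ]
      state_of <- function(node)
        if (node <= ntip) obs[node] else internal[node - ntip]
      p <- model$freqs[internal[root - ntip]]
      for (e in seq_len(nrow(tree$edge))) {
        ch <- tree$edge[e, 2]
        sc <- state_of(ch)
        if (is.na(sc)) next   # missing tip marginalizes to 1 (rows sum to 1)
        p <- p * Pm[[e]][state_of(tree$edge[e, 1]), sc]
      }
      lik <- lik + p
    }
    ll <- ll + log(lik)
  }
  unname(ll)
}

rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, shape = 2)
  x / sum(x)
}

random_nuc_model <- function() {
  make_nuc_model("REV", freqs = rdirichlet1(4),
                 rates = stats::rgamma(6, shape = 2))
}

random_pair_model <- function(state_space = "16") {
  if (state_space == "16")
    make_pair_model("16", freqs = rdirichlet1(16),
                    kappa = stats::rgamma(1, 4))
  else
    make_pair_model("7", freqs = rdirichlet1(7),
                    alpha = stats::rgamma(1, 4), beta = stats::rgamma(1, 4))
}

# a small allele set with structures, built in code
tiny_records <- function() {
  seqstruct(id = c("a", "b", "c"),
            sequence = c("GCGAAACGCU", "GCGAAACGCU", "GUGAAACACU"),
            structure = rep("(((....)))", 3),
            copy_count = c(3L, 2L, 5L))
}

tiny_matrix <- function() species_matrix("toy", tiny_records())

random_tip_states <- function(tree, nsites, nstates, na_frac = 0.1) {
  ntip <- length(tree$tip.label)
  m <- matrix(sample.int(nstates, ntip * nsites, replace = TRUE),
              ntip, nsites, dimnames = list(tree$tip.label, NULL))
  m[stats::runif(length(m)) < na_frac] <- NA
  m
}
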