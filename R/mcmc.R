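# Random-walk Metropolis-Hastings over the transformed model parameters of
# a mixed family, with the tree (topology and branch lengths) held fixed.
# The prior is iid Normal(0, 1) on every transformed parameter (softmax
# logits and log rates), which keeps prior-only sampling exactly checkable.

#' Posterior sampling of substitution-model parameters
#'
#' Metropolis-Hastings with a spherical Gaussian random-walk proposal whose
#' step size adapts during burn-in toward ~30% acceptance. The equilibrium
#' check re-runs the chain with doubled `n_iter` and declares convergence
#' when every posterior-mean natural parameter changes by less than 1%
#' relative (matching the practice of growing the run until extra
#' iterations stop moving the estimates).
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition`.
#' @param family a [model_family()].
#' @param tree optional fixed tree; default NJ.
#' @param n_iter total iterations (>= 10 * thin).
#' @param thin keep every `thin`-th draw.
#' @param burn_in_fraction fraction of iterations discarded (and used for
#'   adaptation).
#' @param seed RNG seed; same seed gives an identical sample stream.
#' @param prior_only ignore the likelihood (prior-recovery checks).
#' @param check_convergence run the doubling rule and report `converged`.
#' @param init optional starting transformed vector (default: ML-free
#'   empirical start).
#' @return List of class `mcmc_fit`: `samples` (retained draws, natural
#'   scale), `transformed`, `logL`, `posterior_mean`, `acceptance_rate`,
#'   `step`, `converged` (NA unless checked), `warnings`.
#' @export
mcmc_sample <- function(matrix, partition, family = model_family(),
                        tree = NULL, n_iter = 20000L, thin = 20L,
                        burn_in_fraction = 0.3, seed = 1L,
                        prior_only = FALSE, check_convergence = FALSE,
                        init = NULL) {
  if (n_iter < 10L * thin) stop("n_iter must be at least 10 * thin")
  if (is.null(tree)) tree <- build_nj_tree(matrix)
  emp <- empirical_stats(matrix, partition)
  spec <- family_spec(family, emp)
  sd <- prepare_site_data(matrix, partition)
  trav <- tree_traversal(tree)

  loglik <- function(x) {
    if (prior_only) return(0)
    mods <- spec$unpack(x)
    tryCatch(loglik_prepared(sd, trav, tree$edge.length, mods$nuc, mods$pair,
                             mods$pair_rate),
             error = function(e) -Inf)
  }
  logprior <- function(x) sum(stats::dnorm(x, 0, 1, log = TRUE))

  run_chain <- function(n_iter, seed) {
    set.seed(seed)
    d <- spec$n_params
    x <- if (is.null(init)) spec$init else init
    if (prior_only) x <- stats::rnorm(d)
    lp <- loglik(x) + logprior(x)
    step <- 0.1
    n_burn <- floor(burn_in_fraction * n_iter)
    keep_idx <- seq(n_burn + thin, n_iter, by = thin)
    kept <- matrix(NA_real_, length(keep_idx), d)
    keptll <- numeric(length(keep_idx))
    acc <- 0L; acc_win <- 0L; ki <- 0L
    for (it in seq_len(n_iter)) {
      prop <- x + stats::rnorm(d, sd = step)
      lpp <- loglik(prop) + logprior(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        x <- prop; lp <- lpp; acc <- acc + 1L; acc_win <- acc_win + 1L
      }
      if (it <= n_burn && it %% 100L == 0L) {
        rate <- acc_win / 100
        step <- step * exp(rate - 0.3)   # adapt toward ~30% acceptance
        acc_win <- 0L
      }
      if (ki < length(keep_idx) && it == keep_idx[ki + 1L]) {
        ki <- ki + 1L
        kept[ki, ] <- x
        keptll[ki] <- if (prior_only) NA_real_ else lp - logprior(x)
      }
    }
    list(kept = kept, logL = keptll, acc_rate = acc / n_iter, step = step)
  }

  ch <- run_chain(n_iter, seed)
  nat <- t(apply(ch$kept, 1, spec$natural))
  warn <- character(0)
  if (ch$acc_rate < 0.05 || ch$acc_rate > 0.8) {
    warn <- sprintf("acceptance rate %.3f outside [0.05, 0.8]", ch$acc_rate)
    warning(warn)
  }
  converged <- NA
  if (check_convergence) {
    ch2 <- run_chain(2L * n_iter, seed + 1L)
    nat2 <- t(apply(ch2$kept, 1, spec$natural))
    m1 <- colMeans(nat); m2 <- colMeans(nat2)
    rel <- abs(m2 - m1) / pmax(abs(m1), 1e-8)
    converged <- all(rel < 0.01)
  }
  structure(list(samples = as.data.frame(nat),
                 transformed = ch$kept, logL = ch$logL,
                 posterior_mean = colMeans(nat),
                 acceptance_rate = ch$acc_rate, step = ch$step,
                 converged = converged, warnings = warn,
                 family = family, seed = seed),
            class = "mcmc_fit")
}

#' Posterior-mean models from an MCMC run
#'
#' Rebuilds the nucleotide and pair models at the posterior mean of the
#' transformed parameters (the "equilibrium-state" matrices of the
#' analysis).
#'
#' @param mcmc an `mcmc_fit`.
#' @param matrix,partition,family the inputs of the run.
#' @return List with `nuc` and `pair` models.
#' @export
mcmc_mean_models <- function(mcmc, matrix, partition, family = mcmc$family) {
  emp <- empirical_stats(matrix, partition)
  spec <- family_spec(family, emp)
  spec$unpack(colMeans(mcmc$transformed))
}

#' Write retained posterior samples as TSV
#'
#' @param mcmc an `mcmc_fit`.
#' @param path output path.
#' @export
write_mcmc_tsv <- function(mcmc, path) {
  df <- cbind(mcmc$samples, logL = mcmc$logL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
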