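# ML fitting of mixed nucleotide + base-pair models, AICc model selection.
# All free parameters live on an unconstrained transformed scale: simplex
# frequencies through a reference-cell softmax, positive rates through log.

softmax0 <- function(z) {
  e <- exp(c(0, z) - max(0, z))
  e / sum(e)
}
inv_softmax0 <- function(p) log(p[-1] / p[1])

# a model family is nuc = HKY85|REV crossed with a pair-model flavor (or
# NULL for a DNA-only fit of all columns)
PAIR_FLAVORS <- c("pair16_free", "pair16_prod", "pair7_free", "pair7_fixmm")

#' Define a mixed model family
#'
#' @param nuc `"HKY85"` or `"REV"` for the unpaired (4-state) partition.
#' @param pair one of `"pair16_free"` (free doublet frequencies),
#'   `"pair16_prod"` (doublet frequencies constrained to products of
#'   nucleotide frequencies), `"pair7_free"`, `"pair7_fixmm"` (mismatch
#'   frequency fixed at its empirical value), or `NULL` for a DNA-only fit.
#' @param name optional label; defaults to `nuc+pair`.
#' @return A `model_family` list.
#' @export
model_family <- function(nuc = "HKY85", pair = "pair16_free", name = NULL) {
  stopifnot(nuc %in% c("HKY85", "REV"),
            is.null(pair) || pair %in% PAIR_FLAVORS)
  if (is.null(name))
    name <- paste0(nuc, if (is.null(pair)) "+DNAonly" else paste0("+", pair))
  structure(list(nuc = nuc, pair = pair, name = name), class = "model_family")
}

empirical_stats <- function(matrix, partition) {
  enc <- encode_doublets(matrix, partition)
  un <- enc$unpaired_sites
  nf <- vapply(NUC, function(b) sum(un == b, na.rm = TRUE), numeric(1)) + 1
  nf <- nf / sum(nf)
  ps <- enc$pair_sites
  df <- vapply(DOUBLETS, function(d) sum(ps == d, na.rm = TRUE), numeric(1)) + 0.5
  df <- df / sum(df)
  lump <- lump_mismatches(ps)
  sf <- vapply(PAIR7_STATES, function(s) sum(lump == s, na.rm = TRUE),
               numeric(1)) + 0.5
  sf <- sf / sum(sf)
  list(nuc_freqs = nf, doublet_freqs = df, pair7_freqs = sf)
}

# parameter packing for one family given empirical starting stats
family_spec <- function(family, emp) {
  nuc_np <- if (family$nuc == "HKY85") 4L else 8L
  nuc_init <- if (family$nuc == "HKY85")
    c(inv_softmax0(emp$nuc_freqs), log(2))
  else c(inv_softmax0(emp$nuc_freqs), rep(0, 5))
  nuc_unpack <- function(x) {
    pf <- softmax0(x[1:3])
    if (family$nuc == "HKY85")
      make_nuc_model("HKY85", freqs = pf, kappa = exp(x[4]))
    else
      make_nuc_model("REV", freqs = pf, rates = c(exp(x[4:8]), 1))
  }
  nuc_names <- c(paste0("pi_", NUC),
                 if (family$nuc == "HKY85") "kappa"
                 else paste0("r_", NUC_PAIRS[1:5]))
  nuc_natural <- function(x) {
    pf <- softmax0(x[1:3])
    if (family$nuc == "HKY85") c(pf, exp(x[4])) else c(pf, exp(x[4:8]))
  }

  if (is.null(family$pair)) {
    pr_np <- 0L; pr_init <- numeric(0)
    pr_unpack <- function(x) NULL
    pr_natural <- function(x) numeric(0)
    pr_names <- character(0)
  } else if (family$pair == "pair16_free") {
    pr_np <- 16L
    pr_init <- c(inv_softmax0(emp$doublet_freqs), log(2))
    pr_unpack <- function(x)
      make_pair_model("16", freqs = softmax0(x[1:15]), kappa = exp(x[16]))
    pr_natural <- function(x) c(softmax0(x[1:15]), exp(x[16]))
    pr_names <- c(paste0("pi_", DOUBLETS), "kappa_pair")
  } else if (family$pair == "pair16_prod") {
    pr_np <- 4L
    nf0 <- sqrt(emp$doublet_freqs[paste0(NUC, NUC)])
    nf0 <- nf0 / sum(nf0)
    pr_init <- c(inv_softmax0(nf0), log(2))
    pr_unpack <- function(x) {
      nf <- softmax0(x[1:3]); names(nf) <- NUC
      f16 <- nf[substr(DOUBLETS, 1, 1)] * nf[substr(DOUBLETS, 2, 2)]
      make_pair_model("16", freqs = f16, kappa = exp(x[4]))
    }
    pr_natural <- function(x) c(softmax0(x[1:3]), exp(x[4]))
    pr_names <- c(paste0("pinuc_", NUC), "kappa_pair")
  } else if (family$pair == "pair7_free") {
    pr_np <- 8L
    pr_init <- c(inv_softmax0(emp$pair7_freqs), log(2), 0)
    pr_unpack <- function(x)
      make_pair_model("7", freqs = softmax0(x[1:6]),
                      alpha = exp(x[7]), beta = exp(x[8]))
    pr_natural <- function(x) c(softmax0(x[1:6]), exp(x[7:8]))
    pr_names <- c(paste0("pi_", PAIR7_STATES), "alpha", "beta")
  } else { # pair7_fixmm
    pr_np <- 7L
    mm <- emp$pair7_freqs["MM"]
    canon0 <- emp$pair7_freqs[1:6] / sum(emp$pair7_freqs[1:6])
    pr_init <- c(inv_softmax0(canon0), log(2), 0)
    pr_unpack <- function(x) {
      canon <- softmax0(x[1:5]) * (1 - mm)
      make_pair_model("7", freqs = c(canon, mm),
                      alpha = exp(x[6]), beta = exp(x[7]))
    }
    pr_natural <- function(x) {
      canon <- softmax0(x[1:5]) * (1 - mm)
      c(canon, mm, exp(x[6:7]))
    }
    pr_names <- c(paste0("pi_", PAIR7_STATES), "alpha", "beta")
  }

  # pair flavors carry a free rate multiplier for the paired partition:
  # branch lengths are in per-column units while the doublet model is
  # normalized per pair site, and the stem clock need not equal the loop
  # clock
  has_rate <- !is.null(family$pair)
  rate_np <- if (has_rate) 1L else 0L
  list(
    n_params = nuc_np + pr_np + rate_np,
    init = c(nuc_init, pr_init, if (has_rate) log(2)),
    unpack = function(x) {
      pr_idx <- nuc_np + seq_len(pr_np)
      list(nuc = nuc_unpack(x[seq_len(nuc_np)]),
           pair = pr_unpack(x[pr_idx]),
           pair_rate = if (has_rate) exp(x[nuc_np + pr_np + 1L]) else 1)
    },
    natural = function(x) {
      pr_idx <- nuc_np + seq_len(pr_np)
      v <- c(nuc_natural(x[seq_len(nuc_np)]), pr_natural(x[pr_idx]),
             if (has_rate) exp(x[nuc_np + pr_np + 1L]))
      names(v) <- c(nuc_names, pr_names, if (has_rate) "pair_rate")
      v
    })
}

count_sites <- function(partition) nrow(partition$paired) + length(partition$unpaired)

aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a mixed model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over model parameters on the
#' transformed scale (L-BFGS-B). Branch lengths are fixed at their input
#' (NJ) values by default; set `optimize_branch_lengths = TRUE` to include
#' them in the optimization. Multistart jitters the initial point
#' reproducibly from `seed`. Non-convergence is flagged, not thrown.
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition`.
#' @param family a [model_family()].
#' @param tree optional `ape::phylo`; defaults to [build_nj_tree()].
#' @param optimize_branch_lengths also optimize branch lengths.
#' @param n_starts number of optimization starts.
#' @param seed RNG seed for the multistart jitter.
#' @return List of class `fitted_model`: `nuc_model`, `pair_model`, `tree`,
#'   `logL`, `n_params`, `n_sites`, `AICc`, `params` (natural scale),
#'   `converged`, `family`.
#' @export
fit_ml <- function(matrix, partition, family = model_family(), tree = NULL,
                   optimize_branch_lengths = FALSE, n_starts = 1L, seed = 1L) {
  if (is.null(tree)) tree <- build_nj_tree(matrix)
  if (!setequal(tree$tip.label, matrix$records$id))
    stop("tree taxa and alignment rows disagree")
  emp <- empirical_stats(matrix, partition)
  spec <- family_spec(family, emp)
  sd <- prepare_site_data(matrix, partition)
  trav <- tree_traversal(tree)
  nb <- length(tree$edge.length)
  bl0 <- pmax(tree$edge.length, 1e-6)
  npar <- spec$n_params + if (optimize_branch_lengths) nb else 0L

  objective <- function(x) {
    mods <- spec$unpack(x[seq_len(spec$n_params)])
    len <- if (optimize_branch_lengths)
      exp(x[spec$n_params + seq_len(nb)]) else tree$edge.length
    ll <- tryCatch(
      loglik_prepared(sd, trav, len, mods$nuc, mods$pair, mods$pair_rate),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  x0 <- c(spec$init, if (optimize_branch_lengths) log(bl0))
  set.seed(seed)
  starts <- list(x0)
  if (n_starts > 1L)
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- x0 + stats::rnorm(npar, sd = 0.3)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = rep(-20, npar), upper = rep(20, npar),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed for ", family$name)
  mods <- spec$unpack(best$par[seq_len(spec$n_params)])
  tr <- tree
  if (optimize_branch_lengths)
    tr$edge.length <- exp(best$par[spec$n_params + seq_len(nb)])
  n <- count_sites(partition)
  out <- list(family = family, nuc_model = mods$nuc, pair_model = mods$pair,
              tree = tr, logL = -best$value, n_params = npar, n_sites = n,
              AICc = aicc(-best$value, npar, n),
              params = spec$natural(best$par[seq_len(spec$n_params)]),
              transformed = best$par,
              converged = best$convergence == 0)
  class(out) <- "fitted_model"
  out
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s: logL = %.3f, k = %d, n = %d sites, AICc = %.3f%s\n",
              x$family$name, x$logL, x$n_params, x$n_sites, x$AICc,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Fit candidate model families and rank them by AICc
#'
#' All candidates (mixed and DNA-only) are scored on the same site
#' definition — one site per consensus base pair plus one per unpaired
#' column — so their AICc values are comparable.
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition`.
#' @param candidates list of [model_family()] objects; default covers
#'   HKY85 crossed with the four pair flavors plus the two DNA-only fits.
#' @param tree optional shared tree.
#' @param ... passed to [fit_ml()].
#' @return List of class `model_selection`: `best` (minimum-AICc
#'   `fitted_model`), `fits`, and `table` (ranked data frame).
#' @export
select_model <- function(matrix, partition, candidates = default_candidates(),
                         tree = NULL, ...) {
  if (length(candidates) == 0L) stop("need at least one candidate family")
  if (is.null(tree)) tree <- build_nj_tree(matrix)
  fits <- list()
  for (fam in candidates) {
    f <- tryCatch(fit_ml(matrix, partition, fam, tree = tree, ...),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[fam$name]] <- f
  }
  if (length(fits) == 0L) stop("all candidate fits failed")
  tab <- data.frame(
    model = names(fits),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "n_params"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  tab <- tab[order(tab$AICc), ]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  structure(list(best = fits[[tab$model[1]]], fits = fits, table = tab),
            class = "model_selection")
}

#' @rdname select_model
#' @export
default_candidates <- function() {
  list(model_family("HKY85", "pair16_free"),
       model_family("HKY85", "pair16_prod"),
       model_family("HKY85", "pair7_free"),
       model_family("HKY85", "pair7_fixmm"),
       model_family("HKY85", NULL),
       model_family("REV", NULL))
}
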