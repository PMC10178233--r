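# Substitution models: 4-state nucleotide (HKY85, REV) and base-pair
# doublet models (16-state, and 7-state with lumped mismatches), all built
# as q_ij = s_ij * pi_j with the diagonal closing rows to zero and Q
# rescaled to one expected substitution per unit time.

#' @rdname make_nuc_model
#' @export
NUC_PAIRS <- c("AC", "AG", "AU", "CG", "CU", "GU")

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "U") && b %in% c("C", "U"))
}

normalize_q <- function(Q, freqs) {
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero mean rate)")
  Q / mu
}

#' Build a 4-state nucleotide substitution model
#'
#' HKY85: one transition/transversion ratio `kappa` and free base
#' frequencies. REV (GTR): six symmetric exchangeabilities (order
#' AC, AG, AU, CG, CU, GU) and free frequencies. Q is normalized to unit
#' mean substitution rate.
#'
#' @param kind `"HKY85"` or `"REV"`.
#' @param freqs positive base frequencies, order A, C, G, U (renormalized
#'   to sum 1).
#' @param kappa transition/transversion ratio (HKY85).
#' @param rates 6 exchangeabilities (REV), order `NUC_PAIRS`.
#' @return Object of class `nuc_model`: `kind`, `freqs`, `Q`, parameters.
#' @export
make_nuc_model <- function(kind = c("HKY85", "REV"), freqs = rep(0.25, 4),
                           kappa = 2, rates = rep(1, 6)) {
  kind <- match.arg(kind)
  if (any(freqs <= 0)) stop("frequencies must be positive")
  freqs <- freqs / sum(freqs)
  names(freqs) <- NUC
  if (kind == "HKY85") {
    if (kappa < 0) stop("kappa must be >= 0")
    rates <- ifelse(NUC_PAIRS %in% c("AG", "CU"), kappa, 1)
  } else {
    if (length(rates) != 6 || any(rates < 0)) stop("need 6 nonnegative rates")
  }
  names(rates) <- NUC_PAIRS
  S <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (p in NUC_PAIRS) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    S[a, b] <- S[b, a] <- rates[p]
  }
  Q <- S * rep(freqs, each = 4)
  Q <- normalize_q(Q, freqs)
  structure(list(kind = kind, freqs = freqs, kappa = if (kind == "HKY85") kappa else NA,
                 rates = rates, Q = Q, reversible = TRUE),
            class = "nuc_model")
}

doublet_split <- function(d) c(substr(d, 1, 1), substr(d, 2, 2))

.model_cache <- new.env(parent = emptyenv())

#' Single-position adjacency of the 16 doublet states
#'
#' Two ordered doublets are adjacent when they differ at exactly one of the
#' two positions; models with `no_double_substitution` allow rates only on
#' these edges.
#'
#' @return 16 x 16 logical matrix, dimnames `DOUBLETS`.
#' @export
doublet_adjacency <- function() {
  if (!is.null(.model_cache$adj)) return(.model_cache$adj)
  A <- matrix(FALSE, 16, 16, dimnames = list(DOUBLETS, DOUBLETS))
  for (i in 1:16) for (j in 1:16) {
    if (i == j) next
    di <- doublet_split(DOUBLETS[i]); dj <- doublet_split(DOUBLETS[j])
    A[i, j] <- sum(di != dj) == 1L
  }
  .model_cache$adj <- A
  A
}

# logical masks splitting the allowed doublet edges into transition and
# transversion changes of the moving nucleotide
doublet_masks <- function() {
  if (!is.null(.model_cache$masks)) return(.model_cache$masks)
  adj <- doublet_adjacency()
  ts <- tv <- matrix(FALSE, 16, 16, dimnames = dimnames(adj))
  for (i in 1:16) for (j in 1:16) {
    if (!adj[i, j]) next
    di <- doublet_split(DOUBLETS[i]); dj <- doublet_split(DOUBLETS[j])
    ch <- which(di != dj)
    if (is_transition(di[ch], dj[ch])) ts[i, j] <- TRUE else tv[i, j] <- TRUE
  }
  .model_cache$masks <- list(ts = ts, tv = tv)
  .model_cache$masks
}

#' @rdname state-spaces
#' @export
PAIR7_STATES <- c("AU", "GU", "GC", "UA", "UG", "CG", "MM")

pair7_edges <- function() {
  # canonical/wobble chain edges plus each non-MM state <-> MM
  chain <- rbind(c("AU", "GU"), c("GU", "GC"), c("UA", "UG"), c("UG", "CG"))
  mm <- cbind(setdiff(PAIR7_STATES, "MM"), "MM")
  list(chain = chain, mm = mm)
}

#' Build a base-pair (doublet) substitution model
#'
#' 16-state models live on the ordered doublets `DOUBLETS`, with rates only
#' between doublets differing at one position (no double substitutions).
#' Exchangeabilities take the value `kappa` when the changing nucleotide
#' undergoes a transition (A<->G, C<->U) and 1 for a transversion. The
#' 7-state variant lumps the ten non-canonical doublets into a single
#' mismatch state MM, with `alpha` on the canonical/wobble chain edges and
#' `beta` on edges to MM.
#'
#' @param state_space `"16"` or `"7"`.
#' @param freqs stationary frequencies over the 16 doublets or 7 states
#'   (positive; renormalized).
#' @param kappa transition/transversion exchangeability ratio (16-state).
#' @param exch optional full symmetric exchangeability matrix overriding
#'   `kappa` (16-state; entries on non-adjacent pairs are ignored/zeroed).
#' @param alpha,beta 7-state exchangeabilities (chain and MM edges).
#' @return Object of class `pair_model`: `states`, `freqs`, `Q`,
#'   `no_double_substitution`, `reversible`.
#' @export
make_pair_model <- function(state_space = c("16", "7"),
                            freqs = NULL, kappa = 2, exch = NULL,
                            alpha = 2, beta = 1) {
  state_space <- match.arg(state_space)
  if (state_space == "16") {
    states <- DOUBLETS
    if (is.null(freqs)) freqs <- rep(1 / 16, 16)
    if (length(freqs) != 16 || any(freqs <= 0))
      stop("need 16 positive doublet frequencies")
    freqs <- freqs / sum(freqs); names(freqs) <- states
    adj <- doublet_adjacency()
    if (is.null(exch)) {
      mk <- doublet_masks()
      exch <- kappa * mk$ts + 1 * mk$tv
      dimnames(exch) <- list(states, states)
    } else {
      if (!isSymmetric(unname(exch))) stop("exch must be symmetric")
      exch[!adj] <- 0
    }
    S <- exch
  } else {
    states <- PAIR7_STATES
    if (is.null(freqs)) freqs <- rep(1 / 7, 7)
    if (length(freqs) != 7 || any(freqs <= 0))
      stop("need 7 positive state frequencies")
    freqs <- freqs / sum(freqs); names(freqs) <- states
    S <- matrix(0, 7, 7, dimnames = list(states, states))
    eg <- pair7_edges()
    for (r in seq_len(nrow(eg$chain)))
      S[eg$chain[r, 1], eg$chain[r, 2]] <- S[eg$chain[r, 2], eg$chain[r, 1]] <- alpha
    for (r in seq_len(nrow(eg$mm)))
      S[eg$mm[r, 1], eg$mm[r, 2]] <- S[eg$mm[r, 2], eg$mm[r, 1]] <- beta
  }
  n <- length(states)
  Q <- S * rep(freqs, each = n)
  Q <- normalize_q(Q, freqs)
  structure(list(state_space = state_space, states = states, freqs = freqs,
                 Q = Q, no_double_substitution = TRUE, reversible = TRUE),
            class = "pair_model")
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi Q = 0 with sum(pi) = 1 via the null space of t(Q) (SVD).
#' Errors when the chain is reducible (negative mass, a degenerate null
#' space, or a residual in pi Q = 0).
#'
#' @param Q square rate matrix (rows sum to 0).
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  sv <- svd(t(Q))
  if (n > 1 && sv$d[n - 1] < 1e-12 * max(sv$d))
    stop("reducible rate matrix: pi Q = 0 has no unique solution")
  pi <- sv$v[, n]
  pi <- pi / sum(pi)
  if (any(pi < -1e-8)) stop("reducible rate matrix: no positive stationary distribution")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (max(abs(pi %*% Q)) > 1e-8 * max(abs(Q)))
    stop("reducible rate matrix: pi Q = 0 unsatisfied")
  names(pi) <- rownames(Q)
  pi
}

# Matrix exponential by scaling-and-squaring with a (6,6) Pade approximant;
# used for non-reversible generators where the eigen route is unsafe.
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, 1e-300)/0.5)))
  A <- A / 2^s
  c_ <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/665280)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A4 %*% A2
  U <- A %*% (c_[2] * diag(n) + c_[4] * A2 + c_[6] * A4)
  V <- c_[1] * diag(n) + c_[3] * A2 + c_[5] * A4 + c_[7] * A6
  P <- solve(V - U, V + U)
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Reversible models use the symmetrized eigendecomposition (exact and
#' stable); other generators fall back to scaling-and-squaring.
#'
#' @param model a `nuc_model` or `pair_model`, or a bare list with `Q`,
#'   `freqs`, `reversible`.
#' @param t branch length (expected substitutions per site), >= 0.
#' @return Stochastic matrix of transition probabilities.
#' @export
transition_probabilities <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  Q <- model$Q
  n <- nrow(Q)
  if (t == 0) return(diag(n))
  if (isTRUE(model$reversible)) {
    ed <- model_eigen(model)
    P <- ed$inv_sqrt_pi %*% (ed$vectors %*% (exp(ed$values * t) * t(ed$vectors))) %*% ed$sqrt_pi
  } else {
    P <- expm_pade(Q * t)
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# cacheable symmetrized eigendecomposition of a reversible Q
model_eigen <- function(model) {
  if (!is.null(model$.eigen)) return(model$.eigen)
  pi <- model$freqs
  sp <- sqrt(pi)
  B <- (sp %o% (1 / sp)) * model$Q   # diag(sqrt pi) Q diag(1/sqrt pi)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors,
       sqrt_pi = diag(sp), inv_sqrt_pi = diag(1 / sp))
}

# attach the eigen cache (models are plain lists; callers keep the copy)
cache_eigen <- function(model) {
  model$.eigen <- model_eigen(model)
  model
}

#' Apply a GC-biased conversion multiplier to a doublet model
#'
#' Multiplies every allowed rate into a GC-type destination (GC or CG) by
#' `lambda` and renormalizes to unit mean rate under the new stationary
#' distribution. For `lambda != 1` the result is not time-reversible; it is
#' the forward generator used to emulate gBGC in simulation and the
#' construction used in directional tests.
#'
#' @param pair_model a 16-state `pair_model`.
#' @param lambda nonnegative multiplier on rates into GC-type pairs.
#' @return A `pair_model` (reversible flag FALSE when lambda != 1).
#' @export
gbgc_bias_model <- function(pair_model, lambda) {
  stopifnot(inherits(pair_model, "pair_model"), pair_model$state_space == "16")
  if (lambda < 0) stop("lambda must be >= 0")
  Q <- pair_model$Q
  gc_targets <- c("GC", "CG")
  Q[, gc_targets] <- Q[, gc_targets] * lambda
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi <- stationary_distribution(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  structure(list(state_space = "16", states = DOUBLETS, freqs = pi, Q = Q,
                 no_double_substitution = TRUE,
                 reversible = isTRUE(all.equal(lambda, 1))),
            class = "pair_model")
}
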