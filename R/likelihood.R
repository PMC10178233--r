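# Felsenstein pruning over an arbitrary finite state space. Sites are
# columns of an integer state matrix (taxa x sites, NA = missing/gap, which
# contributes a flat partial likelihood). Patterns are compressed once per
# data set and tip partials are precomputed; per-node partials are rescaled
# at the root to avoid underflow (trees here are small).

compress_patterns <- function(states, nstates) {
  key <- apply(states, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  st <- states[, first, drop = FALSE]
  ns <- ncol(st)
  ntip <- nrow(st)
  tips <- vector("list", ntip)
  for (k in seq_len(ntip)) {
    M <- matrix(0, nstates, ns)
    s <- st[k, ]
    M[cbind(s[!is.na(s)], which(!is.na(s)))] <- 1
    M[, is.na(s)] <- 1
    tips[[k]] <- M
  }
  names(tips) <- rownames(states)
  list(weights = as.numeric(tabulate(idx, nbins = ns)),
       tip_partials = tips, n_patterns = ns, nstates = nstates)
}

# traversal bookkeeping shared by every evaluation on the same tree
tree_traversal <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  eo <- match(paste(tr$edge[, 1], tr$edge[, 2]),
              paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge = tr$edge, edge_orig = eo, ntip = length(tree$tip.label),
       nnode = tree$Nnode, root = tr$edge[nrow(tr$edge), 1],
       tip_label = tree$tip.label)
}

# pruning on a compressed pattern set; trav from tree_traversal, lengths
# are the branch lengths in the ORIGINAL edge order
prune_loglik_cp <- function(cp, trav, lengths, model) {
  if (cp$n_patterns == 0L) return(0)
  model <- cache_eigen(model)
  Pm <- lapply(lengths, function(t) transition_probabilities(model, t))
  partial <- vector("list", trav$ntip + trav$nnode)
  for (k in seq_len(trav$ntip))
    partial[[k]] <- cp$tip_partials[[trav$tip_label[k]]]
  for (r in seq_len(nrow(trav$edge))) {
    par <- trav$edge[r, 1]; ch <- trav$edge[r, 2]
    contrib <- Pm[[trav$edge_orig[r]]] %*% partial[[ch]]
    partial[[par]] <- if (is.null(partial[[par]])) contrib
    else partial[[par]] * contrib
  }
  M <- partial[[trav$root]]
  mx <- apply(M, 2, max)
  if (any(mx <= 0)) return(-Inf)
  lik <- colSums(model$freqs * sweep(M, 2, mx, "/"))
  sum(cp$weights * (log(lik) + log(mx)))
}

states_to_index <- function(chr_matrix, alphabet) {
  idx <- match(chr_matrix, alphabet)
  dim(idx) <- dim(chr_matrix)
  rownames(idx) <- rownames(chr_matrix)
  idx
}

# one-off encoding of a partitioned alignment into the compressed pattern
# sets every model family needs
prepare_site_data <- function(matrix, partition) {
  enc <- encode_doublets(matrix, partition)
  seqs <- do.call(rbind, strsplit(matrix$records$sequence, "", fixed = TRUE))
  rownames(seqs) <- matrix$records$id
  seqs[seqs %in% c("-", "N")] <- NA
  list(
    unpaired = compress_patterns(states_to_index(enc$unpaired_sites, NUC), 4L),
    pair16 = compress_patterns(states_to_index(enc$pair_sites, DOUBLETS), 16L),
    pair7 = compress_patterns(
      states_to_index(lump_mismatches(enc$pair_sites), PAIR7_STATES), 7L),
    allcols = compress_patterns(states_to_index(seqs, NUC), 4L),
    # observed mismatch tokens: a 7-state fit is put on the 16-state
    # observation space by a uniform identity term log(1/10) per token
    n_mm_obs = sum(!is.na(enc$pair_sites) &
                     !(enc$pair_sites %in% setdiff(PAIR7_STATES, "MM"))))
}

loglik_prepared <- function(sd, trav, lengths, nuc_model, pair_model,
                            pair_rate = 1) {
  if (is.null(pair_model))
    return(prune_loglik_cp(sd$allcols, trav, lengths, nuc_model))
  if (pair_model$state_space == "16") {
    cp <- sd$pair16; corr <- 0
  } else {
    cp <- sd$pair7
    corr <- -sd$n_mm_obs * log(10)  # uniform mismatch identity given MM
  }
  prune_loglik_cp(sd$unpaired, trav, lengths, nuc_model) +
    prune_loglik_cp(cp, trav, lengths * pair_rate, pair_model) + corr
}

#' Log-likelihood of a partitioned alignment under mixed models
#'
#' Unpaired columns are scored under the 4-state nucleotide model and each
#' consensus base pair as one site under the doublet model (Felsenstein
#' pruning in both partitions; gaps/N marginalized). With `pair_model =
#' NULL` the paired columns are scored as independent nucleotide columns
#' under the nucleotide model (a "DNA-only" fit). So that 4-, 7- and
#' 16-state fits are comparable, a 7-state model is scored on the 16-state
#' observation space: each observed mismatch token contributes a uniform
#' identity term log(1/10) on top of its lumped MM likelihood.
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition`.
#' @param nuc_model a `nuc_model`.
#' @param pair_model a `pair_model` (`"16"` or `"7"`), or NULL.
#' @param tree `ape::phylo` with tips = allele ids, branch lengths in
#'   expected substitutions per site.
#' @param pair_rate rate multiplier of the paired partition relative to the
#'   nucleotide branch lengths (doublet sites span two columns, so their
#'   clock need not match the per-column clock).
#' @return Total natural-log likelihood.
#' @export
log_likelihood <- function(matrix, partition, nuc_model, pair_model, tree,
                           pair_rate = 1) {
  if (!setequal(tree$tip.label, matrix$records$id))
    stop("tree taxa and alignment rows disagree")
  sd <- prepare_site_data(matrix, partition)
  trav <- tree_traversal(tree)
  loglik_prepared(sd, trav, tree$edge.length, nuc_model, pair_model,
                  pair_rate)
}

# map 16 ordered doublets onto the 7-state space (non-canonical -> MM)
lump_mismatches <- function(pair_sites) {
  out <- pair_sites
  canon <- setdiff(PAIR7_STATES, "MM")
  out[!is.na(out) & !(out %in% canon)] <- "MM"
  out
}
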