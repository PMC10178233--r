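#' Jukes-Cantor corrected pairwise distances
#'
#' Proportion of differing sites over pairwise-comparable (non-gap, non-N)
#' positions, corrected as d = -3/4 log(1 - 4p/3). A saturated pair
#' (p >= 0.75) is an error naming the offending allele pair.
#'
#' @param records a `seqstruct`-style data frame of aligned sequences.
#' @return Symmetric distance matrix with allele ids as dimnames.
#' @export
jc_distance <- function(records) {
  n <- nrow(records)
  if (n < 2L) stop("need at least two records")
  seqs <- do.call(rbind, strsplit(records$sequence, "", fixed = TRUE))
  base <- seqs %in% NUC
  dim(base) <- dim(seqs)
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    comp <- base[a, ] & base[b, ]
    m <- sum(comp)
    p <- if (m == 0L) 0 else sum(seqs[a, comp] != seqs[b, comp]) / m
    if (p >= 0.75)
      stop("saturated distance (p >= 0.75) between '", records$id[a],
           "' and '", records$id[b], "'")
    D[a, b] <- D[b, a] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbor-joining tree from an allele matrix
#'
#' NJ on Jukes-Cantor corrected distances (pairwise deletion); negative NJ
#' branch lengths are clamped to zero. Two-allele matrices return the
#' trivial two-tip tree splitting the corrected distance.
#'
#' @param matrix a `species_matrix` (or a `seqstruct` data frame).
#' @return An `ape::phylo` tree over the allele ids.
#' @export
build_nj_tree <- function(matrix) {
  recs <- if (inherits(matrix, "species_matrix")) matrix$records else matrix
  if (length(unique(recs$id)) != nrow(recs))
    stop("allele ids must be unique to label tree tips")
  D <- jc_distance(recs)
  n <- nrow(D)
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
               tip.label = rownames(D), Nnode = 1L,
               edge.length = rep(D[1, 2] / 2, 2))
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
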