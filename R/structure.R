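#' Parse a dot-bracket structure into base pairs
#'
#' Standard stack parse of Vienna notation. Pairs are returned 1-based with
#' `i < j`, ordered by opening position.
#'
#' @param structure a dot-bracket string over `(`, `)`, `.`.
#' @return Integer matrix with columns `i`, `j` (0 rows if unpaired).
#' @export
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid structure character '", ch[bad[1]], "' at position ", bad[1])
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  res_i <- integer(0); res_j <- integer(0)
  for (p in seq_along(ch)) {
    if (ch[p] == "(") {
      stack <- c(stack, p)
    } else if (ch[p] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced structure: unmatched ')' at position ", p)
      res_i <- c(res_i, stack[length(stack)])
      res_j <- c(res_j, p)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced structure: unmatched '(' at position ", stack[1])
  if (length(res_i)) {
    o <- order(res_i)
    pairs <- cbind(i = res_i[o], j = res_j[o])
  }
  pairs
}

pairs_to_dotbracket <- function(pairs, ncols) {
  ch <- rep(".", ncols)
  if (nrow(pairs)) {
    ch[pairs[, 1]] <- "("
    ch[pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

crosses <- function(a, b) {
  # TRUE if pairs (a1,a2), (b1,b2) interleave (pseudoknot)
  (a[1] < b[1] & b[1] < a[2] & a[2] < b[2]) ||
    (b[1] < a[1] & a[1] < b[2] & b[2] < a[2])
}

#' Consensus secondary structure of an allele set
#'
#' A candidate base pair (i, j) is retained when at least `threshold` of the
#' alleles contain it in their individual structures. The retained set is
#' made non-crossing (Vienna notation cannot express pseudoknots) by greedy
#' selection in decreasing support, ties broken by the smaller opening
#' position.
#'
#' @param matrix a `species_matrix`.
#' @param threshold minimum per-pair support, in (0, 1]; default 0.70.
#' @return List of class `consensus_structure`: `dotbracket`, `pairs`
#'   (matrix i, j), `support` (fraction per retained pair), `ncols`.
#' @export
consensus_structure <- function(matrix, threshold = 0.70) {
  stopifnot(inherits(matrix, "species_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  recs <- matrix$records
  if (nrow(recs) == 0L) stop("empty species matrix")
  n <- nrow(recs)
  tab <- new.env(hash = TRUE)
  for (k in seq_len(n)) {
    prs <- parse_dotbracket(recs$structure[k])
    if (nrow(prs)) {
      keys <- paste(prs[, 1], prs[, 2], sep = ":")
      for (key in keys) {
        cur <- if (is.null(tab[[key]])) 0L else tab[[key]]
        tab[[key]] <- cur + 1L
      }
    }
  }
  keys <- ls(tab)
  if (length(keys) == 0L) {
    cons <- list(dotbracket = strrep(".", matrix$ncols),
                 pairs = cbind(i = integer(0), j = integer(0)),
                 support = numeric(0), ncols = matrix$ncols)
    class(cons) <- "consensus_structure"
    return(cons)
  }
  ij <- do.call(rbind, lapply(strsplit(keys, ":", fixed = TRUE), as.integer))
  supp <- vapply(keys, function(k) tab[[k]], integer(1)) / n
  keep <- supp >= threshold
  ij <- ij[keep, , drop = FALSE]
  supp <- supp[keep]
  # greedy non-crossing: decreasing support, ties by smaller i
  o <- order(-supp, ij[, 1], ij[, 2])
  ij <- ij[o, , drop = FALSE]; supp <- supp[o]
  sel <- logical(nrow(ij))
  used <- logical(matrix$ncols)
  for (r in seq_len(nrow(ij))) {
    a <- ij[r, ]
    if (used[a[1]] || used[a[2]]) next
    ok <- TRUE
    for (s in which(sel)) {
      if (crosses(a, ij[s, ])) { ok <- FALSE; break }
    }
    if (ok) { sel[r] <- TRUE; used[a[1]] <- used[a[2]] <- TRUE }
  }
  ij <- ij[sel, , drop = FALSE]; supp <- supp[sel]
  o <- order(ij[, 1])
  ij <- ij[o, , drop = FALSE]; supp <- supp[o]
  colnames(ij) <- c("i", "j")
  cons <- list(dotbracket = pairs_to_dotbracket(ij, matrix$ncols),
               pairs = ij, support = unname(supp), ncols = matrix$ncols)
  class(cons) <- "consensus_structure"
  cons
}

#' Partition alignment columns into paired and unpaired regions
#'
#' Every column of the alignment falls either in a stem (a member of exactly
#' one consensus base pair) or in an unpaired region, so
#' `2 * nrow(paired) + length(unpaired) == ncols`.
#'
#' @param consensus a `consensus_structure`, or a dot-bracket string.
#' @param ncols total number of alignment columns.
#' @return List of class `structure_partition`: `paired` (matrix i, j),
#'   `unpaired` (integer vector), `ncols`.
#' @export
partition_columns <- function(consensus, ncols) {
  if (is.character(consensus)) {
    if (nchar(consensus) != ncols) stop("consensus length != ncols")
    pairs <- parse_dotbracket(consensus)
  } else {
    if (consensus$ncols != ncols) stop("consensus length != ncols")
    pairs <- consensus$pairs
  }
  in_pair <- logical(ncols)
  in_pair[pairs] <- TRUE
  part <- list(paired = pairs, unpaired = which(!in_pair), ncols = ncols)
  class(part) <- "structure_partition"
  part
}

#' @export
print.structure_partition <- function(x, ...) {
  cat(sprintf("<structure_partition> %d columns: %d base pairs (%d cols), %d unpaired\n",
              x$ncols, nrow(x$paired), 2L * nrow(x$paired), length(x$unpaired)))
  invisible(x)
}

#' Write a partition as TSV (column, role, partner)
#'
#' Positions are printed 1-based; unpaired columns have partner `NA`.
#'
#' @param partition a `structure_partition`.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  role <- rep("unpaired", partition$ncols)
  partner <- rep(NA_integer_, partition$ncols)
  if (nrow(partition$paired)) {
    role[partition$paired] <- "paired"
    partner[partition$paired[, 1]] <- partition$paired[, 2]
    partner[partition$paired[, 2]] <- partition$paired[, 1]
  }
  utils::write.table(data.frame(column = seq_len(partition$ncols),
                                role = role, partner = partner),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' State-space constants
#'
#' `NUC` is the RNA alphabet; `DOUBLETS` the 16 ordered base-pair states
#' (position-1 nucleotide varying slowest: AA, AC, ..., UU).
#'
#' @name state-spaces
#' @export
DOUBLETS <- c(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0)))

#' @rdname state-spaces
#' @export
NUC <- c("A", "C", "G", "U")

#' Encode paired sites as doublets and unpaired columns as nucleotides
#'
#' Each consensus base pair (i, j) becomes one 16-state doublet site per
#' allele (the ordered pair of the bases at i and j); a gap or N on either
#' side makes the site missing (`NA`). Unpaired columns stay 4-state with
#' gap/N as `NA`.
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition` for its alignment.
#' @return List with `pair_sites` (alleles x pairs character matrix of
#'   doublets), `unpaired_sites` (alleles x unpaired-columns matrix of
#'   bases), both with allele ids as rownames.
#' @export
encode_doublets <- function(matrix, partition) {
  stopifnot(inherits(matrix, "species_matrix"),
            inherits(partition, "structure_partition"))
  if (partition$ncols != matrix$ncols)
    stop("partition does not match alignment width")
  seqs <- do.call(rbind, strsplit(matrix$records$sequence, "", fixed = TRUE))
  rownames(seqs) <- matrix$records$id
  miss <- seqs %in% c("-", "N")
  dim(miss) <- dim(seqs)
  np <- nrow(partition$paired)
  pair_sites <- matrix(NA_character_, nrow(seqs), np,
                       dimnames = list(rownames(seqs), NULL))
  if (np) {
    for (s in seq_len(np)) {
      i <- partition$paired[s, 1]; j <- partition$paired[s, 2]
      ok <- !miss[, i] & !miss[, j]
      pair_sites[ok, s] <- paste0(seqs[ok, i], seqs[ok, j])
    }
  }
  un <- seqs[, partition$unpaired, drop = FALSE]
  un[miss[, partition$unpaired, drop = FALSE]] <- NA_character_
  list(pair_sites = pair_sites, unpaired_sites = un)
}
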