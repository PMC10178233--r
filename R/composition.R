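#' Per-allele GC content over selected columns
#'
#' GC is computed per allele as 100 * (G + C) / (A + C + G + U) over the
#' selected columns, ignoring gaps and N; alleles with no countable base in
#' the selection are dropped. Copy counts are ignored: each distinct allele
#' enters the species mean once.
#'
#' @param records a `seqstruct` data frame (or any data frame with a
#'   `sequence` column of equal-length aligned strings).
#' @param columns integer vector of column indices to use; default all.
#' @param per_allele return the per-allele vector instead of the mean.
#' @return Mean GC percent across alleles (or per-allele vector).
#' @export
gc_content <- function(records, columns = NULL, per_allele = FALSE) {
  if (nrow(records) < 1L) stop("need at least one record")
  seqs <- do.call(rbind, strsplit(records$sequence, "", fixed = TRUE))
  if (is.null(columns)) columns <- seq_len(ncol(seqs))
  if (length(columns) == 0L) stop("empty column selection")
  sel <- seqs[, columns, drop = FALSE]
  gc <- rowSums(sel == "G" | sel == "C")
  tot <- rowSums(sel == "A" | sel == "C" | sel == "G" | sel == "U")
  if (all(tot == 0)) stop("no countable bases in selection")
  pct <- 100 * gc[tot > 0] / tot[tot > 0]
  if (per_allele) pct else mean(pct)
}

#' GC homogeneity across alleles
#'
#' Sample standard deviation (n - 1 denominator) of per-allele GC percents
#' over the selected columns: low values mean the alleles agree in GC.
#'
#' @inheritParams gc_content
#' @return SD of per-allele GC, in percentage points.
#' @export
gc_homogeneity <- function(records, columns = NULL) {
  if (nrow(records) < 2L) stop("need at least two records for an SD")
  stats::sd(gc_content(records, columns, per_allele = TRUE))
}

#' Average number of pairwise nucleotide differences (K)
#'
#' K is the mean over all unordered allele pairs of the number of aligned
#' positions at which both alleles carry an unambiguous base and the bases
#' differ (pairwise deletion of gaps/N, as in DnaSP). Alleles enter
#' unweighted; copy counts are ignored.
#'
#' @param records a `seqstruct` data frame (>= 2 records).
#' @param columns optional column subset.
#' @return K, a nonnegative real.
#' @export
avg_nucleotide_differences <- function(records, columns = NULL) {
  n <- nrow(records)
  if (n < 2L) stop("need at least two records for K")
  seqs <- do.call(rbind, strsplit(records$sequence, "", fixed = TRUE))
  if (!is.null(columns)) seqs <- seqs[, columns, drop = FALSE]
  base <- seqs %in% NUC
  dim(base) <- dim(seqs)
  total <- 0
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      comp <- base[a, ] & base[b, ]
      total <- total + sum(seqs[a, comp] != seqs[b, comp])
    }
  }
  total / (n * (n - 1L) / 2)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t approximation (the exact
#' permutation null is not used).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman rho undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Annotates GC distributions across species with a normality check.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) stop("n must be in [3, 5000]")
  if (stats::sd(x) == 0) stop("constant data: W undefined")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Per-column base frequency profile
#'
#' A tabular stand-in for a sequence logo: for each alignment column the
#' relative frequencies of A, C, G, U over non-gap bases, plus the gap/N
#' fraction of the column.
#'
#' @param records a `seqstruct` data frame.
#' @return Data frame with columns `column`, `A`, `C`, `G`, `U`, `gap`;
#'   A..U rows sum to 1 where any base is present.
#' @export
base_frequency_profile <- function(records) {
  if (nrow(records) < 1L) stop("need at least one record")
  seqs <- do.call(rbind, strsplit(records$sequence, "", fixed = TRUE))
  n <- nrow(seqs)
  counts <- sapply(NUC, function(b) colSums(seqs == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, NUC))
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot == 0, 1, tot)
  data.frame(column = seq_len(ncol(seqs)), freq,
             gap = 1 - tot / n, row.names = NULL)
}

#' Per-species GC report
#'
#' Computes total, paired-region and unpaired-region GC with across-allele
#' SDs for one species matrix under a structure partition.
#'
#' @param matrix a `species_matrix`.
#' @param partition a `structure_partition`.
#' @return One-row data frame: species, n_alleles, gc_total, gc_paired,
#'   gc_unpaired, sd_paired, sd_unpaired, K.
#' @export
gc_report <- function(matrix, partition) {
  recs <- matrix$records
  pcols <- as.integer(partition$paired)
  ucols <- partition$unpaired
  sd_or_na <- function(cols) {
    if (nrow(recs) >= 2L && length(cols))
      tryCatch(gc_homogeneity(recs, cols), error = function(e) NA_real_)
    else NA_real_
  }
  data.frame(
    species = matrix$species,
    n_alleles = nrow(recs),
    gc_total = gc_content(recs),
    gc_paired = if (length(pcols)) gc_content(recs, pcols) else NA_real_,
    gc_unpaired = if (length(ucols)) gc_content(recs, ucols) else NA_real_,
    sd_paired = sd_or_na(pcols),
    sd_unpaired = sd_or_na(ucols),
    K = if (nrow(recs) >= 2L) avg_nucleotide_differences(recs) else NA_real_,
    stringsAsFactors = FALSE)
}
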