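#' Sequence-structure records
#'
#' An ITS2 allele set is held as a `seqstruct` data frame with one row per
#' allele and columns `id`, `sequence` (aligned, RNA alphabet A/C/G/U plus
#' `-` and `N`), `structure` (dot-bracket of the same length) and
#' `copy_count` (positive integer; how many raw reads/copies supported the
#' allele). DNA input (`T`) is normalized to RNA (`U`) on read; structures
#' must be balanced Vienna strings.
#'
#' @param id character vector of allele labels.
#' @param sequence character vector of aligned sequences.
#' @param structure character vector of dot-bracket strings.
#' @param copy_count integer vector of copy counts (recycled; default 1).
#' @return A `data.frame` of class `seqstruct`.
#' @export
seqstruct <- function(id, sequence, structure, copy_count = 1L) {
  sequence <- normalize_rna(sequence)
  structure <- as.character(structure)
  copy_count <- as.integer(rep_len(copy_count, length(id)))
  recs <- data.frame(id = as.character(id), sequence = sequence,
                     structure = structure, copy_count = copy_count,
                     stringsAsFactors = FALSE)
  validate_seqstruct(recs)
  class(recs) <- c("seqstruct", "data.frame")
  recs
}

normalize_rna <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGUN-]", x)
  if (any(bad))
    stop("invalid sequence character in record(s): ",
         paste(which(bad), collapse = ", "),
         " (only A,C,G,U/T,N,- are accepted)")
  x
}

validate_seqstruct <- function(recs) {
  stopifnot(is.data.frame(recs),
            all(c("id", "sequence", "structure", "copy_count") %in% names(recs)))
  if (nrow(recs) == 0L) stop("empty record set")
  if (any(nchar(recs$sequence) != nchar(recs$structure)))
    stop("sequence/structure length mismatch in record(s): ",
         paste(recs$id[nchar(recs$sequence) != nchar(recs$structure)],
               collapse = ", "))
  if (any(grepl("[^().]", recs$structure)))
    stop("invalid structure character (only '(', ')', '.') in record(s): ",
         paste(recs$id[grepl("[^().]", recs$structure)], collapse = ", "))
  for (k in seq_len(nrow(recs)))
    tryCatch(parse_dotbracket(recs$structure[k]),
             error = function(e) stop("record '", recs$id[k], "': ",
                                      conditionMessage(e), call. = FALSE))
  if (any(recs$copy_count < 1L)) stop("copy_count must be >= 1")
  invisible(recs)
}

#' Read a Vienna-triplet sequence-structure file
#'
#' The file is a FASTA dialect of 3-line groups: a `>` header (optionally
#' carrying `count=N`), the aligned sequence, and its dot-bracket structure.
#' `T` is mapped to `U` and letters are upper-cased.
#'
#' @param path path to the file.
#' @return A `seqstruct` data frame.
#' @export
read_seqstruct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  if (length(lines) %% 3L != 0L)
    stop("malformed Vienna-triplet file (line count not a multiple of 3): ",
         path)
  hdr <- lines[seq(1L, length(lines), by = 3L)]
  seqs <- trimws(lines[seq(2L, length(lines), by = 3L)])
  strs <- trimws(lines[seq(3L, length(lines), by = 3L)])
  if (!all(startsWith(hdr, ">")))
    stop("malformed header line (must start with '>'): ",
         hdr[!startsWith(hdr, ">")][1L])
  hdr <- sub("^>\\s*", "", hdr)
  cnt <- rep(1L, length(hdr))
  has_cnt <- grepl("count=([0-9]+)", hdr)
  cnt[has_cnt] <- as.integer(sub(".*count=([0-9]+).*", "\\1", hdr[has_cnt]))
  id <- sub("\\s.*$", "", hdr)
  seqstruct(id = id, sequence = seqs, structure = strs, copy_count = cnt)
}

#' Write sequence-structure records as Vienna triplets
#'
#' Inverse of [read_seqstruct()]: `read_seqstruct(write_seqstruct(x, f))`
#' reproduces `x`.
#'
#' @param records a `seqstruct` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seqstruct <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) stop("nothing to write")
  validate_seqstruct(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    writeLines(c(sprintf(">%s count=%d", records$id[k], records$copy_count[k]),
                 records$sequence[k], records$structure[k]), con)
  }
  invisible(path)
}

#' Remove singleton alleles
#'
#' Alleles supported by a single copy are likely sequencing/assembly
#' artifacts and are removed before any downstream analysis; kept records
#' preserve their input order.
#'
#' @param records a `seqstruct` data frame with copy counts.
#' @param quiet suppress the kept/removed message.
#' @return The records with `copy_count >= 2`.
#' @export
filter_singleton_alleles <- function(records, quiet = FALSE) {
  keep <- records$copy_count >= 2L
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message(sprintf("filter_singleton_alleles: kept %d, removed %d singleton(s)",
                    sum(keep), sum(!keep)))
  if (nrow(out) == 0L)
    warning("all alleles were singletons; empty record set returned")
  class(out) <- c("seqstruct", "data.frame")
  out
}

#' Read a plain FASTA file (sequence only)
#'
#' For structure-free inputs such as 5.8S allele sets. Headers may carry
#' `count=N` like the Vienna-triplet dialect; sequences are normalized to
#' the RNA alphabet.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id`, `sequence`, `copy_count`.
#' @export
read_fasta_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("malformed FASTA (no leading header): ", path)
  grp <- cumsum(is_hdr)
  hdr <- sub("^>\\s*", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  cnt <- rep(1L, length(hdr))
  has_cnt <- grepl("count=([0-9]+)", hdr)
  cnt[has_cnt] <- as.integer(sub(".*count=([0-9]+).*", "\\1", hdr[has_cnt]))
  data.frame(id = sub("\\s.*$", "", hdr), sequence = normalize_rna(seqs),
             copy_count = cnt, stringsAsFactors = FALSE)
}

#' Bundle allele records into a species matrix
#'
#' A species matrix is the per-species unit of analysis: an aligned
#' sequence-structure allele set, optionally with a consensus structure
#' attached (see [consensus_structure()]).
#'
#' @param species_name species label.
#' @param records a `seqstruct` data frame; all sequences must share one
#'   aligned length.
#' @param consensus optional dot-bracket consensus of that length.
#' @return An object of class `species_matrix`.
#' @export
species_matrix <- function(species_name, records, consensus = NULL) {
  validate_seqstruct(records)
  len <- unique(nchar(records$sequence))
  if (length(len) != 1L)
    stop("records of species '", species_name,
         "' have differing aligned lengths: ", paste(len, collapse = ", "))
  if (!is.null(consensus) && nchar(consensus) != len)
    stop("consensus length != alignment length")
  structure(list(species = as.character(species_name), records = records,
                 ncols = len, consensus = consensus),
            class = "species_matrix")
}

#' @export
print.species_matrix <- function(x, ...) {
  cat(sprintf("<species_matrix> %s: %d allele(s), %d aligned columns%s\n",
              x$species, nrow(x$records), x$ncols,
              if (is.null(x$consensus)) "" else ", consensus attached"))
  invisible(x)
}
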