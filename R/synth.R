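# Synthetic ITS2 allele families. The forward model mirrors the assumed
# biology: a species tree, structure-constrained substitution (4-state HKY
# in loops, 16-state no-double-substitution doublet model in stems), a
# gBGC-style multiplier on rates into GC-type pairs, and incomplete
# within-species homogenization (alleles on a star tree whose depth scales
# with 1 - h). Gene conversion both homogenizes repeats and drives gBGC, so
# the effective GC bias of a species scales with its homogenization level:
# lambda_s = 1 + (lambda - 1) * h_s.

# evaluate expr under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (has) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Configuration of the synthetic ITS2-family generator
#'
#' Defaults emulate the study system: 29 allele families, ITS2-like length
#' 260 nt with ~46% of columns in four stems, GC-rich loops via skewed base
#' frequencies, within-species allele heterogeneity spanning K of roughly
#' 2-13 across homogenization levels, and a GC-biased doublet process in
#' stems.
#'
#' @param n_species number of species-level allele families.
#' @param alleles_per_species integer, or length-2 range sampled per
#'   species.
#' @param seq_length alignment columns (>= 40).
#' @param paired_fraction fraction of columns inside stems.
#' @param n_stems number of stems in the simulated structure.
#' @param species_tree_depth root-to-tip depth of the Yule species tree, in
#'   expected substitutions per site.
#' @param h homogenization in [0, 1] (scalar, or one value per species);
#'   allele divergence scales with 1 - h. The default spreads species
#'   evenly over 0.35-0.95, giving within-species K spanning roughly the
#'   2-13 range observed in real ITS2 allele families.
#' @param allele_depth star-tree branch length at h = 0 (expected
#'   substitutions per site).
#' @param lambda gBGC strength: multiplier (at h = 1) on doublet rates into
#'   GC-type pairs; 1 = neutral.
#' @param conversion_history extra paired-region exposure (expected
#'   substitutions per doublet site at h = 1) of each terminal lineage to
#'   its own biased process, scaled by h_s: concerted evolution churns the
#'   array faster than the species clock, and every conversion event is a
#'   gBGC opportunity.
#' @param stem_pairing_bias stationary-frequency weight of canonical
#'   Watson-Crick doublets relative to mismatches (wobble pairs get its
#'   square root): structural selection keeps stems mostly base-paired.
#'   Symmetric between GC and AU, so it does not by itself bias GC.
#' @param kappa transition/transversion ratio of the loop (HKY85) model,
#'   also the doublet-model exchangeability ratio.
#' @param base_freqs loop base frequencies (A, C, G, U).
#' @param copy_count_mean mean allele copy count (geometric; exercises the
#'   singleton filter).
#' @param seed integer seed; all randomness flows from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_species = 29L, alleles_per_species = c(4L, 30L),
                         seq_length = 260L, paired_fraction = 0.46,
                         n_stems = 4L, species_tree_depth = 0.2,
                         h = seq(0.35, 0.95, length.out = n_species),
                         allele_depth = 0.04, lambda = 3,
                         conversion_history = 1.5,
                         stem_pairing_bias = 10,
                         kappa = 4, base_freqs = c(0.18, 0.32, 0.32, 0.18),
                         copy_count_mean = 5, seed = 1L) {
  stopifnot(seq_length >= 40L, paired_fraction >= 0, paired_fraction <= 1,
            lambda >= 0, all(h >= 0), all(h <= 1), kappa >= 0,
            stem_pairing_bias >= 1,
            length(base_freqs) == 4, all(base_freqs > 0))
  structure(list(n_species = as.integer(n_species),
                 alleles_per_species = alleles_per_species,
                 seq_length = as.integer(seq_length),
                 paired_fraction = paired_fraction, n_stems = as.integer(n_stems),
                 species_tree_depth = species_tree_depth,
                 h = h, allele_depth = allele_depth, lambda = lambda,
                 conversion_history = conversion_history,
                 stem_pairing_bias = stem_pairing_bias,
                 kappa = kappa, base_freqs = base_freqs / sum(base_freqs),
                 copy_count_mean = copy_count_mean, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a nested multi-stem secondary structure
#'
#' Stems are laid out side by side, separated by unpaired linkers, each
#' enclosing a terminal loop (>= 3 nt). The realized number of paired
#' columns equals `2 * round(paired_fraction * seq_length / 2)`.
#'
#' @param seq_length total columns.
#' @param paired_fraction target fraction of paired columns.
#' @param n_stems number of stems.
#' @param seed RNG seed (deterministic output per seed).
#' @return A dot-bracket string of length `seq_length`.
#' @export
simulate_structure <- function(seq_length, paired_fraction, n_stems = 4L,
                               seed = 1L) {
  npair_cols <- 2L * round(paired_fraction * seq_length / 2)
  P <- npair_cols %/% 2L
  if (P == 0L) return(strrep(".", seq_length))
  if (P < n_stems) stop("infeasible: fewer base pairs than stems")
  U <- seq_length - npair_cols
  min_loop <- 3L
  if (U < n_stems * min_loop)
    stop("infeasible: not enough unpaired columns for ", n_stems, " loops")
  with_seed(seed, {
    # split pairs across stems, then spread spare unpaired columns over
    # loops and the n_stems + 1 linkers
    stem_p <- rep(P %/% n_stems, n_stems)
    extra <- P - sum(stem_p)
    if (extra > 0) {
      idx <- sample.int(n_stems, extra)
      stem_p[idx] <- stem_p[idx] + 1L
    }
    loops <- rep(min_loop, n_stems)
    linkers <- rep(0L, n_stems + 1L)
    spare <- U - sum(loops)
    if (spare > 0) {
      slots <- sample.int(n_stems * 2L + 1L, spare, replace = TRUE)
      for (s in slots) {
        if (s <= n_stems) loops[s] <- loops[s] + 1L
        else linkers[s - n_stems] <- linkers[s - n_stems] + 1L
      }
    }
    parts <- character(0)
    for (k in seq_len(n_stems)) {
      parts <- c(parts, strrep(".", linkers[k]),
                 strrep("(", stem_p[k]), strrep(".", loops[k]),
                 strrep(")", stem_p[k]))
    }
    parts <- c(parts, strrep(".", linkers[n_stems + 1L]))
    paste(parts, collapse = "")
  })
}

# root draw with composition fixed to probs (largest-remainder counts,
# shuffled order): the root is the study condition, not a noise source
sample_composition <- function(n, probs) {
  probs <- probs / sum(probs)
  counts <- floor(n * probs)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * probs - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  sample(rep.int(seq_along(probs), counts))
}

# sample child states along one edge: states are integer indices
evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

# evolve root states down an ape tree; edge_model(edge_row) -> model
sim_tree_states <- function(tree, root_states, edge_model) {
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  states[[root]] <- root_states
  ord <- ape::reorder.phylo(tree, "cladewise")
  eo <- match(paste(ord$edge[, 1], ord$edge[, 2]),
              paste(tree$edge[, 1], tree$edge[, 2]))
  for (r in seq_len(nrow(ord$edge))) {
    par <- ord$edge[r, 1]; ch <- ord$edge[r, 2]
    m <- edge_model(eo[r])
    P <- transition_probabilities(m, tree$edge.length[eo[r]])
    states[[ch]] <- evolve_states(states[[par]], P)
  }
  stats::setNames(states[seq_len(ntip)], tree$tip.label)
}

assemble_sequence <- function(un_states, pair_states, partition) {
  ch <- character(partition$ncols)
  ch[partition$unpaired] <- NUC[un_states]
  if (nrow(partition$paired)) {
    d <- DOUBLETS[pair_states]
    ch[partition$paired[, 1]] <- substr(d, 1, 1)
    ch[partition$paired[, 2]] <- substr(d, 2, 2)
  }
  paste(ch, collapse = "")
}

#' Simulate ITS2-like allele families
#'
#' Draws a Yule species tree scaled to `species_tree_depth`, evolves a root
#' sequence along it (loops under HKY85, stems under the 16-state
#' no-double-substitution doublet model with the species' effective GC
#' bias), then evolves each species' alleles on a star tree of depth
#' `(1 - h_s) * allele_depth`. The root is drawn from the stationary
#' distribution of the family-average biased process, so GC bias is already
#' reflected in standing composition, as in a long-evolved rDNA array.
#'
#' @param config a [synth_config()].
#' @return List of class `synth_family`: `families` (list of
#'   `species_matrix`), `structure` (true dot-bracket), `partition`,
#'   `truth` (per-species h, lambda_eff, realized GC and K, the species
#'   tree, seed).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    struct <- simulate_structure(config$seq_length, config$paired_fraction,
                                 config$n_stems,
                                 seed = sample.int(2^30, 1))
    part <- partition_columns(struct, config$seq_length)
    h <- rep_len(config$h, config$n_species)

    nuc <- make_nuc_model("HKY85", freqs = config$base_freqs,
                          kappa = config$kappa)
    bf <- config$base_freqs; names(bf) <- NUC
    f16 <- bf[substr(DOUBLETS, 1, 1)] * bf[substr(DOUBLETS, 2, 2)]
    wts <- rep(1, 16); names(wts) <- DOUBLETS
    wts[c("GC", "CG", "AU", "UA")] <- config$stem_pairing_bias
    wts[c("GU", "UG")] <- sqrt(config$stem_pairing_bias)
    f16 <- f16 * wts
    pair0 <- make_pair_model("16", freqs = f16 / sum(f16),
                             kappa = config$kappa)
    lam_eff <- 1 + (config$lambda - 1) * h
    pair_s <- lapply(lam_eff, function(l) gbgc_bias_model(pair0, l))
    pair_ref <- gbgc_bias_model(pair0, 1 + (config$lambda - 1) * mean(h))

    ntip <- config$n_species
    if (ntip >= 2L) {
      tree <- ape::rphylo(ntip, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length * config$species_tree_depth / depth
      tree$tip.label <- sprintf("sp%02d", seq_len(ntip))
    } else {
      tree <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "sp01",
                   Nnode = 1L, edge.length = config$species_tree_depth)
      class(tree) <- "phylo"
    }
    is_tip_edge <- tree$edge[, 2] <= ntip

    nU <- length(part$unpaired); nP <- nrow(part$paired)
    root_un <- sample_composition(nU, config$base_freqs)
    root_pair <- if (nP) sample_composition(nP, pair_ref$freqs)
    else integer(0)

    un_tips <- sim_tree_states(tree, root_un, function(e) nuc)
    pair_tips <- if (nP)
      sim_tree_states(tree, root_pair, function(e) {
        if (is_tip_edge[e]) pair_s[[tree$edge[e, 2]]] else pair_ref
      })
    else stats::setNames(rep(list(integer(0)), ntip), tree$tip.label)

    nall <- if (length(config$alleles_per_species) == 2L)
      sample(config$alleles_per_species[1]:config$alleles_per_species[2],
             ntip, replace = TRUE)
    else rep_len(config$alleles_per_species, ntip)

    families <- vector("list", ntip)
    truth <- data.frame(species = tree$tip.label, h = h,
                        lambda_eff = lam_eff, n_alleles = nall,
                        gc_paired = NA_real_, gc_unpaired = NA_real_,
                        K = NA_real_)
    for (s in seq_len(ntip)) {
      # biased array churn along the terminal lineage, in proportion to
      # the species' homogenization level
      t_conv <- config$conversion_history * h[s]
      sp_pair <- pair_tips[[s]]
      if (nP && t_conv > 0)
        sp_pair <- evolve_states(sp_pair,
                                 transition_probabilities(pair_s[[s]], t_conv))
      t_all <- (1 - h[s]) * config$allele_depth
      Pn <- transition_probabilities(nuc, t_all)
      Pp <- if (nP) transition_probabilities(pair_s[[s]], t_all) else NULL
      ids <- sprintf("%s_a%02d", tree$tip.label[s], seq_len(nall[s]))
      seqs <- character(nall[s])
      for (a in seq_len(nall[s])) {
        ua <- evolve_states(un_tips[[s]], Pn)
        pa <- if (nP) evolve_states(sp_pair, Pp) else integer(0)
        seqs[a] <- assemble_sequence(ua, pa, part)
      }
      cnt <- 1L + stats::rgeom(nall[s], prob = 1 / config$copy_count_mean)
      recs <- seqstruct(id = ids, sequence = seqs,
                        structure = rep(struct, nall[s]), copy_count = cnt)
      families[[s]] <- species_matrix(tree$tip.label[s], recs,
                                      consensus = struct)
      truth$gc_paired[s] <- if (nP) gc_content(recs, as.integer(part$paired))
      else NA_real_
      truth$gc_unpaired[s] <- if (length(part$unpaired))
        gc_content(recs, part$unpaired) else NA_real_
      truth$K[s] <- if (nall[s] >= 2L) avg_nucleotide_differences(recs)
      else NA_real_
    }
    structure(list(families = families, structure = struct, partition = part,
                   truth = list(config = config, tree = tree,
                                per_species = truth)),
              class = "synth_family")
  })
}

#' Collapse a synthetic family to a cross-species alignment
#'
#' Takes the first allele of each species to form a species-level
#' `species_matrix` (tips = species), for fitting a single across-species
#' substitution model.
#'
#' @param fam a `synth_family`.
#' @return A `species_matrix`.
#' @export
species_alignment <- function(fam) {
  recs <- do.call(rbind, lapply(fam$families, function(m) {
    r <- m$records[1, , drop = FALSE]
    r$id <- m$species
    r
  }))
  class(recs) <- c("seqstruct", "data.frame")
  species_matrix("all_species", recs, consensus = fam$structure)
}

#' Write a synthetic family to disk
#'
#' One Vienna-triplet file per species plus `truth.json`.
#'
#' @param fam a `synth_family`.
#' @param dir output directory (created).
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in fam$families)
    write_seqstruct(m$records, file.path(dir, paste0(m$species, ".vienna")))
  truth <- fam$truth
  truth$tree <- ape::write.tree(truth$tree)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Homogenization-gradient study of the gBGC signature
#'
#' Runs the generator across a grid of homogenization levels (one species
#' per level, `n_seeds` replicate families) and pools per-species K and
#' regional GC, the design that exposes the K-GC coupling produced by
#' gBGC.
#'
#' @param h_grid homogenization levels (one species each).
#' @param lambda gBGC strength.
#' @param n_seeds replicate families.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param ... overrides passed to [synth_config()].
#' @return Data frame: seed, species, h, K, gc_paired, gc_unpaired.
#' @export
simulate_h_grid <- function(h_grid = seq(0.05, 0.95, by = 0.1), lambda = 3,
                            n_seeds = 10L, seed = 1L, ...) {
  out <- list()
  for (r in seq_len(n_seeds)) {
    cfg <- synth_config(n_species = length(h_grid), h = h_grid,
                        lambda = lambda, seed = seed + r, ...)
    fam <- simulate_family(cfg)
    df <- fam$truth$per_species
    df$seed <- seed + r
    out[[r]] <- df
  }
  do.call(rbind, out)
}
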