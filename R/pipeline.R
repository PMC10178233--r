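#' Pipeline run configuration
#'
#' Exactly one input mode: `synth` (a [synth_config()]) or `input_dir` (a
#' directory of per-species Vienna-triplet files).
#'
#' @param synth a `synth_config`, or NULL.
#' @param input_dir directory of `*.vienna`/`*.fasta` triplet files, or
#'   NULL.
#' @param consensus_threshold per-pair support threshold for the consensus
#'   structure.
#' @param candidates model families for [select_model()]; default
#'   [default_candidates()].
#' @param estimator `"ml"` or `"mcmc"` for the substitution-parameter
#'   estimates feeding the GC dynamics.
#' @param mcmc list of overrides for [mcmc_sample()] (n_iter, thin, ...).
#' @param out_dir output directory for the result tables.
#' @param seed seed for the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = NULL, input_dir = NULL,
                       consensus_threshold = 0.70,
                       candidates = default_candidates(),
                       estimator = c("ml", "mcmc"), mcmc = list(),
                       out_dir = tempfile("its2gc_run_"), seed = 1L) {
  if (is.null(synth) == is.null(input_dir))
    stop("exactly one of `synth` and `input_dir` must be given")
  if (consensus_threshold <= 0 || consensus_threshold > 1)
    stop("consensus_threshold must be in (0, 1]")
  structure(list(synth = synth, input_dir = input_dir,
                 consensus_threshold = consensus_threshold,
                 candidates = candidates, estimator = match.arg(estimator),
                 mcmc = mcmc, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_species_matrices <- function(dir) {
  files <- list.files(dir, pattern = "\\.(vienna|fasta|fa|txt)$",
                      full.names = TRUE)
  files <- files[basename(files) != "truth.json"]
  if (length(files) == 0L) stop("no sequence-structure files in ", dir)
  lapply(files, function(f) {
    sp <- sub("\\.[^.]*$", "", basename(f))
    species_matrix(sp, read_seqstruct(f))
  })
}

analyze_species <- function(mat, threshold, candidates, estimator, mcmc_opts,
                            seed) {
  recs <- suppressWarnings(filter_singleton_alleles(mat$records,
                                                    quiet = TRUE))
  if (nrow(recs) < 2L)
    stop("fewer than 2 alleles remain after the singleton filter")
  mat <- species_matrix(mat$species, recs)
  cons <- consensus_structure(mat, threshold)
  part <- partition_columns(cons, mat$ncols)
  if (nrow(part$paired) == 0L) stop("no consensus base pairs retained")
  gc <- gc_report(mat, part)
  tree <- build_nj_tree(mat)
  sel <- select_model(mat, part, candidates, tree = tree)

  # GC dynamics need a pair model; use the top-ranked fit that carries a
  # 16-state one (mismatch identities require the full doublet space)
  with_pair16 <- Filter(function(f)
    !is.null(f$pair_model) && f$pair_model$state_space == "16", sel$fits)
  if (length(with_pair16) == 0L) stop("no 16-state candidate fit available")
  aiccs <- vapply(with_pair16, `[[`, numeric(1), "AICc")
  dynfit <- with_pair16[[which.min(aiccs)]]
  nuc_mod <- dynfit$nuc_model
  pair_mod <- dynfit$pair_model
  mcmc_fit <- NULL
  if (estimator == "mcmc") {
    npar <- family_spec(dynfit$family, empirical_stats(mat, part))$n_params
    args <- c(list(matrix = mat, partition = part, family = dynfit$family,
                   tree = tree, seed = seed,
                   init = dynfit$transformed[seq_len(npar)]),
              mcmc_opts)
    mcmc_fit <- do.call(mcmc_sample, args)
    mods <- mcmc_mean_models(mcmc_fit, mat, part)
    nuc_mod <- mods$nuc; pair_mod <- mods$pair
  }
  form <- formation_rates(pair_mod)
  mm <- mismatch_conversion(pair_mod)
  star_up <- gc_star_nucleotide(nuc_mod)
  star_p <- gc_star_pair(pair_mod)
  list(species = mat$species, gc = gc, partition = part,
       selection = sel, mcmc = mcmc_fit,
       formation = form, mismatch = mm,
       trend_paired = gc_trend(gc$gc_paired, star_p, region = "paired"),
       trend_unpaired = gc_trend(gc$gc_unpaired, star_up,
                                 region = "unpaired"))
}

#' Run the full structure-partitioned GC analysis
#'
#' Per species: singleton filter, consensus structure at the configured
#' support threshold, paired/unpaired partition, GC/K statistics, AICc
#' model selection, formation-rate and mismatch-conversion summaries, and
#' GC*/trend for both regions. Across species: Spearman correlations of K
#' against total/paired/unpaired GC. Tables are written to
#' `config$out_dir`; species failing a stage are skipped with a warning.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `gc_table`, `correlations`,
#'   `model_selection`, `transformation`, `gcstar`, `skipped`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mats <- if (!is.null(config$synth)) {
    cfg <- config$synth
    simulate_family(cfg)$families
  } else load_species_matrices(config$input_dir)
  if (length(mats) == 0L) stop("empty input: no species matrices")

  res <- list(); skipped <- character(0)
  for (mat in mats) {
    r <- tryCatch(
      analyze_species(mat, config$consensus_threshold, config$candidates,
                      config$estimator, config$mcmc, config$seed),
      error = function(e) {
        warning("species '", mat$species, "' skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(r)) res[[mat$species]] <- r else
      skipped <- c(skipped, mat$species)
  }
  if (length(res) == 0L) stop("no species could be analyzed")

  gc_table <- do.call(rbind, lapply(res, `[[`, "gc"))
  rownames(gc_table) <- NULL

  correlations <- NULL
  ok <- !is.na(gc_table$K)
  if (sum(ok) >= 3L) {
    sp_cor <- function(y) {
      ct <- tryCatch(spearman_correlation(gc_table$K[ok], y[ok]),
                     error = function(e) list(rho = NA, p_value = NA))
      c(rho = ct$rho, p = ct$p_value)
    }
    correlations <- data.frame(
      comparison = c("K_vs_gc_total", "K_vs_gc_paired", "K_vs_gc_unpaired"),
      rbind(sp_cor(gc_table$gc_total), sp_cor(gc_table$gc_paired),
            sp_cor(gc_table$gc_unpaired)), row.names = NULL)
  }

  model_tab <- do.call(rbind, lapply(res, function(r) {
    t <- r$selection$table; t$species <- r$species; t
  }))
  rownames(model_tab) <- NULL
  trans_tab <- do.call(rbind, lapply(res, function(r) data.frame(
    species = r$species,
    total_to_GC = r$formation$total_to_GC,
    total_to_AU = r$formation$total_to_AU,
    formation_ratio = r$formation$ratio,
    gc_pair_freq = r$formation$gc_pair_freq,
    au_pair_freq = r$formation$au_pair_freq,
    mismatch_ratio = r$mismatch$aggregate_ratio)))
  rownames(trans_tab) <- NULL
  gcstar_tab <- do.call(rbind, lapply(res, function(r) data.frame(
    species = r$species,
    region = c("paired", "unpaired"),
    gc_current = c(r$trend_paired$gc_current, r$trend_unpaired$gc_current),
    gc_star = c(r$trend_paired$gc_star, r$trend_unpaired$gc_star),
    trend = c(r$trend_paired$trend, r$trend_unpaired$trend))))
  rownames(gcstar_tab) <- NULL

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(gc_table, "gc_table.tsv")
  wt(gc_table[, c("species", "n_alleles", "K")], "diversity_table.tsv")
  wt(correlations, "correlations.tsv")
  wt(model_tab, "model_selection.tsv")
  wt(trans_tab, "transformation_rates.tsv")
  wt(gcstar_tab, "gcstar_table.tsv")
  meta <- list(seed = config$seed, estimator = config$estimator,
               consensus_threshold = config$consensus_threshold,
               n_species_in = length(mats), n_species_analyzed = length(res),
               skipped = skipped,
               gc_species_mean = "unweighted mean of per-allele GC (copy counts ignored)",
               package_version = as.character(utils::packageVersion("its2gc")))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(gc_table = gc_table, correlations = correlations,
                 model_selection = model_tab, transformation = trans_tab,
                 gcstar = gcstar_tab, species = res, skipped = skipped,
                 out_dir = config$out_dir))
}
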