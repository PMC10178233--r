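# Equilibrium GC (GC*), base-pair formation rates into GC-type vs AU-type
# pairs, and mismatch-conversion bias — the GC-evolution statistics at the
# heart of the gBGC analysis.

GC_TYPE <- c("GC", "CG")
AU_TYPE <- c("AU", "UA")
MISMATCHES <- list("A:G" = c("AG", "GA"), "A:C" = c("AC", "CA"),
                   "C:U" = c("CU", "UC"), "G:U" = c("GU", "UG"))

#' Equilibrium GC content of a nucleotide model
#'
#' GC* = 100 * u / (u + v), where u is the stationary-weighted total rate
#' of AT-to-GC substitution per AT base and v the GC-to-AT rate per GC
#' base. Under a constant substitution process the sequence converges to
#' this GC content.
#'
#' @param nuc_model a `nuc_model`.
#' @return GC*, in percent.
#' @export
gc_star_nucleotide <- function(nuc_model) {
  pi <- nuc_model$freqs; Q <- nuc_model$Q
  at <- c("A", "U"); gc <- c("G", "C")
  pat <- sum(pi[at]); pgc <- sum(pi[gc])
  if (pat <= 0 || pgc <= 0) stop("degenerate frequencies: AT or GC mass is zero")
  u <- sum(pi[at] * rowSums(Q[at, gc, drop = FALSE])) / pat
  v <- sum(pi[gc] * rowSums(Q[gc, at, drop = FALSE])) / pgc
  100 * u / (u + v)
}

#' Equilibrium GC content of a base-pair model
#'
#' Solves pi Q = 0 and returns 100 * sum(pi_d * g(d)) with g(d) the
#' fraction of G/C nucleotides in doublet d (for the 7-state space, MM and
#' wobble states count 1/2).
#'
#' @param pair_model a `pair_model` (or any list with an irreducible `Q`).
#' @return GC*, in percent.
#' @export
gc_star_pair <- function(pair_model) {
  pi <- if (isTRUE(pair_model$reversible)) pair_model$freqs
  else stationary_distribution(pair_model$Q)
  g <- gc_weight(names(pi))
  100 * sum(pi * g)
}

gc_weight <- function(states) {
  vapply(states, function(s) {
    if (s == "MM") return(0.5)
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
}

#' Classify the GC evolutionary trend of a region
#'
#' @param gc_current current GC, percent.
#' @param gc_star equilibrium GC, percent.
#' @param tolerance band (percentage points) within which the trend is
#'   called stable; default 0.1.
#' @param region optional label ("paired"/"unpaired").
#' @return List of class `gc_star_estimate`: `region`, `gc_current`,
#'   `gc_star`, `trend` in {"increasing", "decreasing", "stable"}.
#' @export
gc_trend <- function(gc_current, gc_star, tolerance = 0.1, region = NA_character_) {
  stopifnot(gc_current >= 0, gc_current <= 100, gc_star >= 0, gc_star <= 100)
  d <- gc_star - gc_current
  trend <- if (d > tolerance) "increasing" else if (d < -tolerance) "decreasing" else "stable"
  structure(list(region = region, gc_current = gc_current, gc_star = gc_star,
                 trend = trend, tolerance = tolerance),
            class = "gc_star_estimate")
}

single_change_sources <- function(target) {
  # all doublets one substitution away from `target`
  tg <- doublet_split(target)
  out <- character(0)
  for (pos in 1:2) for (b in setdiff(NUC, tg[pos])) {
    d <- tg; d[pos] <- b
    out <- c(out, paste0(d[1], d[2]))
  }
  out
}

#' Formation rates into GC-type versus AU-type base pairs
#'
#' Enumerates the six single-change routes into each target pair (GC, CG,
#' AU, UA), reads the corresponding rate-matrix entries (relative rates; the
#' model should be normalized to unit mean rate), and totals them by
#' destination type. Stationary frequencies of GC-type and AU-type pairs
#' are reported alongside for the frequency-mutability view. A 7-state
#' model is summarized on its lumped graph (MM and the wobble state are the
#' intermediate sources).
#'
#' @param pair_model a `pair_model`.
#' @return List of class `transformation_summary`: `routes` (data frame
#'   source, target, rate, destination_type), `total_to_GC`, `total_to_AU`,
#'   `ratio`, `gc_pair_freq`, `au_pair_freq`.
#' @export
formation_rates <- function(pair_model) {
  Q <- pair_model$Q
  pi <- pair_model$freqs
  if (pair_model$state_space == "16") {
    routes <- do.call(rbind, lapply(c(GC_TYPE, AU_TYPE), function(tg) {
      src <- single_change_sources(tg)
      data.frame(source = src, target = tg, rate = Q[src, tg],
                 destination_type = if (tg %in% GC_TYPE) "GC" else "AU",
                 row.names = NULL)
    }))
  } else {
    edges <- rbind(c("GU", "GC"), c("MM", "GC"), c("UG", "CG"), c("MM", "CG"),
                   c("GU", "AU"), c("MM", "AU"), c("UG", "UA"), c("MM", "UA"))
    routes <- data.frame(source = edges[, 1], target = edges[, 2],
                         rate = Q[edges], row.names = NULL)
    routes$destination_type <- ifelse(routes$target %in% GC_TYPE, "GC", "AU")
  }
  tot_gc <- sum(routes$rate[routes$destination_type == "GC"])
  tot_au <- sum(routes$rate[routes$destination_type == "AU"])
  structure(list(routes = routes,
                 total_to_GC = tot_gc, total_to_AU = tot_au,
                 ratio = tot_gc / tot_au,
                 gc_pair_freq = sum(pi[GC_TYPE]),
                 au_pair_freq = sum(pi[AU_TYPE])),
            class = "transformation_summary")
}

#' Mismatch-conversion bias
#'
#' For each of the four repairable mismatches (A:G, A:C, C:U, G:U), the
#' one-side repair can restore either a GC-type or an AU-type Watson-Crick
#' pair; the per-mismatch rate toward each destination is the mean of the
#' two ordered-doublet rate entries. The aggregate ratio summarizes the
#' conversion bias toward GC across all eight routes.
#'
#' @param pair_model a 16-state `pair_model` (the 7-state space lumps
#'   mismatch identities and is rejected).
#' @return List of class `mismatch_conversion`: `table` (mismatch,
#'   rate_to_GC_type, rate_to_AU_type), `aggregate_ratio`.
#' @export
mismatch_conversion <- function(pair_model) {
  if (pair_model$state_space != "16")
    stop("mismatch_conversion requires the 16-state model: ",
         "the 7-state space lumps mismatch identities into MM")
  Q <- pair_model$Q
  dest <- list(
    "A:G" = list(GC = rbind(c("AG", "CG"), c("GA", "GC")),
                 AU = rbind(c("AG", "AU"), c("GA", "UA"))),
    "A:C" = list(GC = rbind(c("AC", "GC"), c("CA", "CG")),
                 AU = rbind(c("AC", "AU"), c("CA", "UA"))),
    "C:U" = list(GC = rbind(c("CU", "CG"), c("UC", "GC")),
                 AU = rbind(c("CU", "AU"), c("UC", "UA"))),
    "G:U" = list(GC = rbind(c("GU", "GC"), c("UG", "CG")),
                 AU = rbind(c("GU", "AU"), c("UG", "UA"))))
  tab <- do.call(rbind, lapply(names(dest), function(mm) {
    data.frame(mismatch = mm,
               rate_to_GC_type = mean(Q[dest[[mm]]$GC]),
               rate_to_AU_type = mean(Q[dest[[mm]]$AU]),
               row.names = NULL)
  }))
  structure(list(table = tab,
                 aggregate_ratio = sum(tab$rate_to_GC_type) /
                   sum(tab$rate_to_AU_type)),
            class = "mismatch_conversion")
}

#' @export
print.transformation_summary <- function(x, ...) {
  cat(sprintf("<transformation_summary> to GC: %.4f, to AU: %.4f, ratio = %.3f (pi_GC = %.3f, pi_AU = %.3f)\n",
              x$total_to_GC, x$total_to_AU, x$ratio,
              x$gc_pair_freq, x$au_pair_freq))
  invisible(x)
}

#' @export
print.mismatch_conversion <- function(x, ...) {
  print(x$table)
  cat(sprintf("aggregate GC/AU conversion ratio: %.3f\n", x$aggregate_ratio))
  invisible(x)
}
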