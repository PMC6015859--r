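## Full time-window analysis: model selection at a reference cut-off,
## MCMC re-runs across a cut-off grid on a sample of trees, and pooled
## rate-through-time summaries; plus the region / threshold / clade
## sensitivity helpers.

#' Analysis configuration
#'
#' @param cutoffs cut-off grid in Ma (default 25, 20, 15, 10, 5, 2.6, 1,
#'   0.5, spanning the Neogene and Quaternary).
#' @param selection_cutoff breakpoint (Ma) used for the one-off model
#'   selection (default 2.6, the Quaternary onset); the selected constraint
#'   structure is then held fixed across the grid.
#' @param n_trees number of trees sampled for the MCMC stage (default 100).
#' @param generations MCMC generations per tree (default 10000).
#' @param burn_in burn-in fraction discarded when pooling (default 0.1).
#' @param warmup slice-sampler tuning generations (default 500).
#' @param f per-state sampling fractions `c(f0, f1)`.
#' @param threshold fruit-length threshold (cm) when states are derived
#'   from lengths.
#' @param region optional region label to subset to before analysis.
#' @param region_totals optional named list `region -> c(total0, total1)`
#'   of true per-state species totals, used to recompute sampling
#'   fractions after subsetting.
#' @param exclude_clades clade tags to prune before analysis.
#' @param models candidate model set (default [enumerate_models()]).
#' @param alpha LRT level for the stepwise search.
#' @param starts optimizer starts per fit.
#' @param seed master seed; all tree subsampling and per-chain seeds
#'   derive from it by counter.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(cutoffs = c(25, 20, 15, 10, 5, 2.6, 1, 0.5),
                            selection_cutoff = 2.6, n_trees = 100,
                            generations = 10000, burn_in = 0.1,
                            warmup = 500, f = c(1, 1), threshold = 4,
                            region = NULL, region_totals = NULL,
                            exclude_clades = character(0),
                            models = enumerate_models(), alpha = 0.05,
                            starts = 3, seed = 1) {
  stopifnot(threshold > 0, all(cutoffs > 0), n_trees >= 1,
            generations >= 1, burn_in >= 0, burn_in < 1)
  structure(list(cutoffs = sort(cutoffs, decreasing = TRUE),
                 selection_cutoff = selection_cutoff, n_trees = n_trees,
                 generations = generations, burn_in = burn_in,
                 warmup = warmup, f = f, threshold = threshold,
                 region = region, region_totals = region_totals,
                 exclude_clades = exclude_clades, models = models,
                 alpha = alpha, starts = starts, seed = seed),
            class = "analysis_config")
}

.as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) list(trees)
  else if (inherits(trees, "multiPhylo") || is.list(trees)) unclass(trees)
  else stop("expected a phylo, multiPhylo or list of trees")
}

#' Subset trees and traits to one region
#'
#' Prunes every tree to the tips assigned to `region` and recomputes the
#' per-state sampling fractions from the supplied regional species totals.
#'
#' @param trees a `phylo`, `multiPhylo` or list of trees.
#' @param traits a `trait_dataset` with a `region` column.
#' @param region region label to keep.
#' @param totals optional `c(total0, total1)` true species counts for the
#'   region; when given, `f_i = retained_i / total_i`.
#' @param f fall-back sampling fractions when `totals` is `NULL`.
#' @return list with `trees`, `traits` and `f`.
#' @export
subset_by_region <- function(trees, traits, region, totals = NULL,
                             f = c(1, 1)) {
  if (!"region" %in% names(traits)) stop("trait table has no region column")
  keep <- traits$tip[!is.na(traits$region) & traits$region == region]
  if (!length(keep)) stop("no tips in region '", region, "'")
  tl <- .as_tree_list(trees)
  pruned <- lapply(tl, function(tr) {
    drop <- setdiff(tr$tip.label, keep)
    if (length(drop) == ape::Ntip(tr)) stop("region empty on a tree")
    if (length(drop)) ape::drop.tip(tr, drop) else tr
  })
  tra <- traits[traits$tip %in% keep, , drop = FALSE]
  class(tra) <- class(traits)
  if (!is.null(totals)) {
    n1 <- sum(tra$state == 1, na.rm = TRUE)
    n0 <- sum(tra$state == 0, na.rm = TRUE)
    f <- c(min(n0 / totals[1], 1), min(n1 / totals[2], 1))
  }
  list(trees = if (length(pruned) == 1) pruned[[1]]
       else structure(pruned, class = "multiPhylo"),
       traits = tra, f = f)
}

#' Re-threshold fruit lengths at several cut-off values
#'
#' @param traits a `trait_dataset` carrying `length_cm`.
#' @param thresholds cm values (e.g. `c(3.5, 4, 4.5)`).
#' @return named list of `trait_dataset`s, one per threshold; state-1 sets
#'   are nested across decreasing thresholds.
#' @export
sensitivity_threshold <- function(traits, thresholds) {
  if (!"length_cm" %in% names(traits))
    stop("trait table has no length_cm column")
  out <- lapply(thresholds, function(th) {
    st <- classify_fruit_lengths(setNames(traits$length_cm, traits$tip), th)
    tra <- traits
    tra$state <- unname(st)
    tra
  })
  names(out) <- format(thresholds)
  out
}

#' Exclude a tagged clade from trees and traits
#'
#' @param trees a `phylo`, `multiPhylo` or list of trees.
#' @param traits a `trait_dataset` with a `clade` column.
#' @param tag clade tag to remove (must match at least one tip).
#' @return list with `trees`, `traits` and `n_removed`.
#' @export
exclude_clade <- function(trees, traits, tag) {
  if (!"clade" %in% names(traits)) stop("trait table has no clade column")
  drop <- traits$tip[!is.na(traits$clade) & traits$clade == tag]
  if (!length(drop)) stop("clade tag '", tag, "' matches no tips")
  tl <- .as_tree_list(trees)
  pruned <- lapply(tl, function(tr) ape::drop.tip(tr, drop))
  tra <- traits[!traits$tip %in% drop, , drop = FALSE]
  class(tra) <- class(traits)
  list(trees = if (length(pruned) == 1) pruned[[1]]
       else structure(pruned, class = "multiPhylo"),
       traits = tra, n_removed = length(drop))
}

#' Run the full time-window diversification analysis
#'
#' (1) Backward stepwise model selection at the reference cut-off on the
#' first tree; (2) for every cut-off in the grid, MCMC under the selected
#' constraint structure with the breakpoint moved to that cut-off, on a
#' random sample of trees; (3) pooled recent-epoch rate quantiles per
#' cut-off, assembled into a rate-through-time table.
#'
#' @param trees a `phylo`, `multiPhylo` or list of posterior tree samples.
#' @param traits a `trait_dataset`; states must be complete on retained
#'   tips.
#' @param config an [analysis_config()].
#' @param verbose print stage progress.
#' @return a list of class `timeslice_analysis`: `rtt` (rate-through-time
#'   data frame: cutoff x rate x epoch with quantile columns), `selection`
#'   (model-selection report), `spec` (selected model), `chains`, and the
#'   `config`.
#' @export
run_timeslice_analysis <- function(trees, traits, config = analysis_config(),
                                   verbose = FALSE) {
  tl <- .as_tree_list(trees)
  f <- config$f
  if (length(config$exclude_clades)) {
    for (tag in config$exclude_clades) {
      ex <- exclude_clade(tl, traits, tag)
      tl <- .as_tree_list(ex$trees); traits <- ex$traits
    }
  }
  if (!is.null(config$region)) {
    sb <- subset_by_region(tl, traits, config$region,
                           totals = config$region_totals[[config$region]],
                           f = f)
    tl <- .as_tree_list(sb$trees); traits <- sb$traits; f <- sb$f
  }
  hmin <- min(vapply(tl, tree_height, 0))
  cutoffs <- config$cutoffs[config$cutoffs < hmin]
  if (!length(cutoffs)) stop("no cut-off lies inside the trees' depth")

  if (verbose) message("stage 1: stepwise model selection at t = ",
                       config$selection_cutoff, " Ma")
  sel <- stepwise_search(tl[[1]], traits, config$selection_cutoff,
                         models = config$models, f = f,
                         alpha = config$alpha, starts = config$starts,
                         seed = config$seed)
  spec <- sel$spec

  idx <- with_seed(config$seed,
                   sample.int(length(tl), min(config$n_trees, length(tl))))
  chains <- list()
  rtt <- list()
  counter <- 0L
  for (co in cutoffs) {
    co_chains <- list()
    for (i in idx) {
      counter <- counter + 1L
      sd_i <- (config$seed * 10000L + counter) %% .Machine$integer.max
      fit_i <- tryCatch(
        fit_mle(tl[[i]], traits, spec, co, f = f, starts = config$starts,
                seed = sd_i),
        error = function(e) NULL)
      if (is.null(fit_i)) stop("MLE stage failed at cut-off ", co,
                               " on tree ", i)
      ch <- tryCatch(
        run_mcmc(tl[[i]], traits, spec, co, f = f,
                 generations = config$generations, seed = sd_i,
                 init = fit_i$par, warmup = config$warmup,
                 tree_id = as.character(i)),
        error = function(e) stop("MCMC failed at cut-off ", co,
                                 " on tree ", i, ": ", conditionMessage(e)))
      co_chains[[length(co_chains) + 1L]] <- ch
    }
    summ <- summarize_posterior(co_chains, burn_in = config$burn_in)
    recent <- summ[summ$epoch == "recent", , drop = FALSE]
    recent$cutoff <- co
    rtt[[length(rtt) + 1L]] <- recent
    chains[[format(co)]] <- co_chains
    if (verbose) message("cut-off ", co, " Ma done (", length(co_chains),
                         " chains)")
  }
  rtt <- do.call(rbind, rtt)
  rownames(rtt) <- NULL
  structure(list(rtt = rtt[, c("cutoff", setdiff(names(rtt), "cutoff"))],
                 selection = attr(sel, "report"),
                 selection_path = attr(sel, "path"), spec = spec,
                 chains = chains, f = f, config = config),
            class = "timeslice_analysis")
}

#' @export
print.timeslice_analysis <- function(x, ...) {
  cat("timeslice_analysis: model '", x$spec$name, "' over cut-offs ",
      paste(unique(x$rtt$cutoff), collapse = ", "), " Ma\n", sep = "")
  print(head(x$rtt, 12))
  invisible(x)
}
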