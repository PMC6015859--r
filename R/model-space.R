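## Constrained model space for two-epoch BiSSE fits.
##
## A model is a mapping from the 12 rate slots
##   {lambda0, lambda1, mu0, mu1, q01, q10} x {recent, old}
## onto shared free-parameter identifiers (optionally fixing some slots to
## constants).  k = number of distinct free identifiers.

SLOT_NAMES <- c(paste0(RATE_NAMES, ".recent"), paste0(RATE_NAMES, ".old"))

#' Constraint specification for a two-epoch model
#'
#' @param name human-readable model name (unique within a model set).
#' @param map named character vector over the 12 slots
#'   (`lambda0.recent`, ..., `q10.old`); values are free-parameter
#'   identifiers.  Slots listed in `fixed` are omitted from `map`.
#' @param fixed optional named numeric vector fixing slots to constants.
#' @return an object of class `constraint_spec` with element `k`.
#' @export
constraint_spec <- function(name, map, fixed = NULL) {
  fixed_slots <- names(fixed %||% numeric(0))
  free_slots <- setdiff(SLOT_NAMES, fixed_slots)
  if (!setequal(names(map), free_slots))
    stop("map must cover exactly the non-fixed slots; missing: ",
         paste(setdiff(free_slots, names(map)), collapse = ", "))
  map <- map[free_slots]
  k <- length(unique(map))
  if (k < 1 || length(free_slots) == 12 && (k < 3 || k > 12))
    stop("k must lie between 3 (all-shared) and 12 (fully free)")
  structure(list(name = name, map = map, fixed = fixed, k = k),
            class = "constraint_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.constraint_spec <- function(x, ...) {
  cat("constraint_spec '", x$name, "' (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Free-parameter identifiers of a model
#' @param spec a `constraint_spec`.
#' @return character vector of identifiers, in slot order.
#' @export
free_params <- function(spec) unique(unname(spec$map))

#' Expand a free-parameter vector into per-epoch rate matrices
#'
#' @param spec a `constraint_spec`.
#' @param par named numeric vector over `free_params(spec)`.
#' @param breakpoint the epoch boundary age (Ma).
#' @return a [time_slice_params()] with two epochs (recent, old).
#' @export
spec_to_params <- function(spec, par, breakpoint) {
  vals <- setNames(numeric(12), SLOT_NAMES)
  vals[names(spec$map)] <- par[spec$map]
  if (!is.null(spec$fixed)) vals[names(spec$fixed)] <- spec$fixed
  epochs <- rbind(vals[paste0(RATE_NAMES, ".recent")],
                  vals[paste0(RATE_NAMES, ".old")])
  colnames(epochs) <- RATE_NAMES
  time_slice_params(breakpoint, epochs)
}

## per-family slot patterns; family is "lambda" (slots lambda0/lambda1),
## "mu" (mu0/mu1) or "q" (q01/q10)
.family_slots <- function(family) {
  base <- switch(family, lambda = c("lambda0", "lambda1"),
                 mu = c("mu0", "mu1"), q = c("q01", "q10"))
  c(paste0(base, ".recent"), paste0(base, ".old"))
}

## pattern codes: "c" shared-constant, "s" state-dependent constant,
## "t" time-dependent shared, "st" state- and time-dependent,
## "s0"/"s1" a time shift in one state only
.family_pattern <- function(family, code) {
  sl <- .family_slots(family)  # s0.recent, s1.recent, s0.old, s1.old
  id <- switch(code,
    c  = rep(paste0(family), 4),
    s  = c(paste0(family, "0"), paste0(family, "1"))[c(1, 2, 1, 2)],
    t  = c(paste0(family, ".r"), paste0(family, ".r"),
           paste0(family, ".o"), paste0(family, ".o")),
    st = c(paste0(family, "0.r"), paste0(family, "1.r"),
           paste0(family, "0.o"), paste0(family, "1.o")),
    s0 = c(paste0(family, "0.r"), paste0(family, "1"),
           paste0(family, "0.o"), paste0(family, "1")),
    s1 = c(paste0(family, "0"), paste0(family, "1.r"),
           paste0(family, "0"), paste0(family, "1.o")),
    stop("unknown pattern code '", code, "'"))
  setNames(id, sl)
}

#' Build a model from per-family patterns
#'
#' Pattern codes: `"c"` shared and constant in time, `"s"` state-dependent,
#' `"t"` time-dependent (shared between states), `"st"` state- and
#' time-dependent, `"s0"`/`"s1"` time shift in one state only.
#'
#' @param lambda,mu,q pattern codes for the three rate families.
#' @return a [constraint_spec()] named `L:<code>_M:<code>_Q:<code>`.
#' @export
spec_from_patterns <- function(lambda = "c", mu = "c", q = "c") {
  map <- c(.family_pattern("lambda", lambda), .family_pattern("mu", mu),
           .family_pattern("q", q))
  map <- map[SLOT_NAMES]
  constraint_spec(paste0("L:", lambda, "_M:", mu, "_Q:", q), map)
}

#' Enumerate the canonical constrained model set
#'
#' Crosses, per rate family, the patterns shared/state-dependent x
#' constant/time-shifted, keeps the models with at most `max_k` free
#' parameters, and adds the fully free two-epoch model; with the defaults
#' this yields the canonical set of 43 uniquely named models.  The output
#' order is deterministic.  A user-supplied list of [constraint_spec()]s
#' can be substituted anywhere a model set is accepted.
#'
#' @param codes pattern codes crossed per family.
#' @param max_k retain crossed models with `k <= max_k`.
#' @param include_full append the fully free model (k = 12).
#' @return a named list of `constraint_spec`s.
#' @export
enumerate_models <- function(codes = c("c", "s", "t", "st"), max_k = 7,
                             include_full = TRUE) {
  out <- list()
  for (lc in codes) for (mc in codes) for (qc in codes) {
    sp <- spec_from_patterns(lc, mc, qc)
    if (sp$k <= max_k) out[[sp$name]] <- sp
  }
  if (include_full) {
    full <- spec_from_patterns("st", "st", "st")
    out[[full$name]] <- out[[full$name]] %||% full
  }
  out
}

#' Akaike information criterion
#' @param logL log-likelihood at the optimum.
#' @param k number of free parameters (>= 1).
#' @return `2k - 2 logL`.
#' @export
aic <- function(logL, k) {
  if (k < 1) stop("k must be >= 1")
  2 * k - 2 * logL
}

## partition of the 12 slots induced by a spec (fixed slots are singleton
## classes tagged with their value)
.slot_partition <- function(spec) {
  cls <- setNames(rep(NA_character_, 12), SLOT_NAMES)
  cls[names(spec$map)] <- paste0("free:", spec$map)
  if (!is.null(spec$fixed))
    cls[names(spec$fixed)] <- paste0("fixed:", spec$fixed)
  cls
}

#' Is one model nested within another?
#'
#' `nested` is a coarsening of `full`: every equality constraint of `full`
#' is also imposed by `nested`, and any slot fixed in `full` is fixed to
#' the same value in `nested`.
#'
#' @param nested,full `constraint_spec`s.
#' @return logical.
#' @export
is_nested <- function(nested, full) {
  pn <- .slot_partition(nested); pf <- .slot_partition(full)
  ## every class of `full` must fall inside a single class of `nested`
  for (cl in unique(pf)) {
    members <- SLOT_NAMES[pf == cl]
    if (length(unique(pn[members])) > 1) return(FALSE)
  }
  ## slots fixed in full must be identically fixed in nested
  if (!is.null(full$fixed)) {
    fn <- nested$fixed %||% numeric(0)
    for (sl in names(full$fixed)) {
      if (!sl %in% names(fn) || fn[[sl]] != full$fixed[[sl]]) return(FALSE)
    }
  }
  TRUE
}

#' Likelihood-ratio test between structurally nested fits
#'
#' @param nested,full `fit_result`s (see [fit_mle()]) of models fit to the
#'   same data, with `nested$spec` a coarsening of `full$spec`.
#' @param tol slack allowed on `logL_full >= logL_nested` before declaring
#'   an optimizer failure.
#' @return list with `statistic`, `df` and `p`.
#' @export
lrt <- function(nested, full, tol = 1e-4) {
  if (!is_nested(nested$spec, full$spec))
    stop("models are not nested ('", nested$spec$name, "' vs '",
         full$spec$name, "')")
  df <- full$k - nested$k
  if (df <= 0) stop("full model must have more free parameters")
  if (full$logL < nested$logL - tol)
    stop("full-model logL below nested logL beyond tolerance; refit with ",
         "more starts")
  stat <- max(0, 2 * (full$logL - nested$logL))
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Select the preferred model by the delta-AIC rule
#'
#' Among converged fits within 2 AIC units of the minimum AIC, returns the
#' one with the fewest free parameters; ties on k are broken by lower AIC,
#' then by lexicographic model name.
#'
#' @param fits list of `fit_result`s.
#' @param delta AIC window (default 2).
#' @return the selected `fit_result`, with attribute `"report"` holding a
#'   data frame of all candidates (name, k, logL, AIC, dAIC, selected).
#' @export
stepwise_select <- function(fits, delta = 2) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("no converged fits to select from")
  tab <- data.frame(
    name = vapply(fits, function(f) f$spec$name, ""),
    k = vapply(fits, function(f) f$k, 0),
    logL = vapply(fits, function(f) f$logL, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  cand <- which(tab$dAIC < delta)
  ord <- cand[order(tab$k[cand], tab$AIC[cand], tab$name[cand])]
  sel <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == sel
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  out <- fits[[sel]]
  attr(out, "report") <- tab
  out
}

#' Backward stepwise model search
#'
#' Starts from the fully free model, repeatedly tests the immediate
#' coarsenings available in the model set by likelihood-ratio test, accepts
#' the coarsening with the highest p-value above `alpha`, and stops when no
#' coarsening is acceptable.  The final choice over everything fitted along
#' the way is arbitrated by the delta-AIC < 2 / fewest-parameters rule of
#' [stepwise_select()].
#'
#' @param tree,traits,f,cond data and conventions as in [tree_loglik()].
#' @param breakpoint epoch boundary age (Ma) for all candidate models.
#' @param models model set (default [enumerate_models()]).
#' @param alpha LRT significance level for accepting a coarsening.
#' @param starts,seed optimizer settings passed to [fit_mle()].
#' @param verbose print progress.
#' @return as [stepwise_select()], with attribute `"path"` recording the
#'   accepted steps.
#' @export
stepwise_search <- function(tree, traits, breakpoint,
                            models = enumerate_models(), f = c(1, 1),
                            cond = lik_condition(), alpha = 0.05,
                            starts = 3, seed = 1, verbose = FALSE) {
  full_name <- "L:st_M:st_Q:st"
  if (!full_name %in% names(models))
    models[[full_name]] <- spec_from_patterns("st", "st", "st")
  fits <- list()
  do_fit <- function(sp) {
    if (is.null(fits[[sp$name]]))
      fits[[sp$name]] <<- fit_mle(tree, traits, sp, breakpoint, f = f,
                                  cond = cond, starts = starts, seed = seed)
    fits[[sp$name]]
  }
  current <- models[[full_name]]
  do_fit(current)
  path <- character(0)
  repeat {
    nested_specs <- Filter(function(sp) sp$k < current$k &&
                             is_nested(sp, current), models)
    if (!length(nested_specs)) break
    kmax <- max(vapply(nested_specs, function(s) s$k, 0))
    cand <- Filter(function(s) s$k == kmax, nested_specs)
    ps <- vapply(cand, function(sp) {
      ft <- do_fit(sp)
      if (!isTRUE(ft$converged)) return(-1)
      lrt(ft, fits[[current$name]])$p
    }, 0)
    best <- which.max(ps)
    if (ps[best] <= alpha) break
    current <- cand[[best]]
    path <- c(path, sprintf("%s (p = %.4f)", current$name, ps[best]))
    if (verbose) message("accepted coarsening: ", tail(path, 1))
  }
  out <- stepwise_select(fits)
  attr(out, "path") <- path
  out
}
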