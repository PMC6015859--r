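#' @useDynLib epochsse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize pchisq qgamma quantile rbinom rexp rlnorm
#'   runif setNames rnorm cor.test dexp punif ecdf
#' @importFrom utils head tail read.delim write.table
NULL

## Ages are always measured in Ma before present: tips sit at age 0, the
## root at the tree height.  Every epoch-slicing convention in the package
## derives from this ("2.6 Ma" is an age; the most recent epoch is [0, 2.6)).

#' Node ages of an ultrametric tree
#'
#' @param tree an object of class `phylo` (rooted, with branch lengths).
#' @return numeric vector of ages (Ma before present) indexed by node id
#'   (tips `1..ntip`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ape::Ntip(tree))])
  age <- height - depth
  age[seq_len(ape::Ntip(tree))] <- 0
  age
}

#' Tree height (root age)
#' @param tree a `phylo` object.
#' @return root age in Ma.
#' @export
tree_height <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))])
}

#' Validate a tree for time-sliced SSE analysis
#'
#' Checks that the tree is rooted and binary, that every edge has a
#' non-negative branch length, that tip labels are unique, and that the tree
#' is ultrametric to a relative tolerance of the tree height.  Tip ages are
#' then snapped to exactly zero (posterior tree samples carry rounding
#' noise on terminal branches).
#'
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @return the validated tree, with terminal branches adjusted so tips sit
#'   at age 0 exactly.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("expected a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch length on an edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("polytomies are not supported; resolve the tree first")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels: ",
    paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  if (height <= 0) stop("tree height must be positive")
  tip_age <- height - depth[seq_len(ntip)]
  bad <- which(abs(tip_age) > tol * height)
  if (length(bad)) {
    stop("tree is not ultrametric: tip '", tree$tip.label[bad[1]],
         "' has age ", format(tip_age[bad[1]]), " (tolerance ",
         format(tol * height), ")")
  }
  ## snap tips to age 0 by absorbing residuals into terminal branches
  term <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + tip_age
  tree
}

#' Read trees from newick text
#'
#' Reads one or more newick trees (one per line, as in a posterior tree
#' sample file) and validates each for use with the time-sliced likelihood.
#'
#' @param x a newick string, or the path of a file containing newick trees
#'   one per line.
#' @param tol relative ultrametricity tolerance passed to [validate_tree()].
#' @return a single `phylo` if one tree was read, otherwise a `multiPhylo`
#'   list.
#' @export
read_newick <- function(x, tol = 1e-6) {
  if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    lines <- readLines(x)
  } else {
    lines <- unlist(strsplit(paste(x, collapse = "\n"), "\n"))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no newick trees found")
  trees <- lapply(seq_along(lines), function(i) {
    tr <- tryCatch(ape::read.tree(text = lines[[i]]),
                   error = function(e) NULL)
    if (is.null(tr)) {
      ## locate the first structurally broken position for the error message
      pos <- newick_error_position(lines[[i]])
      stop("malformed newick on line ", i, " near character ", pos)
    }
    validate_tree(tr, tol = tol)
  })
  if (length(trees) == 1) trees[[1]] else structure(trees, class = "multiPhylo")
}

## best-effort position of the first parenthesis imbalance / illegal char
newick_error_position <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) return(i)
  }
  nchar(s)
}

#' Write trees as newick text
#' @param tree a `phylo` or `multiPhylo`.
#' @param file optional path; if `NULL` the newick string(s) are returned.
#' @param digits significant digits for branch lengths.
#' @return newick string(s), invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Threshold fruit lengths into the binary megafaunal state
#'
#' State 1 ("megafaunal") means fruit length greater than or equal to the
#' threshold; the boundary is inclusive (a 4.0 cm fruit at a 4 cm threshold
#' is megafaunal).
#'
#' @param lengths named numeric vector of fruit lengths (cm), names are tip
#'   labels.  `NA` propagates to a missing state.
#' @param threshold positive threshold in cm (default 4).
#' @return named integer vector of states (0 small, 1 megafaunal, NA
#'   missing).
#' @export
classify_fruit_lengths <- function(lengths, threshold = 4) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a positive scalar (cm)")
  if (any(!is.na(lengths) & lengths <= 0))
    stop("fruit lengths must be positive")
  out <- ifelse(is.na(lengths), NA_integer_, as.integer(lengths >= threshold))
  names(out) <- names(lengths)
  out
}

#' Trait dataset constructor
#'
#' A trait dataset maps tips to a binary state (0 small-fruited, 1
#' megafaunal-fruited), optionally carrying the underlying fruit length
#' (cm), a region label and a clade tag.  Missing states are `NA`.
#'
#' @param tip character vector of tip labels.
#' @param state integer vector in \{0, 1, NA\}.
#' @param length_cm optional positive fruit lengths.
#' @param region optional region labels (e.g. "NW"/"OW").
#' @param clade optional clade tags.
#' @return a `data.frame` of class `trait_dataset`.
#' @export
trait_dataset <- function(tip, state, length_cm = NULL, region = NULL,
                          clade = NULL) {
  tip <- as.character(tip)
  state <- as.integer(state)
  if (anyDuplicated(tip)) stop("duplicate tip labels in trait table")
  if (any(!state %in% c(0L, 1L) & !is.na(state)))
    stop("states must be 0, 1 or NA")
  df <- data.frame(tip = tip, state = state, stringsAsFactors = FALSE)
  if (!is.null(length_cm)) {
    if (any(!is.na(length_cm) & length_cm <= 0))
      stop("fruit lengths must be positive")
    df$length_cm <- as.numeric(length_cm)
  }
  if (!is.null(region)) df$region <- as.character(region)
  if (!is.null(clade)) df$clade <- as.character(clade)
  class(df) <- c("trait_dataset", "data.frame")
  df
}

#' Read a delimited trait table
#'
#' Expects a header and at least columns `tip` and `state` (or `length_cm`,
#' from which states are derived at the given threshold).  "NA" encodes
#' missing values.  Optional columns: `length_cm`, `region`, `clade`.
#'
#' @param file path to a TSV/CSV file.
#' @param sep field separator (default tab; use "," for CSV).
#' @param threshold cm threshold used when states must be derived from
#'   lengths.
#' @return a `trait_dataset`.
#' @export
read_trait_table <- function(file, sep = "\t", threshold = 4) {
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  if (!"tip" %in% names(df)) stop("trait table must have a 'tip' column")
  if (!"state" %in% names(df)) {
    if (!"length_cm" %in% names(df))
      stop("trait table needs a 'state' or 'length_cm' column")
    df$state <- classify_fruit_lengths(
      setNames(df$length_cm, df$tip), threshold)
  }
  trait_dataset(df$tip, df$state, length_cm = df$length_cm,
                region = df$region, clade = df$clade)
}

#' Write a trait table
#' @param traits a `trait_dataset`.
#' @param file output path.
#' @param sep field separator.
#' @export
write_trait_table <- function(traits, file, sep = "\t") {
  write.table(as.data.frame(traits), file, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Check a trait dataset against a tree
#'
#' @param traits a `trait_dataset`.
#' @param tree a `phylo`.
#' @param require_complete if `TRUE`, every tree tip must have a non-missing
#'   state.
#' @return invisibly, the states aligned to `tree$tip.label`.
#' @export
align_traits <- function(traits, tree, require_complete = TRUE) {
  idx <- match(tree$tip.label, traits$tip)
  if (anyNA(idx))
    stop("tips missing from trait table: ",
         paste(head(tree$tip.label[is.na(idx)], 5), collapse = ", "))
  st <- traits$state[idx]
  if (require_complete && anyNA(st))
    stop("missing tip states for: ",
         paste(head(tree$tip.label[is.na(st)], 5), collapse = ", "),
         "; prune these tips or impute states before fitting")
  setNames(st, tree$tip.label)
}

#' Epoch index of an age
#'
#' Epoch 0 is the most recent interval `[0, b1)`; an age exactly at a
#' breakpoint belongs to the older epoch (deterministic tie-break).
#'
#' @param age numeric ages (Ma).
#' @param breakpoints strictly increasing breakpoint ages (Ma).
#' @return integer epoch indices (0-based).
#' @export
epoch_index <- function(age, breakpoints) {
  vapply(age, function(a) sum(breakpoints <= a), integer(1))
}

#' Partition branches into epoch segments
#'
#' Splits every edge of an ultrametric tree at the given breakpoint ages.
#' Segments exactly partition each edge; the per-edge segment lengths sum
#' to the branch length.
#'
#' @param tree a validated `phylo`.
#' @param breakpoints strictly increasing ages within `(0, root age)`.
#' @return a `data.frame` with columns `parent`, `child`, `start_age`
#'   (younger end), `end_age` (older end), `epoch`.
#' @export
branch_segments <- function(tree, breakpoints) {
  h <- tree_height(tree)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("breakpoints must be strictly increasing")
    if (any(breakpoints <= 0 | breakpoints >= h))
      stop("breakpoints must lie strictly between 0 and the root age (",
           format(h), ")")
  }
  age <- node_ages(tree)
  out <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    a0 <- age[ch]; a1 <- age[par]
    cuts <- breakpoints[breakpoints > a0 & breakpoints < a1]
    bounds <- c(a0, cuts, a1)
    k <- length(bounds) - 1
    out[[e]] <- data.frame(
      parent = rep(par, k), child = rep(ch, k),
      start_age = bounds[-length(bounds)], end_age = bounds[-1],
      epoch = epoch_index(bounds[-length(bounds)], breakpoints))
  }
  do.call(rbind, out)
}
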