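#' Read a set of phylogenies from a Newick file
#'
#' Reads one or more rooted trees (one per line or a multi-tree Newick
#' file) and validates that all trees carry an identical tip label set,
#' as expected for samples from a single posterior tree distribution.
#'
#' @param path Path to a Newick file.
#' @return An object of class \code{multiPhylo} (length >= 1); single
#'   trees are promoted to a one-tree set.
#' @export
read_tree_set <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("Newick parse error in '", path,
                                             "': ", conditionMessage(e)))
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("no trees found in ", path)
  for (i in seq_along(trees)) {
    if (!ape::is.rooted(trees[[i]]))
      stop("tree ", i, " is unrooted; rooted trees are required")
    if (anyDuplicated(trees[[i]]$tip.label))
      stop("tree ", i, " has duplicated tip labels")
    if (!is.null(trees[[i]]$edge.length) && any(trees[[i]]$edge.length < 0))
      stop("tree ", i, " has negative branch lengths")
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tip set of tree ", i, " differs from tree 1")
  }
  trees
}

#' Root-to-tip height of an ultrametric tree
#'
#' @param tree A \code{phylo} object.
#' @return Maximum root-to-tip distance.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Rescale a tree to unit root-to-tip height
#'
#' Rates estimated on a unit-height tree are later divided by the
#' original height (in MY) to recover rates per million years. The
#' original height is stored in the \code{height_my} attribute.
#'
#' @param tree An ultrametric \code{phylo} object.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return The rescaled tree with attribute \code{height_my}.
#' @export
scale_to_unit_height <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  if (h <= 0) stop("tree has zero height")
  if (max(abs(depths - h)) / h > tol)
    stop("tree is not ultrametric within tolerance; per-MY rates undefined")
  tree$edge.length <- tree$edge.length / h
  attr(tree, "height_my") <- h
  tree
}

# canonical taxon labels: runs of whitespace/underscores -> one underscore
normalize_label <- function(x) {
  x <- gsub("[[:space:]_]+", "_", trimws(x))
  x
}

#' Read a species trait table
#'
#' Expects delimited text (comma or tab, auto-detected) with a header
#' containing at least \code{species}, \code{haploid_n} and a binary
#' state column (default \code{state}). The first factor level of the
#' binary column is treated as the "small" hyperstate; a column with
#' levels \code{small}/\code{large} is ordered that way regardless of
#' alphabetical order.
#'
#' @param path Path to the table.
#' @param state_col Name of the binary trait column.
#' @return A data frame with columns \code{species}, \code{haploid_n},
#'   \code{binary_state} (two-level factor).
#' @export
read_trait_table <- function(path, state_col = "state") {
  if (!file.exists(path)) stop("trait file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("species", "haploid_n", state_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  trait_table(df$species, df$haploid_n, df[[state_col]])
}

#' Construct and validate a trait table
#'
#' @param species Character vector of species labels.
#' @param haploid_n Integer haploid chromosome counts (>= 1).
#' @param state Binary hyperstate; character or factor with two levels.
#' @return Validated trait data frame.
#' @export
trait_table <- function(species, haploid_n, state) {
  species <- normalize_label(as.character(species))
  if (anyDuplicated(species))
    stop("duplicate species in trait table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  haploid_n <- as.integer(haploid_n)
  if (any(is.na(haploid_n)) || any(haploid_n < 1))
    stop("haploid_n must be integers >= 1")
  if (!is.factor(state)) {
    vals <- unique(as.character(state))
    if (all(vals %in% c("small", "large"))) {
      state <- factor(as.character(state), levels = c("small", "large"))
    } else {
      state <- factor(as.character(state), levels = sort(vals))
    }
  } else if (all(levels(state) %in% c("small", "large"))) {
    state <- factor(as.character(state), levels = c("small", "large"))
  }
  if (nlevels(state) != 2L)
    stop("binary_state must have exactly two levels, got ",
         nlevels(state))
  data.frame(species = species, haploid_n = haploid_n,
             binary_state = state, stringsAsFactors = FALSE)
}

#' Match trees and traits and prune both to their shared species
#'
#' Tip labels and trait species are matched exactly after
#' whitespace/underscore normalization. Names present on only one side
#' are dropped (reported via \code{message}).
#'
#' @param trees A \code{multiPhylo} set (or single \code{phylo}).
#' @param traits A trait table from \code{\link{trait_table}}.
#' @return List with elements \code{trees} (pruned \code{multiPhylo})
#'   and \code{traits} (subset, ordered to the first tree's tip order).
#' @export
match_and_prune <- function(trees, traits) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  for (i in seq_along(trees))
    trees[[i]]$tip.label <- normalize_label(trees[[i]]$tip.label)
  tips <- trees[[1]]$tip.label
  keep <- intersect(tips, traits$species)
  if (length(keep) == 0L) stop("no species shared between trees and traits")
  if (length(keep) < 4L)
    stop("only ", length(keep), " shared species; need at least 4")
  drop_tips <- setdiff(tips, keep)
  drop_traits <- setdiff(traits$species, keep)
  if (length(drop_tips))
    message("dropping ", length(drop_tips), " tree tips without trait data")
  if (length(drop_traits))
    message("dropping ", length(drop_traits), " trait rows absent from trees")
  out <- trees
  for (i in seq_along(trees)) {
    if (length(drop_tips)) {
      out[[i]] <- ape::drop.tip(trees[[i]], drop_tips)
    } else {
      out[[i]] <- trees[[i]]
    }
  }
  class(out) <- "multiPhylo"
  traits <- traits[match(out[[1]]$tip.label, traits$species), , drop = FALSE]
  rownames(traits) <- NULL
  list(trees = out, traits = traits)
}

#' Prune a named set of taxa (e.g. one family) from a tree set
#'
#' @param trees A \code{multiPhylo} set (or single \code{phylo}).
#' @param drop Character vector of tip labels to remove.
#' @return Pruned \code{multiPhylo}; branch lengths of retained paths
#'   are preserved additively.
#' @export
prune_taxa <- function(trees, drop) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  drop <- normalize_label(drop)
  out <- trees
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tr$tip.label <- normalize_label(tr$tip.label)
    hit <- intersect(tr$tip.label, drop)
    if (length(hit) == 0) { out[[i]] <- tr; next }
    if (length(setdiff(tr$tip.label, hit)) < 3)
      stop("pruning would leave fewer than 3 tips in tree ", i)
    out[[i]] <- ape::drop.tip(tr, hit)
  }
  class(out) <- "multiPhylo"
  out
}
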