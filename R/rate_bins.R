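#' Grid of branch rate scalars
#'
#' Equally spaced multiplicative scalars used by the branch
#' heterogeneity scan. The default 21-point grid spans 0.5 to 2; note
#' it does not contain 1.0 exactly (spacing 0.075), so the "neutral"
#' root category is the bin nearest 1.0 (scalar 1.025). Pass
#' \code{n = 21, low = 0.5, high = 2} for the default or any odd grid
#' containing 1.0 via e.g. \code{make_bin_grid(0.5, 1.5, 21)}.
#'
#' @param low,high Grid end points (low < high).
#' @param n Number of bins (>= 2).
#' @return A \code{chrom_bin_grid}: \code{scalars}, \code{n},
#'   \code{root_bin} (index of the scalar nearest 1.0; ties toward the
#'   lower scalar).
#' @export
make_bin_grid <- function(low = 0.5, high = 2, n = 21L) {
  if (!(low < high)) stop("low must be < high")
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 bins")
  scalars <- seq(low, high, length.out = n)
  structure(list(scalars = scalars, n = n,
                 root_bin = which.min(abs(scalars - 1))),
            class = "chrom_bin_grid")
}

#' Greedy preorder assignment of branch rate bins
#'
#' Scans the tree for branch-specific departures from the clade-wide
#' rate matrix. Every branch starts in the root bin (scalar nearest
#' 1.0). Branches are then visited in preorder; each branch may take
#' its parent branch's bin or the bins directly above and below it
#' (enforcing rate autocorrelation along the tree and limiting
#' overfitting). For each candidate the branch length is multiplied by
#' the candidate scalar, all other branches staying at their current
#' assignment, and the full-tree log-likelihood under \code{Q} is
#' evaluated; the branch is assigned the argmax (ties keep the parent
#' bin).
#'
#' @param tree \code{phylo} scaled consistently with \code{Q} (unit
#'   height when \code{Q} holds unit-height rates).
#' @param traits Matched trait table.
#' @param Q Pooled posterior mean rate matrix
#'   (\code{\link{build_rate_matrix}} of
#'   \code{\link{posterior_mean_rates}}).
#' @param grid A \code{\link{make_bin_grid}}.
#' @param root_mode Root treatment for the likelihood.
#' @return A \code{chrom_bin_assignment} data frame, one row per edge
#'   in the tree's postorder edge table: \code{edge}, \code{parent},
#'   \code{child}, \code{bin}, \code{scalar}, \code{loglik} (full-tree
#'   log-likelihood when the branch was assigned); the scanned tree and
#'   grid are attached as attributes.
#' @export
assign_branch_bins <- function(tree, traits, Q, grid = make_bin_grid(),
                               root_mode = "obs_weighted") {
  pr <- prep_pruning(tree, traits, Q)
  mode <- root_mode_code(root_mode)
  edge <- pr$edge
  nedge <- nrow(edge)
  preord <- rev(seq_len(nedge))
  bins <- rep(grid$root_bin, nedge)
  lls <- rep(NA_real_, nedge)
  parent_edge <- match(edge[, 1], edge[, 2])  # NA for root's children
  ll_at <- function(b) {
    len <- pr$len * grid$scalars[b]
    cpp_prune_loglik(edge, len, pr$ntip, pr$nnode, pr$tip_state,
                     unclass(Q), mode)
  }
  for (e in preord) {
    pbin <- if (is.na(parent_edge[e])) grid$root_bin else bins[parent_edge[e]]
    cand <- intersect(pbin + (-1L:1L), seq_len(grid$n))
    cll <- vapply(cand, function(b) {
      bb <- bins; bb[e] <- b; ll_at(bb)
    }, numeric(1))
    if (all(!is.finite(cll)))
      stop("non-finite likelihood for every candidate bin at edge ", e)
    best <- max(cll)
    pick <- cand[cll >= best - 1e-12]
    bins[e] <- if (pbin %in% pick) pbin else pick[which.max(cll[cand %in% pick])]
    lls[e] <- max(cll)
  }
  out <- data.frame(edge = seq_len(nedge), parent = edge[, 1],
                    child = edge[, 2], bin = bins,
                    scalar = grid$scalars[bins], loglik = lls)
  attr(out, "tree") <- pr$po
  attr(out, "grid") <- grid
  class(out) <- c("chrom_bin_assignment", "data.frame")
  out
}

# edges of the subtree rooted at the MRCA of `species` (postorder tree)
clade_edges <- function(tree, species) {
  tips <- match(species, tree$tip.label)
  tips <- tips[!is.na(tips)]
  if (length(tips) < 2L) return(integer(0))
  mrca <- ape::getMRCA(tree, tips)
  desc <- mrca
  repeat {
    grown <- unique(c(desc, tree$edge[tree$edge[, 1] %in% desc, 2]))
    if (length(grown) == length(desc)) break
    desc <- grown
  }
  which(tree$edge[, 2] %in% setdiff(desc, mrca) |
          (tree$edge[, 1] %in% desc & tree$edge[, 2] %in% desc))
}

#' Clade-level summary of branch rate bins
#'
#' Pools the scanned branches of each named clade (e.g. a family) with
#' at least \code{min_taxa} sampled species and reports, averaged
#' across the tree set, the proportion of its branches in elevated
#' (scalar > 1) and depressed (scalar < 1) bins and the mean scalar. A
#' branch exactly at 1.0 counts as neither.
#'
#' @param assignments List of \code{\link{assign_branch_bins}} results,
#'   one per tree.
#' @param clade_map Named character vector: species -> clade name.
#' @param min_taxa Minimum sampled species per clade (default 5).
#' @return Data frame: \code{clade}, \code{n_taxa},
#'   \code{prop_elevated}, \code{prop_depressed}, \code{mean_scalar},
#'   \code{n_trees}.
#' @export
summarize_clades <- function(assignments, clade_map, min_taxa = 5L) {
  if (inherits(assignments, "chrom_bin_assignment"))
    assignments <- list(assignments)
  clades <- split(names(clade_map), unname(clade_map))
  rows <- list()
  for (cl in names(clades)) {
    sp <- clades[[cl]]
    present <- intersect(sp, attr(assignments[[1]], "tree")$tip.label)
    if (length(present) < min_taxa) {
      message("clade '", cl, "' has ", length(present),
              " sampled taxa (< ", min_taxa, "); excluded")
      next
    }
    ev <- dep <- ms <- numeric(length(assignments))
    for (i in seq_along(assignments)) {
      tr <- attr(assignments[[i]], "tree")
      ed <- clade_edges(tr, present)
      sc <- assignments[[i]]$scalar[ed]
      ev[i] <- mean(sc > 1); dep[i] <- mean(sc < 1); ms[i] <- mean(sc)
    }
    rows[[cl]] <- data.frame(clade = cl, n_taxa = length(present),
                             prop_elevated = mean(ev),
                             prop_depressed = mean(dep),
                             mean_scalar = mean(ms),
                             n_trees = length(assignments))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
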