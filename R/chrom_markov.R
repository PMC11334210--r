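#' Combined chromosome-count by hyperstate space
#'
#' States are ordered count-major, hyperstate-minor:
#' (k_min, S), (k_min, L), (k_min + 1, S), ... so that state
#' \code{(k, h)} sits at row \code{2 * (k - k_min) + h}.
#'
#' @param k_min Smallest haploid count in the space (>= 1).
#' @param k_max Largest haploid count in the space.
#' @return A \code{chrom_state_space} with the ordered states.
#' @export
build_state_space <- function(k_min, k_max) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 1L) stop("k_min must be an integer >= 1")
  if (k_max < k_min) stop("k_max must be >= k_min")
  counts <- rep(k_min:k_max, each = 2L)
  hyper <- rep(1:2, times = k_max - k_min + 1L)
  structure(list(k_min = k_min, k_max = k_max, counts = counts,
                 hyper = hyper, size = 2L * (k_max - k_min + 1L),
                 labels = paste0(counts, c("S", "L")[hyper])),
            class = "chrom_state_space")
}

#' @export
print.chrom_state_space <- function(x, ...) {
  cat("chromosome state space:", x$size, "states, haploid counts",
      x$k_min, "-", x$k_max, "x {S, L}\n")
  invisible(x)
}

#' State space inferred from observed counts
#'
#' Default bounds pad the observed range by one so boundary species can
#' move in both directions, keeping the rate matrix small.
#'
#' @param traits Trait table (see \code{\link{trait_table}}).
#' @param pad Integer padding below the minimum and above the maximum.
#' @return A \code{chrom_state_space}.
#' @export
default_state_space <- function(traits, pad = 1L) {
  build_state_space(max(1L, min(traits$haploid_n) - pad),
                    max(traits$haploid_n) + pad)
}

state_index <- function(space, count, hyper) {
  2L * (count - space$k_min) + hyper
}

#' Model rate parameters
#'
#' Six free rates of the state-dependent chromosome model: fusion
#' (\code{delta_*}, count decrease by one), fission (\code{gamma_*},
#' count increase by one) within the small (S) and large (L)
#' hyperstates, and the hyperstate transition rates \code{q_SL},
#' \code{q_LS}. Polyploidy (\code{rho_*}, count doubling) is retained
#' but constrained to zero by default, as appropriate for clades with
#' no evidence of whole-genome duplication.
#'
#' @param delta_S,delta_L Fusion rates (per unit tree height).
#' @param gamma_S,gamma_L Fission rates.
#' @param q_SL,q_LS Hyperstate transition rates.
#' @param rho_S,rho_L Polyploidy rates (default 0).
#' @return Named numeric vector of class \code{chrom_rate_params}.
#' @export
rate_params <- function(delta_S, delta_L, gamma_S, gamma_L,
                        q_SL, q_LS, rho_S = 0, rho_L = 0) {
  p <- c(delta_S = delta_S, delta_L = delta_L, gamma_S = gamma_S,
         gamma_L = gamma_L, q_SL = q_SL, q_LS = q_LS,
         rho_S = rho_S, rho_L = rho_L)
  if (any(!is.finite(p)) || any(p < 0)) stop("all rates must be finite and >= 0")
  class(p) <- "chrom_rate_params"
  p
}

free_rate_names <- c("delta_S", "delta_L", "gamma_S", "gamma_L",
                     "q_SL", "q_LS")

#' Instantaneous rate matrix over the combined state space
#'
#' Allowed moves: count +/- 1 within a hyperstate (fission/fusion),
#' count doubling within a hyperstate (polyploidy, only while the
#' doubled count stays inside the space), and hyperstate flips at a
#' fixed count. Moves that would exit the space get rate 0.
#'
#' @param params A \code{\link{rate_params}} object.
#' @param space A \code{\link{build_state_space}} object.
#' @return Square matrix (rows sum to zero) of class
#'   \code{chrom_rate_matrix}, with the space and parameters attached
#'   as attributes.
#' @export
build_rate_matrix <- function(params, space) {
  S <- space$size
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  fus <- c(params[["delta_S"]], params[["delta_L"]])
  fis <- c(params[["gamma_S"]], params[["gamma_L"]])
  rho <- c(params[["rho_S"]], params[["rho_L"]])
  qflip <- c(params[["q_SL"]], params[["q_LS"]])
  for (i in seq_len(S)) {
    k <- space$counts[i]; h <- space$hyper[i]
    if (k > space$k_min) Q[i, state_index(space, k - 1L, h)] <- fus[h]
    if (k < space$k_max) Q[i, state_index(space, k + 1L, h)] <- fis[h]
    if (rho[h] > 0 && 2L * k <= space$k_max)
      Q[i, state_index(space, 2L * k, h)] <- Q[i, state_index(space, 2L * k, h)] + rho[h]
    Q[i, state_index(space, k, 3L - h)] <- qflip[h]
  }
  diag(Q) <- -rowSums(Q)
  structure(Q, space = space, params = params,
            class = c("chrom_rate_matrix", "matrix", "array"))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q Rate matrix from \code{\link{build_rate_matrix}} (any
#'   square generator is accepted).
#' @param t Elapsed time (>= 0).
#' @return Row-stochastic matrix; entries clipped to [0, 1] after a
#'   row-sum sanity check at tolerance 1e-9.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  P <- cpp_expm(unclass(Q), t)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop("matrix exponential rows deviate from 1 beyond tolerance")
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

# postorder edge table and per-tip state indices for the C++ kernels
prep_pruning <- function(tree, traits, Q) {
  space <- attr(Q, "space")
  if (is.null(space)) stop("Q must come from build_rate_matrix()")
  po <- stats::reorder(tree, "postorder")
  idx <- match(po$tip.label, traits$species)
  if (anyNA(idx)) stop("traits missing for tips: ",
                       paste(po$tip.label[is.na(idx)], collapse = ", "))
  counts <- traits$haploid_n[idx]
  bad <- counts < space$k_min | counts > space$k_max
  if (any(bad))
    stop("tip counts outside state space [", space$k_min, ", ", space$k_max,
         "] for: ", paste(po$tip.label[bad], collapse = ", "),
         "; widen the space bounds")
  hyper <- as.integer(traits$binary_state[idx])
  list(po = po, edge = po$edge, len = po$edge.length,
       ntip = ape::Ntip(po), nnode = po$Nnode,
       tip_state = state_index(space, counts, hyper))
}

root_mode_code <- function(root_mode) {
  match(match.arg(root_mode, c("obs_weighted", "flat")),
        c("obs_weighted", "flat")) - 1L
}

#' Pruning log-likelihood of tip data under the combined model
#'
#' Felsenstein's pruning algorithm over the count-by-hyperstate space.
#' Each tip has probability one on its observed (count, hyperstate)
#' pair. Underflow is controlled by per-node rescaling.
#'
#' @param tree Rooted \code{phylo}; branch lengths on the same scale as
#'   the rates in \code{Q}.
#' @param traits Trait table covering all tips.
#' @param Q Rate matrix from \code{\link{build_rate_matrix}}.
#' @param root_mode \code{"obs_weighted"} weights root states by their
#'   conditional likelihoods (FitzJohn-style); \code{"flat"} is uniform.
#' @return Log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, traits, Q,
                                root_mode = c("obs_weighted", "flat")) {
  pr <- prep_pruning(tree, traits, Q)
  ll <- cpp_prune_loglik(pr$edge, pr$len, pr$ntip, pr$nnode, pr$tip_state,
                         unclass(Q), root_mode_code(root_mode))
  if (is.nan(ll)) stop("non-finite likelihood")
  ll
}

#' Marginal ancestral state distributions
#'
#' Combines downpass conditional likelihoods with uppass contributions
#' to give, for every internal node, the marginal posterior over the
#' combined states, the marginal over chromosome counts (hyperstate
#' summed out), and the most probable count (ties broken toward the
#' lower count, recorded in \code{count_tied}).
#'
#' @inheritParams tree_log_likelihood
#' @return List with \code{loglik}, \code{node_marginals} (states x
#'   internal nodes; columns named by ape node number),
#'   \code{count_marginals}, \code{most_probable_count}, and
#'   \code{count_tied}.
#' @export
marginal_ancestral_states <- function(tree, traits, Q,
                                      root_mode = c("obs_weighted", "flat")) {
  pr <- prep_pruning(tree, traits, Q)
  space <- attr(Q, "space")
  S <- space$size
  mode <- root_mode_code(root_mode)
  res <- cpp_prune(pr$edge, pr$len, pr$ntip, pr$nnode, pr$tip_state,
                   unclass(Q), mode)
  if (!is.finite(res$loglik)) stop("non-finite likelihood")
  part <- res$partials
  root <- res$root
  edge <- pr$edge
  nedge <- nrow(edge)
  ntot <- pr$ntip + pr$nnode
  P <- vector("list", nedge)
  for (e in seq_len(nedge)) P[[e]] <- cpp_expm(unclass(Q), pr$len[e])
  child_edges <- split(seq_len(nedge), edge[, 1])
  up <- matrix(0, S, ntot)
  up[, root] <- if (mode == 0L) part[, root] / sum(part[, root]) else rep(1 / S, S)
  for (e in rev(seq_len(nedge))) {  # preorder
    par <- edge[e, 1]; chi <- edge[e, 2]
    sib <- rep(1, S)
    for (e2 in child_edges[[as.character(par)]]) {
      if (e2 != e) sib <- sib * as.vector(P[[e2]] %*% part[, edge[e2, 2]])
    }
    m <- as.vector(crossprod(P[[e]], up[, par] * sib))
    up[, chi] <- m / sum(m)
  }
  internal <- (pr$ntip + 1L):ntot
  marg <- matrix(0, S, length(internal),
                 dimnames = list(space$labels, internal))
  for (j in seq_along(internal)) {
    v <- internal[j]
    w <- up[, v] * part[, v]
    marg[, j] <- w / sum(w)
  }
  ncounts <- space$k_max - space$k_min + 1L
  cm <- rowsum(marg, group = space$counts)  # counts x nodes
  cm <- cm[order(as.integer(rownames(cm))), , drop = FALSE]
  count_vals <- as.integer(rownames(cm))
  mpc <- integer(ncol(cm)); tied <- logical(ncol(cm))
  for (j in seq_len(ncol(cm))) {
    top <- which(cm[, j] >= max(cm[, j]) - 1e-12)
    mpc[j] <- count_vals[top[1]]
    tied[j] <- length(top) > 1L
  }
  list(loglik = res$loglik, tree = pr$po,
       node_marginals = marg,
       count_marginals = cm,
       most_probable_count = setNames(mpc, internal),
       count_tied = setNames(tied, internal))
}
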