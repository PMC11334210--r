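# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: enumeration instead of pruning, window
# scans instead of the HPD shortcut, l'Huilier triangles instead of
# the polygon-area routine.

# Log-likelihood by exhaustive enumeration over interior-node states.
# Works for any rooted tree small enough to enumerate (S^n_internal
# terms); uses transition_probabilities() only as exp(Qt).
oracle_loglik_enum <- function(tree, tip_state, Q, root_mode = "obs_weighted") {
  S <- nrow(Q)
  po <- reorder(tree, "postorder")
  ntip <- ape::Ntip(po)
  internal <- (ntip + 1):(ntip + po$Nnode)
  P <- lapply(po$edge.length, function(t) chromdrift::transition_probabilities(Q, t))
  grids <- rep(list(seq_len(S)), length(internal))
  combos <- as.matrix(expand.grid(grids))
  D_root <- numeric(S)
  root <- ntip + 1
  for (r in seq_len(nrow(combos))) {
    st <- integer(ntip + po$Nnode)
    st[seq_len(ntip)] <- tip_state
    st[internal] <- combos[r, ]
    pr <- 1
    for (e in seq_len(nrow(po$edge))) {
      pr <- pr * P[[e]][st[po$edge[e, 1]], st[po$edge[e, 2]]]
    }
    D_root[st[root]] <- D_root[st[root]] + pr
  }
  val <- if (root_mode == "obs_weighted") sum(D_root^2) / sum(D_root)
         else mean(D_root)
  log(val)
}

# Marginal distribution of one internal node's state by enumeration.
oracle_node_marginal_enum <- function(tree, tip_state, Q, node,
                                      root_mode = "obs_weighted") {
  S <- nrow(Q)
  po <- reorder(tree, "postorder")
  ntip <- ape::Ntip(po)
  internal <- (ntip + 1):(ntip + po$Nnode)
  P <- lapply(po$edge.length, function(t) chromdrift::transition_probabilities(Q, t))
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  root <- ntip + 1
  # joint weight of each assignment, including the root prior
  D_root <- numeric(S)
  w <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    st <- integer(ntip + po$Nnode)
    st[seq_len(ntip)] <- tip_state
    st[internal] <- combos[r, ]
    pr <- 1
    for (e in seq_len(nrow(po$edge)))
      pr <- pr * P[[e]][st[po$edge[e, 1]], st[po$edge[e, 2]]]
    w[r] <- pr
    D_root[st[root]] <- D_root[st[root]] + pr
  }
  pi_root <- if (root_mode == "obs_weighted") D_root / sum(D_root)
             else rep(1 / S, S)
  marg <- numeric(S)
  for (r in seq_len(nrow(combos))) {
    st_root <- combos[r, match(root, internal)]
    st_node <- combos[r, match(node, internal)]
    marg[st_node] <- marg[st_node] + w[r] * pi_root[st_root]
  }
  marg / sum(marg)
}

# Shortest window containing >= ceiling(mass * n) samples, by scanning
# every window.
oracle_hpd_brute <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    lo <- x[i]; hi <- x[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Spherical polygon area via fan triangulation and l'Huilier's formula
# for the spherical excess of each triangle. lonlat in degrees, open
# ring; radius in km.
oracle_lhuilier_area <- function(lonlat, radius = 6371.0088) {
  to_xyz <- function(lon, lat) {
    lon <- lon * pi / 180; lat <- lat * pi / 180
    c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  }
  ang <- function(u, v) {  # great-circle angle
    2 * asin(min(1, sqrt(sum((u - v)^2)) / 2))
  }
  tri_excess <- function(a, b, c) {
    A <- ang(b, c); B <- ang(a, c); C <- ang(a, b)
    s <- (A + B + C) / 2
    t <- tan(s / 2) * tan((s - A) / 2) * tan((s - B) / 2) * tan((s - C) / 2)
    4 * atan(sqrt(max(0, t)))
  }
  v <- lapply(seq_len(nrow(lonlat)),
              function(i) to_xyz(lonlat[i, 1], lonlat[i, 2]))
  total <- 0
  for (i in 2:(length(v) - 1))
    total <- total + tri_excess(v[[1]], v[[i]], v[[i + 1]])
  total * radius^2
}

# all rooted binary 4-tip topologies with fixed branch lengths
fixture_trees_4tip <- function() {
  newicks <- c(
    "((A:0.3,B:0.5):0.4,(C:0.6,D:0.2):0.3);",
    "(((A:0.2,B:0.3):0.25,C:0.5):0.35,D:0.7);",
    "(((A:0.2,C:0.3):0.25,B:0.5):0.35,D:0.7);",
    "(((A:0.2,D:0.3):0.25,C:0.5):0.35,B:0.7);",
    "(((C:0.2,D:0.3):0.25,A:0.5):0.35,B:0.7);")
  lapply(newicks, function(s) ape::read.tree(text = s))
}

# small trait table on a 4-tip tree over a modest state space
fixture_traits_4tip <- function() {
  chromdrift::trait_table(c("A", "B", "C", "D"), c(2, 3, 4, 3),
                          c("small", "large", "large", "small"))
}

# exhaustive best constraint-respecting bin configuration for a small
# tree and grid: every branch's bin within +/-1 of its parent branch's
# bin (root's children constrained around the root bin)
oracle_bins_exhaustive <- function(tree, traits, Q, grid,
                                   root_mode = "obs_weighted") {
  po <- reorder(tree, "postorder")
  edge <- po$edge
  nedge <- nrow(edge)
  parent_edge <- match(edge[, 1], edge[, 2])
  combos <- as.matrix(expand.grid(rep(list(seq_len(grid$n)), nedge)))
  ok <- apply(combos, 1, function(b) {
    all(vapply(seq_len(nedge), function(e) {
      pbin <- if (is.na(parent_edge[e])) grid$root_bin else b[parent_edge[e]]
      abs(b[e] - pbin) <= 1
    }, logical(1)))
  })
  combos <- combos[ok, , drop = FALSE]
  best <- NULL; best_ll <- -Inf
  for (r in seq_len(nrow(combos))) {
    tr2 <- po
    tr2$edge.length <- po$edge.length * grid$scalars[combos[r, ]]
    ll <- chromdrift::tree_log_likelihood(tr2, traits, Q, root_mode)
    if (ll > best_ll) { best_ll <- ll; best <- combos[r, ] }
  }
  list(bins = unname(best), loglik = best_ll)
}

# Slow R-language pruning using transition_probabilities() (Pade expm)
# branch by branch; exercises none of the C++ caching or eigen paths.
oracle_loglik_pruneR <- function(tree, tip_state, Q, root_mode = "obs_weighted") {
  po <- reorder(tree, "postorder")
  ntip <- ape::Ntip(po)
  S <- nrow(Q)
  part <- matrix(1, S, ntip + po$Nnode)
  for (i in seq_len(ntip)) { part[, i] <- 0; part[tip_state[i], i] <- 1 }
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    P <- chromdrift::transition_probabilities(Q, po$edge.length[e])
    v <- P %*% part[, po$edge[e, 2]]
    part[, po$edge[e, 1]] <- part[, po$edge[e, 1]] * v
    s <- sum(part[, po$edge[e, 1]])
    part[, po$edge[e, 1]] <- part[, po$edge[e, 1]] / s
    logscale <- logscale + log(s)
  }
  D <- part[, ntip + 1]
  val <- if (root_mode == "obs_weighted") sum(D^2) / sum(D) else mean(D)
  logscale + log(val)
}
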