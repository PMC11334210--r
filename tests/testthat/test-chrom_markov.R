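test_that("state space is count-major with the documented sizes", {
  expect_equal(build_state_space(2, 4)$size, 6)
  expect_equal(build_state_space(19, 19)$size, 2)
  sp <- build_state_space(15, 39)
  expect_equal(sp$size, 50)
  expect_equal(sp$labels[1:4], c("15S", "15L", "16S", "16L"))
  expect_error(build_state_space(0, 4), "k_min")
})

test_that("rate matrix places each move and conserves probability", {
  sp <- build_state_space(2, 4)
  p <- rate_params(delta_S = 0.7, delta_L = 0.1, gamma_S = 2,
                   gamma_L = 0.4, q_SL = 1.1, q_LS = 0.9)
  Q <- build_rate_matrix(p, sp)
  expect_equal(Q["2S", "3S"], 2)       # fission in S
  expect_equal(Q["3S", "2S"], 0.7)     # fusion in S
  expect_equal(Q["3L", "4L"], 0.4)
  expect_equal(Q["2S", "2L"], 1.1)
  expect_equal(Q["4L", "4S"], 0.9)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # boundary: no fusion out of k_min, no fission out of k_max
  expect_equal(sum(Q["2S", setdiff(colnames(Q), c("2S", "3S", "2L"))]), 0)
  expect_equal(sum(Q["4L", setdiff(colnames(Q), c("4L", "3L", "4S"))]), 0)
})

test_that("polyploidy doubles the count only inside the space", {
  sp <- build_state_space(2, 4)
  Q <- build_rate_matrix(rate_params(0, 0, 0, 0, 0.5, 0.5, rho_S = 1), sp)
  expect_equal(Q["2S", "4S"], 1)
  expect_equal(Q["3S", "3S"], -0.5)  # 2*3 = 6 > k_max: only the q flip remains
})

test_that("transition probabilities match closed forms and the stationary limit", {
  sp <- build_state_space(5, 5)  # pure 2-state flip chain
  a <- 0.8; b <- 0.3
  Q <- build_rate_matrix(rate_params(0, 0, 0, 0, q_SL = a, q_LS = b), sp)
  expect_equal(transition_probabilities(Q, 0), diag(2), ignore_attr = TRUE)
  for (t in c(0.1, 1, 3)) {
    P <- transition_probabilities(Q, t)
    expect_equal(P[1, 2], a / (a + b) * (1 - exp(-(a + b) * t)),
                 tolerance = 1e-12)
    expect_equal(P[2, 1], b / (a + b) * (1 - exp(-(a + b) * t)),
                 tolerance = 1e-12)
  }
  # long-time rows converge to the eigen-decomposition stationary dist
  sp2 <- build_state_space(2, 4)
  Q2 <- build_rate_matrix(rate_params(0.5, 0.3, 0.6, 0.2, 0.9, 1.1), sp2)
  ev <- eigen(t(unclass(Q2)))
  stat <- Re(ev$vectors[, which.min(abs(ev$values))])
  stat <- stat / sum(stat)
  P <- transition_probabilities(Q2, 500)
  for (i in seq_len(nrow(P))) expect_equal(unname(P[i, ]), stat, tolerance = 1e-8)
  expect_error(transition_probabilities(Q2, -1), ">= 0")
})

test_that("likelihood with a zero rate matrix reduces to the root weight", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  sp <- build_state_space(2, 4)
  Q <- build_rate_matrix(rate_params(0, 0, 0, 0, 0, 0), sp)
  traits <- trait_table(c("A", "B"), c(3, 3), c("small", "small"))
  expect_equal(tree_log_likelihood(tr, traits, Q, "obs_weighted"), 0)
  expect_equal(tree_log_likelihood(tr, traits, Q, "flat"), log(1 / sp$size))
  # different tip states cannot be reached without change
  traits2 <- trait_table(c("A", "B"), c(3, 4), c("small", "small"))
  expect_equal(tree_log_likelihood(tr, traits2, Q), -Inf)
})

test_that("pruning equals exhaustive enumeration on 3-tip trees", {
  tr <- ape::read.tree(text = "((A:0.4,B:0.7):0.5,C:0.9);")
  sp <- build_state_space(2, 4)
  Q <- build_rate_matrix(rate_params(0.9, 0.2, 1.4, 0.5, 1.8, 0.7), sp)
  traits <- trait_table(c("A", "B", "C"), c(2, 3, 4),
                        c("small", "large", "small"))
  tip_state <- 2L * (traits$haploid_n - sp$k_min) +
    as.integer(traits$binary_state)
  for (mode in c("obs_weighted", "flat")) {
    ll <- tree_log_likelihood(tr, traits, Q, mode)
    ref <- oracle_loglik_enum(tr, tip_state, unclass(Q), mode)
    expect_equal(ll, ref, tolerance = 1e-10)
  }
})

test_that("likelihood obeys the time-rate scaling identity", {
  tr <- simulate_tree(15, seed = 21)
  tr <- scale_to_unit_height(tr)
  ds <- simulate_chromosomes(tr, sim_config(n_tips = 15, seed = 22))
  sp <- default_state_space(ds$traits)
  Q <- build_rate_matrix(rate_params(1.2, 0.3, 0.8, 0.5, 2, 1.5), sp)
  Q2 <- build_rate_matrix(rate_params(2.4, 0.6, 1.6, 1, 4, 3), sp)
  half <- tr; half$edge.length <- tr$edge.length / 2
  expect_equal(tree_log_likelihood(tr, ds$traits, Q),
               tree_log_likelihood(half, ds$traits, Q2), tolerance = 1e-9)
})

test_that("likelihood is invariant to tip ordering", {
  tr <- simulate_tree(10, seed = 31)
  ds <- simulate_chromosomes(scale_to_unit_height(tr),
                             sim_config(n_tips = 10, seed = 32))
  sp <- default_state_space(ds$traits)
  Q <- build_rate_matrix(rate_params(1, 0.2, 1, 0.2, 2, 2), sp)
  ll1 <- tree_log_likelihood(tr, ds$traits, Q)
  shuf <- ds$traits[sample(nrow(ds$traits)), ]
  expect_equal(tree_log_likelihood(tr, shuf, Q), ll1, tolerance = 1e-12)
  rot <- ape::rotate(tr, node = ape::Ntip(tr) + 1)
  expect_equal(tree_log_likelihood(rot, ds$traits, Q), ll1, tolerance = 1e-9)
})

test_that("with no hyperstate flips the model reduces to a count-only chain", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.6):0.4,(C:0.5,D:0.2):0.6);")
  sp <- build_state_space(2, 5)
  Q <- build_rate_matrix(rate_params(0.8, 99, 1.1, 99, q_SL = 0, q_LS = 0),
                         sp)
  traits <- trait_table(c("A", "B", "C", "D"), c(2, 4, 3, 5),
                        rep("small", 4))  # all tips in the S hyperstate
  ll <- tree_log_likelihood(tr, traits, Q, "flat")
  # count-only birth-death chain on counts 2..5 with the S rates
  n <- 4
  Qc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) Qc[i, i - 1] <- 0.8
    if (i < n) Qc[i, i + 1] <- 1.1
  }
  diag(Qc) <- -rowSums(Qc)
  ref <- oracle_loglik_enum(tr, c(1L, 3L, 2L, 4L), Qc, "flat")
  # flat root over the combined space spreads mass over 2x the states
  expect_equal(ll, ref + log(n / sp$size), tolerance = 1e-9)
})

test_that("tip counts outside the space raise an instructive error", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  sp <- build_state_space(3, 4)
  Q <- build_rate_matrix(rate_params(1, 1, 1, 1, 1, 1), sp)
  traits <- trait_table(c("A", "B"), c(2, 4), c("small", "large"))
  expect_error(tree_log_likelihood(tr, traits, Q), "widen")
})

test_that("marginal ancestral states normalize, respect symmetry, and match enumeration", {
  sp <- build_state_space(2, 3)
  Q <- build_rate_matrix(rate_params(0.6, 0.6, 0.6, 0.6, 0.6, 0.6), sp)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  traits <- trait_table(c("A", "B"), c(2, 3), c("small", "small"))
  asr <- marginal_ancestral_states(tr, traits, Q, "flat")
  m <- asr$node_marginals[, 1]
  # symmetric rates, symmetric tips: ancestor symmetric in 2S and 3S
  expect_equal(m[["2S"]], m[["3S"]], tolerance = 1e-9)
  expect_equal(sum(m), 1, tolerance = 1e-9)

  tr3 <- ape::read.tree(text = "((A:0.4,B:0.7):0.5,C:0.9);")
  Q3 <- build_rate_matrix(rate_params(0.9, 0.2, 1.4, 0.5, 1.8, 0.7), sp)
  traits3 <- trait_table(c("A", "B", "C"), c(2, 3, 3),
                         c("small", "large", "small"))
  tip_state <- 2L * (traits3$haploid_n - sp$k_min) +
    as.integer(traits3$binary_state)
  for (mode in c("obs_weighted", "flat")) {
    asr3 <- marginal_ancestral_states(tr3, traits3, Q3, mode)
    for (node in colnames(asr3$node_marginals)) {
      ref <- oracle_node_marginal_enum(tr3, tip_state, unclass(Q3),
                                       as.integer(node), mode)
      expect_equal(unname(asr3$node_marginals[, node]), ref,
                   tolerance = 1e-9)
    }
    expect_lt(max(abs(colSums(asr3$node_marginals) - 1)), 1e-9)
    expect_lt(max(abs(colSums(asr3$count_marginals) - 1)), 1e-9)
  }
})

test_that("the fast kernel agrees with slow R pruning on larger spaces", {
  tr <- simulate_tree(40, seed = 91)
  tru <- scale_to_unit_height(tr)
  ds <- simulate_chromosomes(tru, sim_config(
    n_tips = 40, seed = 92,
    params = rate_params(3, 1, 3, 1, 2, 2)))
  sp <- default_state_space(ds$traits)
  expect_gt(sp$size, 8)  # wide enough to engage the spectral path
  Q <- build_rate_matrix(rate_params(1.5, 0.25, 1.5, 0.25, 2, 2), sp)
  tip_state <- 2L * (ds$traits$haploid_n - sp$k_min) +
    as.integer(ds$traits$binary_state)
  for (mode in c("obs_weighted", "flat")) {
    expect_equal(tree_log_likelihood(tru, ds$traits, Q, mode),
                 oracle_loglik_pruneR(tru, tip_state, unclass(Q), mode),
                 tolerance = 1e-8)
  }
})
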