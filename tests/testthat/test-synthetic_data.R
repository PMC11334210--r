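test_that("birth-death trees meet the contract", {
  tr <- simulate_tree(5, seed = 1)
  expect_equal(ape::Ntip(tr), 5)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  pb <- simulate_tree(40, birth = 1, death = 0, seed = 2)
  expect_true(all(pb$edge.length > 0))
  expect_error(simulate_tree(2), "at least 3")
  expect_error(simulate_tree(10, birth = 0.5, death = 1), "birth > death")
})

test_that("pure-birth root heights track the theoretical expectation", {
  # E[height] for a Yule tree conditioned on n tips, rate b:
  # sum_{k=2}^{n} 1/(b*k)
  n <- 20; b <- 1
  expected <- sum(1 / (b * (2:n)))
  set.seed(3)
  h <- replicate(400, tree_height(ape::rphylo(n, b, 0)))
  se <- stats::sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - expected), 4 * se)
})

test_that("zero rates freeze the root state at every tip", {
  tr <- scale_to_unit_height(simulate_tree(12, seed = 4))
  cfg <- sim_config(params = rate_params(0, 0, 0, 0, 0, 0), root_n = 19,
                    seed = 5)
  ds <- simulate_chromosomes(tr, cfg)
  expect_equal(ds$traits$haploid_n, rep(19L, 12))
  expect_equal(length(unique(ds$traits$binary_state)), 1)
  expect_equal(nrow(ds$events), 0)
})

test_that("fission-only simulation never drops below the root count", {
  tr <- scale_to_unit_height(simulate_tree(25, seed = 6))
  cfg <- sim_config(params = rate_params(0, 0, 2, 2, 1, 1), root_n = 19,
                    seed = 7)
  ds <- simulate_chromosomes(tr, cfg)
  expect_true(all(ds$traits$haploid_n >= 19))
  expect_true(any(ds$traits$haploid_n > 19))
})

test_that("replaying the event log reproduces the recorded tip states", {
  for (s in 1:5) {
    tr <- scale_to_unit_height(simulate_tree(15, seed = 100 + s))
    ds <- simulate_chromosomes(tr, sim_config(n_tips = 15, seed = 200 + s))
    rep <- replay_tip_states(ds)
    expect_equal(rep$haploid_n, ds$traits$haploid_n)
    expect_equal(rep$hyperstate, as.integer(ds$traits$binary_state))
  }
})

test_that("event counts match the Poisson expectation", {
  # single branch of length L with only fission at rate g active:
  # events ~ Poisson(g * L)
  tr <- ape::read.tree(text = "(A:2,B:2);")
  g <- 1.5
  cfg_base <- sim_config(params = rate_params(0, 0, g, g, 0, 0),
                         root_n = 19)
  set.seed(8)
  n_events <- replicate(400, {
    cfg <- cfg_base; cfg$seed <- NULL
    nrow(simulate_chromosomes(tr, cfg)$events)
  })
  lambda <- g * 4  # two branches of length 2
  se <- sqrt(lambda / 400)
  expect_lt(abs(mean(n_events) - lambda), 3 * se)
})

test_that("the neutral binary trait is symmetric and exact", {
  tr <- scale_to_unit_height(simulate_tree(10, seed = 9))
  frozen <- simulate_binary_trait(tr, rate = 0, seed = 10)
  expect_equal(length(unique(frozen)), 1)
  # stationarity: pooled tip-state frequency ~ 0.5 at rate 2
  set.seed(11)
  freq <- mean(replicate(150, {
    tr_i <- ape::rphylo(10, 1, 0)
    tr_i$edge.length <- tr_i$edge.length / tree_height(tr_i)
    mean(simulate_binary_trait(tr_i, 2) == "small")
  }))
  expect_lt(abs(freq - 0.5), 0.06)
})

test_that("two-tip simulation frequencies match the transition probabilities", {
  # star tree with two branches of length 0.7 from a fixed root state;
  # tip-state pairs follow P(0.7) rows independently
  tr <- ape::read.tree(text = "(A:0.7,B:0.7);")
  p <- rate_params(0.9, 0.9, 1.1, 1.1, 0.8, 0.8)
  sp <- build_state_space(1, 60)
  Q <- build_rate_matrix(p, sp)
  P <- transition_probabilities(Q, 0.7)
  root_idx <- 2L * (19L - sp$k_min) + 1L  # (19, S)
  set.seed(12)
  cfg <- sim_config(params = p, root_n = 19, root_prob_small = 1)
  draws <- replicate(4000, {
    cfg$seed <- NULL
    d <- simulate_chromosomes(tr, cfg)
    2L * (d$traits$haploid_n[1] - sp$k_min) +
      as.integer(d$traits$binary_state[1])
  })
  obs <- tabulate(draws, nbins = sp$size)
  expected <- P[root_idx, ] * length(draws)
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / max(sum(expected[!keep]), 1)
  pval <- stats::pchisq(chi, df = sum(keep), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("variance adequacy reports sample variance and quantile", {
  obs <- trait_table(c("a", "b", "c"), c(1, 2, 3),
                     c("small", "large", "small"))
  expect_equal(variance_adequacy(obs, list(obs))$obs_var, 1)
  sims <- lapply(1:5, function(i)
    trait_table(c("a", "b", "c"), c(1, 2, 3) + i %% 2,
                c("small", "large", "small")))
  va <- variance_adequacy(obs, sims)
  expect_equal(va$sim_mean, 1)
  expect_equal(va$obs_quantile, 1)  # all simulated variances <= observed
  const <- trait_table(c("a", "b", "c"), c(7, 7, 7),
                       c("small", "large", "small"))
  expect_equal(variance_adequacy(const, list(obs))$obs_var, 0)
})

test_that("an empty neutral-trait experiment returns an empty report", {
  tr <- scale_to_unit_height(simulate_tree(8, seed = 13))
  counts <- trait_table(tr$tip.label, rep(19L, 8),
                        rep(c("small", "large"), 4))
  rep0 <- false_positive_experiment(c(tr), counts, n_neutral = 0)
  expect_equal(nrow(rep0$per_trait), 0)
  expect_true(is.na(rep0$fp_fusion))
})

test_that("false-positive fractions agree with an independent tally", {
  tr <- scale_to_unit_height(simulate_tree(10, seed = 14))
  ds <- simulate_chromosomes(tr, sim_config(n_tips = 10, seed = 15))
  s <- mcmc_settings(n_generations = 25, n_replicates = 1, burnin = 10,
                     seed = 16)
  rep3 <- false_positive_experiment(c(tr), ds$traits, n_neutral = 3,
                                    settings = s)
  per <- rep3$per_trait
  expect_equal(nrow(per), 3)
  expect_equal(rep3$fp_fusion,
               mean(per$lo_fusion > 0 | per$hi_fusion < 0))
  expect_equal(rep3$fp_fission,
               mean(per$lo_fission > 0 | per$hi_fission < 0))
  expect_true(all(c(rep3$fp_fusion, rep3$fp_fission) >= 0 &
                    c(rep3$fp_fusion, rep3$fp_fission) <= 1))
})
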