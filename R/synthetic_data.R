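#' Configuration for synthetic karyotype datasets
#'
#' Defaults emulate a Carnivora-like study system: ~110-tip trees,
#' haploid counts wandering around a root count of 19 by single fusion
#' and fission steps, a binary hyperstate (small/large range) flipping
#' at rate 2 on unit-height trees with a 50/50 root draw, and fusion
#' and fission six-fold faster in the small hyperstate (1.5 vs 0.25
#' per unit height) -- a strong state effect of the kind the model is
#' built to detect.
#'
#' @param n_tips Number of extant species.
#' @param birth,death Birth-death rates for tree simulation.
#' @param params Generating \code{\link{rate_params}}.
#' @param root_n Root haploid count (default 19).
#' @param root_prob_small Probability the root is in the small
#'   hyperstate (default 0.5).
#' @param neutral_rate Transition rate of the neutral binary trait
#'   used in false-positive experiments (default 2).
#' @param seed Seed for all simulation randomness.
#' @return A \code{chrom_sim_config} list.
#' @export
sim_config <- function(n_tips = 110L, birth = 1, death = 0,
                       params = rate_params(delta_S = 1.5, delta_L = 0.25,
                                            gamma_S = 1.5, gamma_L = 0.25,
                                            q_SL = 2, q_LS = 2),
                       root_n = 19L, root_prob_small = 0.5,
                       neutral_rate = 2, seed = NULL) {
  if (root_prob_small < 0 || root_prob_small > 1)
    stop("root_prob_small must be in [0, 1]")
  if (root_n < 1L) stop("root_n must be >= 1")
  structure(list(n_tips = as.integer(n_tips), birth = birth, death = death,
                 params = params, root_n = as.integer(root_n),
                 root_prob_small = root_prob_small,
                 neutral_rate = neutral_rate, seed = seed),
            class = "chrom_sim_config")
}

#' Simulate an ultrametric birth-death tree
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth Speciation rate (> death).
#' @param death Extinction rate (>= 0).
#' @param seed Optional seed.
#' @return Ultrametric \code{phylo} with \code{n_tips} tips, labels
#'   \code{t1..tn}.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  if (n_tips < 3L) stop("need at least 3 tips")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth, death)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

# Gillespie simulation of the combined (count, hyperstate) chain along
# one branch; counts floored at 1, no upper cap.
sim_branch <- function(n, h, len, p) {
  events <- list()
  t <- 0
  repeat {
    r_fus <- if (n > 1L) c(p[["delta_S"]], p[["delta_L"]])[h] else 0
    r_fis <- c(p[["gamma_S"]], p[["gamma_L"]])[h]
    r_rho <- c(p[["rho_S"]], p[["rho_L"]])[h]
    r_flip <- c(p[["q_SL"]], p[["q_LS"]])[h]
    tot <- r_fus + r_fis + r_rho + r_flip
    if (tot <= 0) break
    t <- t + rexp(1, tot)
    if (t >= len) break
    ev <- sample.int(4L, 1L, prob = c(r_fus, r_fis, r_rho, r_flip))
    type <- c("fusion", "fission", "polyploidy", "flip")[ev]
    n_new <- switch(type, fusion = n - 1L, fission = n + 1L,
                    polyploidy = 2L * n, flip = n)
    h_new <- if (type == "flip") 3L - h else h
    events[[length(events) + 1L]] <-
      data.frame(time = t, type = type, from_n = n, to_n = n_new,
                 from_h = h, to_h = h_new, stringsAsFactors = FALSE)
    n <- n_new; h <- h_new
  }
  list(n = n, h = h,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Simulate chromosome numbers and hyperstates along a tree
#'
#' Exact stochastic (Gillespie) simulation of the joint
#' (count, hyperstate) chain, branch by branch, using the same move
#' set as \code{\link{build_rate_matrix}}: counts change by one
#' (floored at 1, no upper cap), optionally double, and the hyperstate
#' flips. Every event is logged so tip states can be replayed.
#'
#' @param tree \code{phylo} on the same time scale as the rates in
#'   \code{config$params} (unit height for the defaults).
#' @param config A \code{\link{sim_config}}.
#' @return A \code{chrom_sim_dataset}: \code{tree}, \code{traits}
#'   (trait table with hyperstates labeled small/large), \code{events}
#'   (per-branch event log keyed by child node), \code{root_n},
#'   \code{root_h}, \code{config}.
#' @export
simulate_chromosomes <- function(tree, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  po <- stats::reorder(tree, "postorder")
  nedge <- nrow(po$edge)
  ntip <- ape::Ntip(po)
  root <- ntip + 1L
  state_n <- integer(ntip + po$Nnode)
  state_h <- integer(ntip + po$Nnode)
  state_n[root] <- config$root_n
  state_h[root] <- if (runif(1) < config$root_prob_small) 1L else 2L
  logs <- list()
  for (e in rev(seq_len(nedge))) {  # preorder
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    res <- sim_branch(state_n[par], state_h[par], po$edge.length[e], p)
    state_n[chi] <- res$n; state_h[chi] <- res$h
    if (!is.null(res$events)) {
      res$events$branch <- chi
      logs[[length(logs) + 1L]] <- res$events
    }
  }
  events <- if (length(logs)) do.call(rbind, logs) else
    data.frame(time = numeric(0), type = character(0), from_n = integer(0),
               to_n = integer(0), from_h = integer(0), to_h = integer(0),
               branch = integer(0))
  traits <- trait_table(po$tip.label, state_n[seq_len(ntip)],
                        factor(c("small", "large")[state_h[seq_len(ntip)]],
                               levels = c("small", "large")))
  structure(list(tree = po, traits = traits, events = events,
                 root_n = config$root_n, root_h = state_h[root],
                 config = config),
            class = "chrom_sim_dataset")
}

#' Replay a simulated event log from the root
#'
#' Deterministically reapplies the logged events branch by branch and
#' returns the implied tip counts and hyperstates -- a consistency
#' check on the simulator.
#'
#' @param dataset A \code{\link{simulate_chromosomes}} result.
#' @return Data frame \code{species}, \code{haploid_n},
#'   \code{hyperstate} (1 = small, 2 = large).
#' @export
replay_tip_states <- function(dataset) {
  po <- dataset$tree
  ntip <- ape::Ntip(po)
  state_n <- integer(ntip + po$Nnode); state_h <- integer(ntip + po$Nnode)
  root <- ntip + 1L
  state_n[root] <- dataset$root_n; state_h[root] <- dataset$root_h
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    n <- state_n[par]; h <- state_h[par]
    ev <- dataset$events[dataset$events$branch == chi, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      stopifnot(ev$from_n[1] == n, ev$from_h[1] == h)
      n <- ev$to_n[nrow(ev)]; h <- ev$to_h[nrow(ev)]
    }
    state_n[chi] <- n; state_h[chi] <- h
  }
  data.frame(species = po$tip.label, haploid_n = state_n[seq_len(ntip)],
             hyperstate = state_h[seq_len(ntip)], stringsAsFactors = FALSE)
}

#' Simulate a neutral binary trait
#'
#' Symmetric two-state continuous-time chain with uniform root state,
#' simulated exactly along every branch. Used to measure the model's
#' false-positive behavior: the trait mimics the dynamics of the range
#' hyperstate but cannot influence chromosome evolution.
#'
#' @param tree \code{phylo} on the scale of \code{rate} (unit height
#'   for the default rate of 2).
#' @param rate Symmetric transition rate (>= 0).
#' @param seed Optional seed.
#' @return Named factor (levels small/large) over the tips.
#' @export
simulate_binary_trait <- function(tree, rate = 2, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  po <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(po)
  st <- integer(ntip + po$Nnode)
  st[ntip + 1L] <- sample(1:2, 1L)
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    h <- st[par]; t <- 0
    if (rate > 0) repeat {
      t <- t + rexp(1, rate)
      if (t >= po$edge.length[e]) break
      h <- 3L - h
    }
    st[chi] <- h
  }
  setNames(factor(c("small", "large")[st[seq_len(ntip)]],
                  levels = c("small", "large")), po$tip.label)
}

#' Neutral-trait false-positive experiment
#'
#' Holds the chromosome counts fixed, pairs each tree with a freshly
#' simulated neutral binary trait, refits the full model, and records
#' the rate-difference statistic. The fraction of traits whose 95% HPD
#' excludes zero estimates the analysis' false-positive rate; the
#' fraction of |mean deltaR| values exceeding \code{ref_delta}
#' measures how often noise alone matches an observed effect size.
#'
#' @param trees \code{multiPhylo}; trait i is simulated on (and fit
#'   to) tree \code{(i - 1) \%\% length(trees) + 1}.
#' @param counts Trait table supplying the fixed \code{haploid_n}.
#' @param n_neutral Number of neutral traits.
#' @param prior,settings Passed to \code{\link{fit_tree_set}}.
#' @param neutral_rate Transition rate of the neutral trait.
#' @param ref_delta Optional reference |deltaR| (per MY), e.g. the
#'   mean from an empirical fit.
#' @return List: \code{per_trait} data frame (mean and HPD of deltaR
#'   for fusion and fission per trait), \code{fp_fusion},
#'   \code{fp_fission} (fractions with HPD excluding 0),
#'   \code{frac_exceed_ref} (or \code{NA}), \code{errors}.
#' @export
false_positive_experiment <- function(trees, counts, n_neutral,
                                      prior = prior_spec(),
                                      settings = mcmc_settings(),
                                      neutral_rate = 2, ref_delta = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  rows <- list(); errors <- character(0)
  for (i in seq_len(n_neutral)) {
    ti <- (i - 1L) %% length(trees) + 1L
    tr <- trees[[ti]]
    if (is.null(attr(tr, "height_my"))) tr <- scale_to_unit_height(tr)
    trait <- simulate_binary_trait(tr, neutral_rate,
                                   seed = derive_seed(settings$seed, 500 + ti, i))
    traits <- trait_table(counts$species, counts$haploid_n,
                          trait[counts$species])
    s <- settings; s$seed <- derive_seed(settings$seed, 900 + ti, i)
    res <- tryCatch({
      post <- fit_tree_set(c(tr), traits, prior, s)
      post <- back_transform(post)
      dfu <- delta_r(post, "fusion"); dfi <- delta_r(post, "fission")
      data.frame(trait = i, tree = ti,
                 mean_fusion = dfu$mean, lo_fusion = dfu$hpd_low,
                 hi_fusion = dfu$hpd_high,
                 mean_fission = dfi$mean, lo_fission = dfi$hpd_low,
                 hi_fission = dfi$hpd_high)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors <- c(errors, paste0("trait ", i, ": ", res))
    else rows[[length(rows) + 1L]] <- res
  }
  per_trait <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = integer(0), tree = integer(0),
               mean_fusion = numeric(0), lo_fusion = numeric(0),
               hi_fusion = numeric(0), mean_fission = numeric(0),
               lo_fission = numeric(0), hi_fission = numeric(0))
  excl0 <- function(lo, hi) lo > 0 | hi < 0
  n <- nrow(per_trait)
  list(per_trait = per_trait,
       fp_fusion = if (n) mean(excl0(per_trait$lo_fusion, per_trait$hi_fusion)) else NA_real_,
       fp_fission = if (n) mean(excl0(per_trait$lo_fission, per_trait$hi_fission)) else NA_real_,
       frac_exceed_ref = if (n && !is.null(ref_delta))
         mean(pmax(abs(per_trait$mean_fusion), abs(per_trait$mean_fission)) >=
                abs(ref_delta)) else NA_real_,
       errors = errors)
}

#' Variance-based model adequacy check
#'
#' Compares the sample variance of observed tip haploid counts with
#' the variances from datasets simulated under the fitted model. A
#' much larger observed variance flags heterogeneity the fitted
#' process does not capture.
#'
#' @param observed Trait table of the empirical (or reference) data.
#' @param simulated List of \code{\link{simulate_chromosomes}} results
#'   (or trait tables).
#' @return List: \code{obs_var}, \code{sim_var} (vector),
#'   \code{sim_min}, \code{sim_mean}, \code{sim_max}, and
#'   \code{obs_quantile} (fraction of simulated variances at or below
#'   the observed).
#' @export
variance_adequacy <- function(observed, simulated) {
  if (length(simulated) == 0L) stop("need at least one simulated dataset")
  getvar <- function(x) {
    if (inherits(x, "chrom_sim_dataset")) var(x$traits$haploid_n)
    else var(x$haploid_n)
  }
  sim_var <- vapply(simulated, getvar, numeric(1))
  obs <- var(observed$haploid_n)
  list(obs_var = obs, sim_var = sim_var, sim_min = min(sim_var),
       sim_mean = mean(sim_var), sim_max = max(sim_var),
       obs_quantile = mean(sim_var <= obs))
}
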