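#' Exponential prior on the free rates
#'
#' One independent exponential prior per free rate, parameterized by
#' its rate (default 2, i.e. mean 0.5 on the unit-height scale, which
#' keeps mass on biologically plausible values). A mean
#' parameterization is available for convenience.
#'
#' @param rate Exponential rate parameter (> 0).
#' @param mean Optional prior mean; overrides \code{rate} via
#'   \code{rate = 1/mean}.
#' @return A \code{chrom_prior} object.
#' @export
prior_spec <- function(rate = 2, mean = NULL) {
  if (!is.null(mean)) rate <- 1 / mean
  if (!is.finite(rate) || rate <= 0) stop("prior rate must be > 0")
  structure(list(family = "exponential", rate = rate), class = "chrom_prior")
}

#' MCMC settings
#'
#' Defaults mirror a short replication-mode protocol: 500 generations,
#' 6 replicate chains per tree, the first 450 generations discarded as
#' burnin, and initial values drawn uniformly on (0, 10). These runs
#' are short by general MCMC standards; raise \code{n_generations} for
#' de-novo analyses.
#'
#' @param n_generations Generations per chain (one generation = one
#'   full sweep of univariate slice-sampling updates).
#' @param n_replicates Replicate chains per tree.
#' @param burnin Generations discarded from the selected chain.
#' @param init_max Upper bound of the uniform initialization window.
#' @param w Slice-sampler step-out width.
#' @param seed Master seed; per-tree/replicate seeds are derived
#'   deterministically from it.
#' @return A \code{chrom_mcmc_settings} object.
#' @export
mcmc_settings <- function(n_generations = 500L, n_replicates = 6L,
                          burnin = 450L, init_max = 10, w = 1, seed = 42L) {
  if (burnin >= n_generations) stop("burnin must be < n_generations")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(n_generations = as.integer(n_generations),
                 n_replicates = as.integer(n_replicates),
                 burnin = as.integer(burnin), init_max = init_max,
                 w = w, seed = as.integer(seed)),
            class = "chrom_mcmc_settings")
}

derive_seed <- function(master, tree_idx, rep_idx) {
  as.integer((as.double(master) + 7919 * tree_idx + 104729 * rep_idx) %%
               2147483647)
}

# one univariate slice-sampling update (Neal 2003, step-out + shrink)
# on [0, Inf); f takes the scalar and returns the log target.
slice_update <- function(x0, f, fx0, w, max_steps = 100L) {
  y <- fx0 - rexp(1)
  lo <- x0 - runif(1) * w
  hi <- lo + w
  steps <- 0L
  while (lo > 0 && f(lo) > y && steps < max_steps) {
    lo <- lo - w; steps <- steps + 1L
  }
  lo <- max(lo, 0)
  steps <- 0L
  while (f(hi) > y && steps < max_steps) {
    hi <- hi + w; steps <- steps + 1L
  }
  repeat {
    x1 <- runif(1, lo, hi)
    fx1 <- f(x1)
    if (fx1 >= y) return(list(x = x1, fx = fx1))
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-300) return(list(x = x0, fx = fx0))
  }
}

#' Slice-sampling MCMC for the rate parameters on one tree
#'
#' Posterior is the pruning likelihood times independent exponential
#' priors on the six free rates (polyploidy held at zero). One
#' generation updates every free rate once by slice sampling.
#'
#' @param tree Unit-height \code{phylo} (see
#'   \code{\link{scale_to_unit_height}}).
#' @param traits Matched trait table.
#' @param prior \code{\link{prior_spec}} object.
#' @param settings \code{\link{mcmc_settings}} object; its \code{seed}
#'   seeds this chain directly.
#' @param space State space; default derived from the observed counts.
#' @param root_mode Root treatment, as in
#'   \code{\link{tree_log_likelihood}}.
#' @param loglik_fn Likelihood override taking a \code{chrom_rate_params};
#'   used for prior-recovery checks with a constant likelihood.
#' @return Data frame with one row per generation: the six free rates,
#'   \code{loglik} and \code{logpost}.
#' @export
sample_posterior <- function(tree, traits, prior = prior_spec(),
                             settings = mcmc_settings(), space = NULL,
                             root_mode = "obs_weighted", loglik_fn = NULL) {
  if (is.null(space)) space <- default_state_space(traits)
  if (is.null(loglik_fn)) {
    pr <- prep_pruning(tree, traits, build_rate_matrix(
      rate_params(1, 1, 1, 1, 1, 1), space))
    mode <- root_mode_code(root_mode)
    loglik_fn <- function(theta) {
      Q <- build_rate_matrix(do.call(rate_params, as.list(theta)), space)
      cpp_prune_loglik(pr$edge, pr$len, pr$ntip, pr$nnode, pr$tip_state,
                       unclass(Q), mode)
    }
  }
  log_prior <- function(theta) sum(dexp(theta, prior$rate, log = TRUE))
  logpost_fn <- function(theta) loglik_fn(theta) + log_prior(theta)
  set.seed(settings$seed)
  theta <- NULL
  for (try in seq_len(20L)) {
    cand <- setNames(runif(6, 0, settings$init_max), free_rate_names)
    if (is.finite(logpost_fn(cand))) { theta <- cand; break }
  }
  if (is.null(theta)) stop("no finite posterior found in 20 initializations")
  out <- matrix(NA_real_, settings$n_generations, 8,
                dimnames = list(NULL, c(free_rate_names, "loglik", "logpost")))
  cur_lp <- logpost_fn(theta)
  for (g in seq_len(settings$n_generations)) {
    for (j in seq_along(free_rate_names)) {
      fj <- function(x) {
        th <- theta; th[j] <- x
        logpost_fn(th)
      }
      upd <- slice_update(theta[j], fj, cur_lp, settings$w)
      theta[j] <- upd$x
      cur_lp <- upd$fx
    }
    out[g, ] <- c(theta, cur_lp - log_prior(theta), cur_lp)
  }
  df <- as.data.frame(out)
  df$generation <- seq_len(settings$n_generations)
  df
}

#' Fit the model over a posterior tree distribution
#'
#' Runs \code{n_replicates} chains per tree (distinct derived seeds),
#' keeps the chain whose final-generation log posterior is highest
#' (guarding against chains stuck on local likelihood peaks), discards
#' burnin, and pools the remaining samples across trees.
#'
#' @param trees \code{multiPhylo} set; trees in MY are unit-scaled
#'   internally and their heights recorded for back-transformation.
#' @param traits Matched trait table.
#' @inheritParams sample_posterior
#' @return A \code{chrom_posterior} data frame with columns
#'   \code{tree}, \code{replicate}, \code{generation}, the six free
#'   rates, \code{loglik}, \code{logpost}; tree heights (MY) are in
#'   \code{attr(, "height_my")} and \code{attr(, "per_my")} records
#'   the rate scale.
#' @export
fit_tree_set <- function(trees, traits, prior = prior_spec(),
                         settings = mcmc_settings(), space = NULL,
                         root_mode = "obs_weighted") {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(space)) space <- default_state_space(traits)
  heights <- numeric(length(trees))
  pooled <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(attr(tr, "height_my"))) tr <- scale_to_unit_height(tr)
    heights[i] <- attr(tr, "height_my")
    chains <- vector("list", settings$n_replicates)
    final_lp <- rep(-Inf, settings$n_replicates)
    for (r in seq_len(settings$n_replicates)) {
      s <- settings
      s$seed <- derive_seed(settings$seed, i, r)
      chains[[r]] <- tryCatch(
        sample_posterior(tr, traits, prior, s, space, root_mode),
        error = function(e) NULL)
      if (!is.null(chains[[r]]))
        final_lp[r] <- chains[[r]]$logpost[nrow(chains[[r]])]
    }
    if (all(!is.finite(final_lp)))
      stop("all MCMC replicates failed for tree ", i)
    best <- which.max(final_lp)
    keep <- chains[[best]][(settings$burnin + 1L):settings$n_generations, ]
    keep$tree <- i
    keep$replicate <- best
    pooled[[i]] <- keep
  }
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out <- out[, c("tree", "replicate", "generation", free_rate_names,
                 "loglik", "logpost")]
  attr(out, "height_my") <- heights
  attr(out, "per_my") <- FALSE
  attr(out, "space") <- space
  class(out) <- c("chrom_posterior", "data.frame")
  out
}

#' Back-transform pooled rates to per-million-year units
#'
#' Rates estimated on unit-height trees are divided by each tree's
#' original height (MY) so that pooled summaries are on a common per-MY
#' scale.
#'
#' @param posterior A \code{chrom_posterior} from
#'   \code{\link{fit_tree_set}}.
#' @return The posterior with rate columns divided by the matching
#'   tree height; \code{attr(, "per_my")} becomes \code{TRUE}.
#' @export
back_transform <- function(posterior) {
  h <- attr(posterior, "height_my")
  if (is.null(h)) stop("posterior lacks recorded tree heights")
  if (isTRUE(attr(posterior, "per_my"))) return(posterior)
  if (any(h <= 0)) stop("tree heights must be > 0")
  scale <- h[posterior$tree]
  for (nm in free_rate_names) posterior[[nm]] <- posterior[[nm]] / scale
  attr(posterior, "per_my") <- TRUE
  posterior
}

#' Posterior mean rate parameters
#'
#' @param posterior A \code{chrom_posterior}.
#' @return A \code{\link{rate_params}} of column means (polyploidy 0).
#' @export
posterior_mean_rates <- function(posterior) {
  m <- colMeans(posterior[, free_rate_names, drop = FALSE])
  do.call(rate_params, as.list(m))
}
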