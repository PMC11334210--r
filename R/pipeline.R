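#' Configuration for a full analysis run
#'
#' Bundles inputs and options for \code{\link{run_analysis}}. Trees
#' and traits may be given as paths (Newick / delimited text) or as
#' in-memory objects.
#'
#' @param trees Path to a Newick tree-set file, or a
#'   \code{multiPhylo}/\code{phylo}.
#' @param traits Path to a trait table, or a data frame from
#'   \code{\link{trait_table}}.
#' @param occurrences Optional path to (or data frame of) occurrence
#'   coordinates; when given, the binary state is rebuilt from
#'   median-discretized convex-hull range areas.
#' @param state_col Binary trait column name in the trait file.
#' @param bounds_pad State-space padding around the observed counts.
#' @param root_mode Root treatment for all likelihoods.
#' @param prior,mcmc Prior and MCMC settings.
#' @param grid Rate-bin grid for the heterogeneity scan.
#' @param clade_map Optional named vector species -> clade for the
#'   clade rate summary.
#' @param prune_clades Optional character vector of tip labels removed
#'   before analysis (robustness runs).
#' @param n_adequacy Simulated datasets for the variance adequacy
#'   check (0 disables).
#' @param n_neutral Neutral traits for the false-positive experiment
#'   (0 disables).
#' @param stages Stages to run, a subset of
#'   \code{c("fit", "deltar", "tiprates", "bins", "adequacy",
#'   "neutralfp")}.
#' @param seed Master seed.
#' @return A \code{chrom_analysis_config}.
#' @export
analysis_config <- function(trees, traits, occurrences = NULL,
                            state_col = "state", bounds_pad = 1L,
                            root_mode = "obs_weighted",
                            prior = prior_spec(), mcmc = mcmc_settings(),
                            grid = make_bin_grid(), clade_map = NULL,
                            prune_clades = NULL, n_adequacy = 0L,
                            n_neutral = 0L,
                            stages = c("fit", "deltar", "tiprates", "bins",
                                       "adequacy", "neutralfp"),
                            seed = 42L) {
  if (is.character(trees) && !file.exists(trees))
    stop("tree file not found: ", trees)
  if (is.character(traits) && !file.exists(traits))
    stop("trait file not found: ", traits)
  if (is.character(occurrences) && !file.exists(occurrences))
    stop("occurrence file not found: ", occurrences)
  mcmc$seed <- as.integer(seed)
  structure(list(trees = trees, traits = traits, occurrences = occurrences,
                 state_col = state_col, bounds_pad = as.integer(bounds_pad),
                 root_mode = root_mode, prior = prior, mcmc = mcmc,
                 grid = grid, clade_map = clade_map,
                 prune_clades = prune_clades,
                 n_adequacy = as.integer(n_adequacy),
                 n_neutral = as.integer(n_neutral),
                 stages = stages, seed = as.integer(seed)),
            class = "chrom_analysis_config")
}

#' Swap the binary trait column of a configuration
#'
#' Robustness helper: re-points the analysis at another binary trait
#' (e.g. body-size class instead of range-size class). A numeric
#' column is discretized at its median (>= median becomes
#' \code{large}).
#'
#' @param config A \code{\link{analysis_config}}.
#' @param column Column name in the trait file / data frame.
#' @return Updated configuration with the trait table materialized.
#' @export
substitute_trait <- function(config, column) {
  df <- if (is.character(config$traits)) {
    first <- readLines(config$traits, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    read.table(config$traits, header = TRUE, sep = sep,
               stringsAsFactors = FALSE)
  } else config$traits
  if (is.data.frame(df) && "binary_state" %in% names(df) &&
      !column %in% names(df))
    stop("column '", column, "' not found in trait table")
  if (!column %in% names(df)) stop("column '", column,
                                   "' not found in trait table")
  val <- df[[column]]
  if (is.numeric(val)) {
    if (length(unique(val)) < 2L) stop("column '", column,
                                       "' has a single value; not discretizable")
    cls <- ifelse(val >= median(val), "large", "small")
  } else {
    if (length(unique(val)) != 2L)
      stop("column '", column, "' is not binary")
    cls <- as.character(val)
  }
  config$traits <- trait_table(df$species, df$haploid_n, cls)
  config$substituted_trait <- column
  config
}

load_analysis_inputs <- function(config) {
  trees <- if (is.character(config$trees)) read_tree_set(config$trees)
           else if (inherits(config$trees, "phylo")) c(config$trees)
           else config$trees
  traits <- if (is.character(config$traits))
    read_trait_table(config$traits, config$state_col) else config$traits
  if (!is.null(config$occurrences)) {
    occ <- if (is.character(config$occurrences))
      read_occurrences(config$occurrences) else config$occurrences
    ranges <- discretize_by_median(estimate_ranges(occ))
    keep <- intersect(traits$species, ranges$species)
    traits <- trait_table(keep,
                          traits$haploid_n[match(keep, traits$species)],
                          ranges$class[match(keep, ranges$species)])
  }
  if (!is.null(config$prune_clades)) trees <- prune_taxa(trees, config$prune_clades)
  match_and_prune(trees, traits)
}

#' Run the full analysis pipeline
#'
#' Loads and matches inputs, fits the model by MCMC over the tree set,
#' and derives every enabled downstream product: per-MY rate
#' differences, tip rates, the branch rate-bin scan with clade
#' summaries, the variance adequacy check, and the neutral-trait
#' false-positive experiment. Deterministic given the master seed.
#'
#' @param config A \code{\link{analysis_config}}.
#' @return A \code{chrom_analysis_report} list with one element per
#'   enabled stage plus a \code{provenance} block (seed, settings,
#'   dropped/pruned taxa, package version).
#' @export
run_analysis <- function(config) {
  inputs <- load_analysis_inputs(config)
  trees <- inputs$trees; traits <- inputs$traits
  space <- build_state_space(max(1L, min(traits$haploid_n) - config$bounds_pad),
                             max(traits$haploid_n) + config$bounds_pad)
  report <- list()
  post <- NULL
  if ("fit" %in% config$stages) {
    post <- fit_tree_set(trees, traits, config$prior, config$mcmc,
                         space, config$root_mode)
    post_my <- back_transform(post)
    report$posterior <- post_my
    mean_rates <- posterior_mean_rates(post)  # unit-height scale
    report$mean_rates_unit <- mean_rates
  }
  if ("deltar" %in% config$stages && !is.null(post)) {
    report$delta_r <- list(fusion = delta_r(report$posterior, "fusion"),
                           fission = delta_r(report$posterior, "fission"),
                           q = delta_r(report$posterior, "q"))
  }
  Qmean <- if (!is.null(post))
    build_rate_matrix(report$mean_rates_unit, space) else NULL
  if ("tiprates" %in% config$stages && !is.null(Qmean)) {
    tr <- get_tip_rates(trees[[1]], traits, Qmean, config$root_mode)
    report$tip_rates <- tr
    report$tip_rate_summary <- summarize_tip_rates(tr)
  }
  if ("bins" %in% config$stages && !is.null(Qmean)) {
    assignments <- lapply(seq_along(trees), function(i)
      assign_branch_bins(scale_to_unit_height(trees[[i]]), traits, Qmean,
                         config$grid, config$root_mode))
    report$bin_assignments <- assignments
    if (!is.null(config$clade_map))
      report$clade_summary <- summarize_clades(assignments, config$clade_map)
  }
  if ("adequacy" %in% config$stages && config$n_adequacy > 0 &&
      !is.null(post)) {
    sims <- lapply(seq_len(config$n_adequacy), function(i) {
      tr <- scale_to_unit_height(trees[[(i - 1L) %% length(trees) + 1L]])
      simulate_chromosomes(tr, sim_config(
        params = report$mean_rates_unit, root_n = 19L,
        seed = derive_seed(config$seed, 300L, i)))
    })
    report$adequacy <- variance_adequacy(traits, sims)
  }
  if ("neutralfp" %in% config$stages && config$n_neutral > 0) {
    ref <- if (!is.null(report$delta_r))
      max(abs(report$delta_r$fusion$mean),
          abs(report$delta_r$fission$mean)) else NULL
    report$false_positives <- false_positive_experiment(
      trees, traits, config$n_neutral, config$prior, config$mcmc,
      ref_delta = ref)
  }
  report$provenance <- list(seed = config$seed,
                            n_trees = length(trees),
                            n_species = nrow(traits),
                            space = c(space$k_min, space$k_max),
                            mcmc = unclass(config$mcmc),
                            prior = unclass(config$prior),
                            root_mode = config$root_mode,
                            pruned = config$prune_clades,
                            substituted_trait = config$substituted_trait,
                            package_version =
                              as.character(utils::packageVersion("chromdrift")))
  class(report) <- "chrom_analysis_report"
  report
}
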