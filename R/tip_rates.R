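#' Per-tip rates of chromosome number change
#'
#' For each extant species: the absolute difference between its
#' haploid count and the most probable count of its immediate ancestor
#' (from marginal ancestral state reconstruction, hyperstate summed
#' out), divided by the connecting branch length in MY. A fast tip
#' rate flags a species whose karyotype changed recently; the metric
#' checks whether a few outlier species drive clade-level rate
#' estimates.
#'
#' The reconstruction runs on the unit-height tree (the scale the
#' rates in \code{Q} were estimated on); the division uses branch
#' lengths in MY.
#'
#' @param tree Ultrametric \code{phylo} with branch lengths in MY.
#' @param traits Matched trait table.
#' @param Q Rate matrix built from pooled posterior mean rates on the
#'   unit-height scale (see \code{\link{posterior_mean_rates}}).
#' @param root_mode Root treatment for the reconstruction.
#' @return Data frame: \code{species}, \code{tip_n}, \code{anc_n},
#'   \code{branch_my}, \code{tip_rate} (changes per MY), and
#'   \code{binary_state}. Zero-length terminal branches with a count
#'   change yield \code{NA} with a warning.
#' @export
get_tip_rates <- function(tree, traits, Q, root_mode = "obs_weighted") {
  unit <- scale_to_unit_height(tree)
  asr <- marginal_ancestral_states(unit, traits, Q, root_mode)
  po <- asr$tree  # postorder copy; same node numbering as tree
  ntip <- ape::Ntip(po)
  tipidx <- seq_len(ntip)
  parent <- po$edge[match(tipidx, po$edge[, 2]), 1]
  h <- attr(unit, "height_my")
  bl_my <- po$edge.length[match(tipidx, po$edge[, 2])] * h
  idx <- match(po$tip.label, traits$species)
  tip_n <- traits$haploid_n[idx]
  anc_n <- asr$most_probable_count[as.character(parent)]
  rate <- abs(tip_n - anc_n) / bl_my
  bad <- bl_my == 0 & tip_n != anc_n
  if (any(bad)) {
    warning("zero-length terminal branch with a count change for: ",
            paste(po$tip.label[bad], collapse = ", "),
            "; tip rate reported as NA")
    rate[bad] <- NA_real_
  }
  rate[bl_my == 0 & tip_n == anc_n] <- 0
  data.frame(species = po$tip.label, tip_n = tip_n,
             anc_n = unname(anc_n), branch_my = bl_my,
             tip_rate = rate,
             binary_state = traits$binary_state[idx],
             stringsAsFactors = FALSE)
}

#' Summarize tip rates by hyperstate
#'
#' @param table Output of \code{\link{get_tip_rates}}.
#' @return List with \code{by_state} (per-state mean rate, zero and
#'   non-zero tip counts), \code{max_rate}, and \code{max_species}
#'   (all species attaining the maximum).
#' @export
summarize_tip_rates <- function(table) {
  if (nrow(table) == 0L) stop("empty tip-rate table")
  ok <- !is.na(table$tip_rate)
  by_state <- do.call(rbind, lapply(split(table[ok, ], table$binary_state[ok]),
    function(d) data.frame(n = nrow(d),
                           mean_rate = if (nrow(d)) mean(d$tip_rate) else NA_real_,
                           n_zero = sum(d$tip_rate == 0),
                           n_nonzero = sum(d$tip_rate > 0))))
  mx <- max(table$tip_rate[ok])
  list(by_state = by_state, max_rate = mx,
       max_species = table$species[ok][table$tip_rate[ok] == mx])
}
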