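#' Highest posterior density interval
#'
#' Shortest contiguous window over the sorted samples containing
#' \code{ceiling(mass * n)} of them -- the standard empirical HPD
#' estimator for unimodal posteriors.
#'
#' @param samples Numeric vector (>= 10 values).
#' @param mass Probability mass of the interval (default 0.95).
#' @return List with \code{low}, \code{high}, \code{mass}.
#' @export
hpd <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(list(low = x[1], high = x[n], mass = mass))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  list(low = x[i], high = x[i + k - 1], mass = mass)
}

#' Posterior rate-difference statistic
#'
#' For each posterior sample the rate in the small hyperstate minus the
#' rate in the large hyperstate (fusion: delta_S - delta_L; fission:
#' gamma_S - gamma_L; q: q_SL - q_LS, a diagnostic). A positive
#' difference means faster chromosome evolution in small-hyperstate
#' lineages. Support is called from the HPD interval: entirely positive
#' -> \code{small_elevated}; entirely negative -> \code{large_elevated};
#' otherwise \code{indeterminate}.
#'
#' @param posterior A \code{chrom_posterior}; back-transform first
#'   (\code{\link{back_transform}}) to report per-MY differences.
#' @param which One of \code{"fusion"}, \code{"fission"}, \code{"q"}.
#' @param mass HPD mass (default 0.95).
#' @return A \code{chrom_delta_r} list: \code{parameter},
#'   \code{samples}, \code{mean}, \code{hpd_low}, \code{hpd_high},
#'   \code{support}.
#' @export
delta_r <- function(posterior, which = c("fusion", "fission", "q"),
                    mass = 0.95) {
  which <- match.arg(which)
  if (nrow(posterior) == 0L) stop("empty posterior")
  d <- switch(which,
              fusion  = posterior$delta_S - posterior$delta_L,
              fission = posterior$gamma_S - posterior$gamma_L,
              q       = posterior$q_SL - posterior$q_LS)
  iv <- hpd(d, mass)
  support <- if (iv$low > 0) "small_elevated"
             else if (iv$high < 0) "large_elevated"
             else "indeterminate"
  structure(list(parameter = which, samples = d, mean = mean(d),
                 hpd_low = iv$low, hpd_high = iv$high, mass = mass,
                 support = support),
            class = "chrom_delta_r")
}

#' @export
print.chrom_delta_r <- function(x, ...) {
  cat(sprintf("deltaR(%s): mean %.4g, %d%% HPD [%.4g, %.4g] -> %s\n",
              x$parameter, x$mean, round(100 * x$mass), x$hpd_low,
              x$hpd_high, x$support))
  invisible(x)
}
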