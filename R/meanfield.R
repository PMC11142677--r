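# Mean-field analytical layer: erosion dynamics, intrinsic allele age,
# numerical log-fitness response, and the dosage regime predictor.

#' Mean-field parameters
#'
#' Derived rates of the mean-field approximation: the net conversion rate
#' `g = d / (8h)` (probability that a transmitted gamete underwent
#' conversion at a given heterozygous target) and the net erosion rate
#' `rho = N*v*d / (2h) = 4*N*v*g` per generation.
#'
#' @param N,u,v,d,h Model parameters.
#' @return List with `N`, `u`, `v`, `d`, `h`, `g`, `rho`, `fourNu`.
#' @export
meanfield_params <- function(N, u, v, d, h) {
  g <- d / (8 * h)
  list(N = N, u = u, v = v, d = d, h = h,
       g = g, rho = 4 * N * v * g, fourNu = 4 * N * u)
}

#' Erosion rate of an allele
#'
#' Mean-field decay of the proportion of active sites of an allele at
#' frequency `f`: `d(theta)/dt = -rho * f * theta`.
#'
#' @param theta Proportion of active sites in `[0, 1]`.
#' @param f Allele frequency in `[0, 1]`.
#' @param params A [meanfield_params()] list.
#' @return The per-generation rate of change of theta (non-positive).
#' @export
erosion_ode <- function(theta, f, params) {
  stopifnot(theta >= 0, theta <= 1, f >= 0, f <= 1)
  -params$rho * f * theta
}

#' Intrinsic age of an allele
#'
#' Frequency-weighted cumulative time, `z(t) = rho * integral of f`,
#' accumulated by trapezoidal rule over the recorded generations. Under weak
#' erosion `z` approximates the cumulated erosion `1 - theta`: an allele
#' ages faster when more frequent.
#'
#' @param generations Increasing generation times of the trajectory.
#' @param f Allele frequency at those times.
#' @param params A [meanfield_params()] list.
#' @return Numeric vector `z` along the trajectory (same length as `f`).
#' @export
intrinsic_age <- function(generations, f, params) {
  n <- length(f)
  stopifnot(length(generations) == n)
  if (n == 0) return(numeric(0))
  if (n == 1) return(0)
  dt <- diff(generations)
  mid <- (f[-1] + f[-n]) / 2
  params$rho * c(0, cumsum(dt * mid))
}

#' Numerical log-fitness response to erosion (alpha)
#'
#' Slope of minus the log fitness of a homozygote as a function of its
#' erosion level z, at z = 0. Sites are eroded in order of decreasing
#' affinity — mirroring the preferential conversion of high-affinity sites —
#' and the derivative is taken by central finite difference with step `dz`,
#' averaged over `n_rep` random fresh alleles. Uses R's RNG.
#'
#' @param mean_affinity,h,d Model parameters.
#' @param c_hom Dosage multiplier of the homozygote.
#' @param dz Finite-difference step on the erosion fraction.
#' @param n_rep Alleles to average over.
#' @return Estimate of alpha (non-negative).
#' @export
estimate_alpha <- function(mean_affinity, h, d, c_hom = 1,
                           dz = 0.01, n_rep = 100) {
  lw <- function(y_sorted, z) {
    keep <- y_sorted[seq_len(max(1L, round((1 - z) * length(y_sorted))))]
    log(fertility(q_hom(site_moments(keep, c_hom)), d))
  }
  mean(vapply(seq_len(n_rep), function(i) {
    y <- sort(raffinity(h, mean_affinity))   # increasing: erode from the top
    -(lw(y, 2 * dz) - lw(y, 0)) / (2 * dz)
  }, numeric(1)))
}

#' Predicted equilibrium regime under gene dosage
#'
#' Classifies the Red Queen equilibrium from the scaled mutation rate and
#' the cumulated dosage effect: monomorphic when `4Nu <= 10`; otherwise
#' polymorphic when `sigma0 * tau < 3`, else eviction (the dominant allele's
#' homozygote advantage eliminates rarer alleles).
#'
#' @param params A [meanfield_params()] list (for `fourNu`).
#' @param sigma0 Fresh-allele haplo-insufficiency (see [sigma0()]).
#' @param tau Mean time between successive allele invasions (generations),
#'   e.g. from [measure_tau()].
#' @return `"monomorphic"`, `"polymorphic"` or `"eviction"`.
#' @export
regime_predictor <- function(params, sigma0, tau) {
  if (!(params$fourNu > 10)) return("monomorphic")
  if (sigma0 * tau < 3) "polymorphic" else "eviction"
}

#' Mean-field report for a configuration
#'
#' Convenience wrapper assembling the analytical quantities for a
#' configuration: `g`, `rho`, `alpha`, `sigma0`, `4Nu`, and — when a run is
#' supplied — the measured `tau`, `sigma0*tau` and the predicted regime.
#'
#' @param config An [sim_config()] object.
#' @param run Optional `rq_run` from which tau is measured.
#' @param n_rep Replicates for the sigma0 and alpha estimates.
#' @return Named list of mean-field quantities.
#' @export
meanfield_report <- function(config, run = NULL, n_rep = 100) {
  p <- meanfield_params(config$N, config$u, config$v, config$d, config$h)
  rep <- list(
    g = p$g, rho = p$rho, fourNu = p$fourNu,
    alpha = estimate_alpha(config$mean_affinity, config$h, config$d,
                           config$c_hom, n_rep = n_rep),
    sigma0 = sigma0(config$mean_affinity, config$h, config$d, config$c_hom,
                    n_rep = n_rep)
  )
  if (!is.null(run)) {
    rep$tau <- run$summary$tau
    rep$sigma0_tau <- rep$sigma0 * rep$tau
    rep$regime <- if (is.na(rep$tau)) NA_character_
                  else regime_predictor(p, rep$sigma0, rep$tau)
  }
  rep
}
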