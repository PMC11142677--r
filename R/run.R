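#' Run a Red Queen simulation
#'
#' Executes the full generation loop: PRDM9-locus mutation, target-site
#' mutation, then production of exactly N offspring by explicit meiosis
#' (each gamete: draw a parent uniformly, attempt up to `n_mei` meioses,
#' redraw the parent on failure). Statistics are recorded every
#' `record_every` generations; equilibrium summaries are time-averages over
#' generations past the burn-in.
#'
#' @param config An [sim_config()] object.
#' @param init Optional population snapshot (as returned in `$population`)
#'   to restart from instead of the default initial population (monomorphic
#'   for a single fresh allele, all sites active).
#' @param return_population If `TRUE`, include the final population snapshot
#'   in the result (serialisable with [write_population()]).
#' @return An `rq_run` list:
#' \describe{
#'   \item{trajectory}{Per-generation, per-allele data frame: frequency `f`,
#'     fraction of active sites `theta`, mean affinity of active sites,
#'     background-averaged symmetric-binding rate `q` and fertility `w`
#'     (weight 2 for homozygous carriers, 1 for heterozygous).}
#'   \item{scalars}{Per-generation population scalars: diversity `D`,
#'     `theta_bar`, `q_bar`, `w_bar`, mean haplo-insufficiency `sigma_bar`,
#'     cumulative meiosis success rate.}
#'   \item{s0}{New-allele selection coefficient probes (if enabled).}
#'   \item{summary}{Equilibrium means past the burn-in (see
#'     [summarize_run()]).}
#'   \item{counters}{Meiosis attempt/failure tallies.}
#' }
#' @export
run_redqueen <- function(config, init = NULL, return_population = FALSE) {
  validate_config(config)
  res <- rq_run_cpp(config, init, return_population)
  res$config <- config
  res$summary <- summarize_run(res, burn_in = config$burn_in)
  class(res) <- "rq_run"
  res
}

#' Equilibrium summary of a run
#'
#' Time-averages the recorded population scalars over generations strictly
#' beyond the burn-in, and measures the mean time between successive allele
#' invasions (tau).
#'
#' @param run An `rq_run` object (or a list with `$scalars`, `$s0`,
#'   `$trajectory`).
#' @param burn_in Generations to discard (defaults to the run's configured
#'   burn-in).
#' @param invasion_threshold Frequency an allele must first exceed to count
#'   as an invasion when measuring tau.
#' @return List of equilibrium means: `D`, `theta_bar`, `erosion`
#'   (`1 - theta_bar`), `q_bar`, `w_bar`, `sigma_bar`, `s0`, `tau`,
#'   `n_generations` averaged over.
#' @export
summarize_run <- function(run, burn_in = NULL,
                          invasion_threshold = 0.1) {
  if (is.null(burn_in)) burn_in <- run$config$burn_in
  sc <- run$scalars
  keep <- sc$generation > burn_in
  if (!any(keep)) {
    return(list(D = NA_real_, theta_bar = NA_real_, erosion = NA_real_,
                q_bar = NA_real_, w_bar = NA_real_, sigma_bar = NA_real_,
                s0 = NA_real_, tau = NA_real_, n_generations = 0L))
  }
  s0 <- NA_real_
  if (!is.null(run$s0) && nrow(run$s0) > 0) {
    k0 <- run$s0$generation > burn_in
    if (any(k0)) s0 <- mean(run$s0$s0[k0])
  }
  list(
    D = mean(sc$D[keep]),
    theta_bar = mean(sc$theta_bar[keep]),
    erosion = 1 - mean(sc$theta_bar[keep]),
    q_bar = mean(sc$q_bar[keep]),
    w_bar = mean(sc$w_bar[keep]),
    sigma_bar = mean(sc$sigma_bar[keep], na.rm = TRUE),
    s0 = s0,
    tau = measure_tau(run$trajectory, burn_in = burn_in,
                      threshold = invasion_threshold),
    n_generations = sum(keep)
  )
}

#' Mean time between successive allele invasions
#'
#' An invasion is the first time a new allele exceeds the frequency
#' threshold. Returns the mean spacing between successive invasion times
#' past the burn-in (`NA` with fewer than two invasions).
#'
#' @param trajectory Per-allele trajectory data frame (`generation`,
#'   `allele_id`, `f`).
#' @param burn_in Generations to discard.
#' @param threshold Invasion frequency threshold (default 0.1).
#' @return Mean inter-invasion time in generations.
#' @export
measure_tau <- function(trajectory, burn_in = 0, threshold = 0.1) {
  tr <- trajectory[trajectory$f > threshold, c("generation", "allele_id")]
  if (nrow(tr) == 0) return(NA_real_)
  first <- tapply(tr$generation, tr$allele_id, min)
  inv <- sort(first[first > burn_in])
  if (length(inv) < 2) return(NA_real_)
  mean(diff(inv))
}

#' @export
print.rq_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("redqueen run: %d generations (burn-in %d), mode %s\n",
              x$config$generations, x$config$burn_in, x$config$mode))
  cat(sprintf("  equilibrium: D = %.3g, erosion = %.3g, q_bar = %.3g, w_bar = %.3g\n",
              s$D, s$erosion, s$q_bar, s$w_bar))
  if (!is.na(s$s0)) cat(sprintf("  s0 = %.3g  (4Ns0 = %.3g at simulated N)\n",
                                s$s0, 4 * x$config$N * s$s0))
  if (!is.na(s$tau)) cat(sprintf("  tau = %.4g generations between invasions\n", s$tau))
  invisible(x)
}
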