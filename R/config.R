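#' Simulation configuration
#'
#' Validates and assembles the full parameter set of one simulation run.
#'
#' @param N Population size (diploid individuals), `N >= 2`.
#' @param u Mutation rate at the PRDM9 locus, per gene copy per generation.
#' @param v Inactivating mutation rate at target sites, per site per diploid
#'   individual per generation (the hit lands on one random copy).
#' @param h Number of target sites recognised by each allele.
#' @param d Mean number of DSBs per meiocyte (chromosome pair).
#' @param mean_affinity Mean of the exponential affinity distribution.
#' @param c_hom Homozygous dosage multiplier in `[1, 2]`; 1 disables dosage.
#' @param n_mei Meiosis attempts allowed per drawn parent (1 to 5).
#' @param mode `"symmetry_required"` (full model: meiosis needs a DSB at a
#'   symmetrically bound site) or `"control_no_symmetry"` (control model:
#'   any DSB suffices).
#' @param generations Number of generations to simulate.
#' @param burn_in Generations discarded before equilibrium averaging
#'   (`generations > burn_in >= 0`).
#' @param seed Integer seed for the simulation's own RNG.
#' @param L Number of chromosome slots available for target sites. Default
#'   `200 * h`, enough for ~200 concurrently live alleles; the run aborts if
#'   fewer than `h` free slots remain.
#' @param prdm9_slot 1-based slot index of the PRDM9 locus (default:
#'   mid-chromosome).
#' @param record_every Record summary statistics every this many generations.
#' @param s0_every Evaluate the new-allele selection coefficient every this
#'   many generations (0 disables; probes consume RNG draws, so toggling this
#'   changes the realised trajectory for a given seed).
#' @param s0_probes Fresh probe alleles per evaluation.
#' @return A validated `rq_config` list.
#' @export
sim_config <- function(N, u, v,
                       h = 400,
                       d = 6,
                       mean_affinity = 0.2,
                       c_hom = 1,
                       n_mei = 1,
                       mode = c("symmetry_required", "control_no_symmetry"),
                       generations = 50000,
                       burn_in = 10000,
                       seed = 1,
                       L = 200L * h,
                       prdm9_slot = NULL,
                       record_every = 1,
                       s0_every = 0,
                       s0_probes = 10) {
  mode <- match.arg(mode)
  if (is.null(prdm9_slot)) prdm9_slot <- as.integer(L %/% 2)
  cfg <- list(
    N = as.integer(N), u = u, v = v, h = as.integer(h), d = d,
    mean_affinity = mean_affinity, c_hom = c_hom, n_mei = as.integer(n_mei),
    mode = mode, generations = as.integer(generations),
    burn_in = as.integer(burn_in), seed = seed, L = as.integer(L),
    prdm9_slot = as.integer(prdm9_slot),
    record_every = as.integer(record_every),
    s0_every = as.integer(s0_every), s0_probes = as.integer(s0_probes)
  )
  validate_config(cfg)
  structure(cfg, class = "rq_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$N >= 2,
    cfg$u >= 0, cfg$u <= 1,
    cfg$v >= 0, cfg$v <= 1,
    cfg$h >= 1,
    cfg$d > 0,
    cfg$mean_affinity > 0,
    cfg$c_hom >= 1, cfg$c_hom <= 2,
    cfg$n_mei >= 1, cfg$n_mei <= 5,
    cfg$generations >= 0,
    cfg$burn_in >= 0,
    cfg$generations == 0 || cfg$generations > cfg$burn_in,
    cfg$L > cfg$h,
    cfg$prdm9_slot >= 1, cfg$prdm9_slot <= cfg$L,
    cfg$record_every >= 1,
    cfg$s0_every >= 0,
    cfg$s0_probes >= 1
  )
  invisible(cfg)
}

#' @export
print.rq_config <- function(x, ...) {
  cat(sprintf(
    "redqueen config: N = %d, u = %g, v = %g, h = %d, d = %g, ybar = %g,\n  c_hom = %g, n_mei = %d, mode = %s, generations = %d (burn-in %d), seed = %s\n",
    x$N, x$u, x$v, x$h, x$d, x$mean_affinity, x$c_hom, x$n_mei, x$mode,
    x$generations, x$burn_in, format(x$seed)))
  invisible(x)
}

#' Documented parameter presets
#'
#' Returns the parameter sets used for the model's reference experiments:
#'
#' \describe{
#'   \item{`scaling_reference`}{Central configuration of the scaling
#'     experiments: `N = 5000, h = 400, d = 6, mean_affinity = 0.2`,
#'     `u = 5e-5`, `v = 2e-6`, no dosage.}
#'   \item{`monomorphic_example`}{Illustrative monomorphic regime:
#'     `u = 5e-6, v = 5e-5`, otherwise as the reference, no dosage.}
#'   \item{`polymorphic_example`}{Illustrative polymorphic regime:
#'     `u = 5e-4, v = 5e-5`, no dosage.}
#'   \item{`dosage_example`}{As `polymorphic_example` but with full gene dosage
#'     (`c_hom = 2`), which drives the eviction regime.}
#'   \item{`calibration_row1` ... `calibration_row7`}{The mouse-calibrated
#'     settings (`h = 800`, pre-rescaling `v = 1e-7`, `N = 1e5`), with the
#'     documented 20-fold rescaling already applied (`N = 5000`, `u` and `v`
#'     multiplied by 20). Rows vary `u`, `mean_affinity`, `d`, `c_hom` and
#'     `n_mei`.}
#' }
#'
#' @param name Preset name.
#' @param rescale Extra rescaling factor: divides `N` and multiplies `u` and
#'   `v` by `rescale`, leaving `4Nu`, `4Nv` (and approximately the
#'   equilibrium diversity, erosion and selection statistics) invariant.
#' @param ... Overrides passed on to [sim_config()] (e.g. `generations`,
#'   `seed`, `mode`).
#' @return An `rq_config`.
#' @export
preset <- function(name, rescale = 1, ...) {
  cal <- function(u, ybar, d, c_hom, n_mei) {
    list(N = 5000, u = u * 20, v = 1e-7 * 20, h = 800, d = d,
         mean_affinity = ybar, c_hom = c_hom, n_mei = n_mei)
  }
  base <- switch(
    name,
    scaling_reference = list(N = 5000, u = 5e-5, v = 2e-6, h = 400, d = 6,
                             mean_affinity = 0.2, c_hom = 1, n_mei = 1),
    monomorphic_example = list(N = 5000, u = 5e-6, v = 5e-5, h = 400, d = 6,
                            mean_affinity = 0.2, c_hom = 1, n_mei = 1),
    polymorphic_example = list(N = 5000, u = 5e-4, v = 5e-5, h = 400, d = 6,
                            mean_affinity = 0.2, c_hom = 1, n_mei = 1),
    dosage_example = list(N = 5000, u = 5e-4, v = 5e-5, h = 400, d = 6,
                       mean_affinity = 0.2, c_hom = 2, n_mei = 1),
    calibration_row1 = cal(3e-6, 0.2, 8, 2, 1),
    calibration_row2 = cal(3e-6, 0.44, 8, 1, 1),
    calibration_row3 = cal(3e-6, 0.3, 8, 1.5, 1),
    calibration_row4 = cal(3e-5, 0.2, 8, 2, 1),
    calibration_row5 = cal(3e-6, 2, 8, 2, 1),
    calibration_row6 = cal(3e-6, 0.2, 8, 2, 5),
    calibration_row7 = cal(3e-6, 0.2, 24, 2, 1),
    stop("unknown preset: ", name)
  )
  if (rescale != 1) {
    base$N <- as.integer(round(base$N / rescale))
    base$u <- base$u * rescale
    base$v <- base$v * rescale
  }
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}
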