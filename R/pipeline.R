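#' Full kinetic (k_obs) route to the equilibrium K_D
#'
#' Simulates one association trace per protein concentration, fits each with
#' \code{\link{fit_exponential}}, and regresses the fitted k_obs on
#' concentration with \code{\link{kinetic_kd}}. Each trace is read on a
#' schedule targeted at its expected rate (\code{\link{fp_design_times}}),
#' as one would after a pilot read; the rate estimation itself is blind to
#' the truth.
#'
#' @param truth an \code{\link{fp_truth}} (the planted condition).
#' @param protein_concs protein concentrations (nM); default eight points
#'   spanning 0.25--8 times the planted K_D.
#' @param n_timepoints reads per trace; default 12.
#' @param seed integer seed.
#' @return a \code{\link{kinetic_kd}} fit.
#' @export
fp_kinetic_pipeline <- function(truth,
                                protein_concs = truth$K_D *
                                  c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
                                n_timepoints = 12, seed = 1L) {
  stopifnot(inherits(truth, "fp_truth"))
  k_exp <- truth$k_a * protein_concs * 1e-9 + truth$k_d
  kobs <- vapply(seq_along(protein_concs), function(i) {
    tr <- simulate_fp_timecourses(truth, protein_concs[i],
                                  fp_design_times(k_exp[i], n_timepoints),
                                  mode = "association",
                                  seed = seed * 1000L + i)[[1]]
    fit_exponential(tr, "association")$K
  }, numeric(1))
  kinetic_kd(data.frame(protein_nM = protein_concs, kobs = kobs))
}

#' Three-route FP K_D determination with concordance check
#'
#' Runs the three orthogonal routes to the probe K_D on simulated data from
#' one planted truth: (1) the saturation binding isotherm with
#' depletion-aware fitting, (2) the k_obs kinetic analysis
#' (\code{\link{fp_kinetic_pipeline}}), and (3) a dissociation-by-
#' displacement experiment whose fitted off-rate is divided by the kinetic
#' route's association rate constant. Returns the three estimates and their
#' \code{\link{kd_concordance}}.
#'
#' @param truth an \code{\link{fp_truth}}.
#' @param seed integer seed.
#' @param titration_concs protein titration for the saturation route;
#'   default a two-fold ladder spanning 1/16 to 32 times the planted K_D.
#' @param dissociation_protein protein concentration pre-equilibrated with
#'   the probe before displacement (nM); default 20.
#' @param fold_threshold concordance pass threshold; default 2.
#' @return list with elements \code{saturation}, \code{kinetic},
#'   \code{dissociation} (fit objects), \code{kds} (named vector, nM) and
#'   \code{concordance}.
#' @export
fp_three_route_kd <- function(truth, seed = 1L,
                              titration_concs = truth$K_D * 2^seq(-4, 5),
                              dissociation_protein = 20,
                              fold_threshold = 2) {
  stopifnot(inherits(truth, "fp_truth"))
  iso <- simulate_binding_isotherm(truth, titration_concs,
                                   depletion = "on", seed = seed * 1000L + 91L)
  sat <- fit_saturation(iso, probe_conc = truth$probe_conc,
                        model = "depletion")
  kin <- fp_kinetic_pipeline(truth, seed = seed)
  dis_tr <- simulate_fp_timecourses(truth, dissociation_protein,
                                    fp_design_times(truth$k_d),
                                    mode = "dissociation",
                                    seed = seed * 1000L + 92L)[[1]]
  dis <- fit_exponential(dis_tr, "dissociation")
  kds <- c(saturation = sat$Kd,
           kinetic = kin$K_D,
           dissociation = dis$K / kin$k_a * 1e9)
  list(saturation = sat, kinetic = kin, dissociation = dis, kds = kds,
       concordance = kd_concordance(kds, fold_threshold = fold_threshold))
}
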