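#' Simulate an affinity selection of a DEL against a cofactor-loaded target
#'
#' For every library compound the per-round capture probability is
#' \code{p = bg + (1 - bg) * f_bound}, where \code{f_bound} is the bound
#' fraction at the selection protein concentration given the compound's
#' apparent K_D under the condition's cofactor (via the cooperative
#' ternary-complex closed form), and \code{bg} is the nonspecific background
#' capture rate. Rounds compound multiplicatively (\code{w = p^rounds}) and
#' sequencing depth is allocated by (Dirichlet-)multinomial sampling over the
#' normalised weights. Nonbinders have \code{f_bound = 0}. Under the SAM
#' condition a fixed fraction of the nominal SAM is treated as contaminating
#' MTA.
#'
#' @param library a \code{\link{gen_library}} result.
#' @param truth a \code{\link{ground_truth}}.
#' @param config a \code{\link{selection_config}}.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a \code{\link{count_table}} with one count column per condition.
#' @export
simulate_selection <- function(library, truth, config, seed = 1L) {
  stopifnot(inherits(library, "del_library"),
            inherits(truth, "del_ground_truth"),
            inherits(config, "selection_config"))
  n <- nrow(library$bb)
  bg <- truth$background_capture

  kd_app <- matrix(Inf, n, length(config$conditions),
                   dimnames = list(NULL, config$conditions))
  for (s in truth$series) {
    sel <- rep(TRUE, n)
    for (p in names(s$positions)) {
      if (!p %in% names(library$bb))
        stop("planted series position ", p, " not in library")
      sel <- sel & library$bb[[p]] == s$positions[[p]]
    }
    if (!any(sel))
      stop("planted series matches no library compound")
    for (cond in config$conditions) {
      kd <- .series_kd_under(s, cond, config)
      kd_app[sel, cond] <- pmin(kd_app[sel, cond], kd)
    }
  }

  f_bound <- config$protein_conc / (config$protein_conc + kd_app)
  f_bound[is.na(f_bound)] <- 0          # Inf K_D -> nonbinder
  p <- bg + (1 - bg) * f_bound
  w <- p^config$rounds

  counts <- with_seed(seed, {
    sapply(config$conditions, function(cond) {
      wn <- w[, cond] / sum(w[, cond])
      if (config$depth == 0) return(integer(n))
      if (config$dispersion > 0) {
        g <- stats::rgamma(n, shape = wn / config$dispersion)
        if (sum(g) == 0) g <- wn
        wn <- g / sum(g)
      }
      as.integer(stats::rmultinom(1, config$depth, wn))
    })
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = n)
  colnames(counts) <- config$conditions
  count_table(bb = library$bb, counts = counts,
              totals = stats::setNames(rep(config$depth,
                                           length(config$conditions)),
                                       config$conditions))
}

# Apparent K_D of a planted series under one selection condition.
.series_kd_under <- function(series, cond, config) {
  a_of <- function(nm) if (nm %in% names(series$alpha)) series$alpha[[nm]] else 1
  kc <- config$cofactor_kc
  if (cond == "none") return(series$kd_apo)
  if (cond %in% c("MTA", "SIN"))
    return(.apparent_kd_multi(series$kd_apo, config$cofactor_conc,
                              kc[[cond]], a_of(cond)))
  if (cond == "SAM") {
    f <- config$sam_mta_contamination
    return(.apparent_kd_multi(
      series$kd_apo,
      conc  = c((1 - f) * config$cofactor_conc, f * config$cofactor_conc),
      K     = c(kc[["SAM"]], kc[["MTA"]]),
      alpha = c(a_of("SAM"), a_of("MTA"))))
  }
  stop("unknown cofactor condition: ", cond)
}

#' Two-state melt-curve parameters
#'
#' @param Tm melting midpoint, deg C (in [25, 95]).
#' @param slope transition width parameter (K, > 0) of the logistic.
#' @param F_folded,F_unfolded baseline fluorescence of the folded and
#'   unfolded states (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (signal units).
#' @param T_grid temperatures read, deg C; default one reading per 0.5 deg C
#'   over 25--95, mirroring a 0.5 deg C/min ramp.
#' @return object of class \code{melt_params}.
#' @export
melt_params <- function(Tm, slope = 1.5, F_folded = 1000, F_unfolded = 10000,
                        noise_sd = 0, T_grid = seq(25, 95, by = 0.5)) {
  stopifnot(Tm >= 25, Tm <= 95, slope > 0, noise_sd >= 0)
  if (!length(T_grid)) stop("empty temperature grid")
  structure(list(Tm = Tm, slope = slope, F_folded = F_folded,
                 F_unfolded = F_unfolded, noise_sd = noise_sd,
                 T_grid = T_grid),
            class = "melt_params")
}

#' Simulate a two-state thermal melt curve
#'
#' \code{F(T) = F_folded + (F_unfolded - F_folded) / (1 + exp((Tm - T)/slope))}
#' plus Gaussian noise. The noiseless curve passes through the midpoint
#' signal exactly at \code{T = Tm}.
#'
#' @param params a \code{\link{melt_params}}.
#' @param seed integer seed (only used when \code{noise_sd > 0}).
#' @param condition label stored on the curve.
#' @return a \code{\link{melt_curve}}.
#' @export
simulate_melt_curve <- function(params, seed = 1L, condition = "") {
  stopifnot(inherits(params, "melt_params"))
  f <- params$F_folded + (params$F_unfolded - params$F_folded) /
    (1 + exp((params$Tm - params$T_grid) / params$slope))
  if (params$noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, params$noise_sd))
  melt_curve(params$T_grid, f, condition = condition)
}

#' Ground truth for fluorescence-polarization simulations
#'
#' @param K_D equilibrium dissociation constant (nM, > 0).
#' @param k_a association rate constant (M^-1 s^-1, > 0); the implied
#'   dissociation rate is \code{k_d = K_D * 1e-9 * k_a} (s^-1).
#' @param probe_conc fluorescent probe concentration (nM).
#' @param mP_free,mP_bound polarization of free and fully bound probe (mP).
#' @param noise_sd additive Gaussian noise SD (mP).
#' @return object of class \code{fp_truth}.
#' @export
fp_truth <- function(K_D, k_a = 1e4, probe_conc = 1,
                     mP_free = 50, mP_bound = 150, noise_sd = 2) {
  stopifnot(K_D > 0, k_a > 0, probe_conc >= 0, noise_sd >= 0)
  structure(list(K_D = K_D, k_a = k_a, k_d = K_D * 1e-9 * k_a,
                 probe_conc = probe_conc, mP_free = mP_free,
                 mP_bound = mP_bound, noise_sd = noise_sd),
            class = "fp_truth")
}

#' Observation times for a kinetic FP trace
#'
#' Sampling schedule for a pseudo-first-order trace with expected observed
#' rate \code{k_obs}: a zero read, then points concentrated over the
#' exponential rise (0.2--1.2 of the characteristic time \code{1/k_obs})
#' with plateau anchors out to six characteristic times. Concentrating the
#' reads where the curvature lives minimises the variance of the fitted
#' rate for a fixed number of reads.
#'
#' @param k_obs expected observed rate of the trace (s^-1).
#' @param n number of timepoints (>= 8).
#' @return numeric vector of times (s), increasing, starting at 0.
#' @export
fp_design_times <- function(k_obs, n = 12) {
  stopifnot(k_obs > 0, n >= 8)
  fr <- c(seq(0.2, 1.2, length.out = n - 6), 1.5, 2, 3, 4.5, 6)
  c(0, fr / k_obs)
}

#' Simulate pseudo-first-order FP association or dissociation traces
#'
#' Association: \code{mP(t) = mP_free + (mP_eq - mP_free)(1 - exp(-k_obs t))}
#' with \code{k_obs = k_a [P] + k_d} and the plateau \code{mP_eq} from the
#' binding isotherm at \code{[P]} (free-ligand approximation; protein in
#' excess over probe). Dissociation: pre-equilibrated signal decaying to
#' \code{mP_free} at rate \code{k_d} after displacement by excess unlabeled
#' competitor.
#'
#' @param truth an \code{\link{fp_truth}}.
#' @param protein_concs protein concentrations (nM, >= 0), one trace each.
#' @param timepoints times (s), increasing, starting at 0.
#' @param mode \code{"association"} or \code{"dissociation"}.
#' @param seed integer seed.
#' @return list of \code{\link{fp_trace}} objects.
#' @export
simulate_fp_timecourses <- function(truth, protein_concs, timepoints,
                                    mode = c("association", "dissociation"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "fp_truth"))
  if (any(protein_concs < 0)) stop("negative protein concentrations")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing and start at 0")
  with_seed(seed, {
    lapply(seq_along(protein_concs), function(i) {
      P <- protein_concs[i]
      mP_eq <- truth$mP_free +
        (truth$mP_bound - truth$mP_free) * P / (P + truth$K_D)
      mp <- if (mode == "association") {
        k_obs <- truth$k_a * P * 1e-9 + truth$k_d
        truth$mP_free + (mP_eq - truth$mP_free) * (1 - exp(-k_obs * timepoints))
      } else {
        truth$mP_free + (mP_eq - truth$mP_free) * exp(-truth$k_d * timepoints)
      }
      if (truth$noise_sd > 0)
        mp <- mp + stats::rnorm(length(mp), 0, truth$noise_sd)
      fp_trace(timepoints, mp, protein_conc = P, condition = mode)
    })
  })
}

#' Simulate a saturation binding isotherm
#'
#' With depletion \code{"off"} the response follows the hyperbola
#' \code{Y = Bmax X / (K_D + X)} in the titrant's total concentration. With
#' depletion \code{"on"} the exact pairwise-binding quadratic is used for the
#' bound fraction of the fixed labeled species (probe or labeled protein) at
#' concentration \code{truth$probe_conc}, which matters whenever K_D is not
#' well above that concentration.
#'
#' @param truth an \code{\link{fp_truth}}; \code{mP_bound - mP_free} sets
#'   Bmax and \code{probe_conc} the fixed labeled-species concentration.
#' @param titration_concs total titrant concentrations (nM, >= 0).
#' @param depletion \code{"on"} or \code{"off"}.
#' @param seed integer seed.
#' @return a \code{\link{dose_response_curve}} of delta-signal vs titrant.
#' @export
simulate_binding_isotherm <- function(truth, titration_concs,
                                      depletion = c("on", "off"),
                                      seed = 1L) {
  depletion <- match.arg(depletion)
  stopifnot(inherits(truth, "fp_truth"), all(titration_concs >= 0))
  Bmax <- truth$mP_bound - truth$mP_free
  fb <- if (depletion == "off") {
    titration_concs / (titration_concs + truth$K_D)
  } else {
    bound_fraction_quadratic(titration_concs, truth$probe_conc, truth$K_D)
  }
  y <- Bmax * fb
  if (truth$noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, truth$noise_sd))
  dose_response_curve(titration_concs, y, condition = "isotherm")
}

#' Exact bound fraction of a fixed labeled species under ligand depletion
#'
#' Pairwise binding of titrant (total \code{X}) to a fixed species (total
#' \code{P}): the physical root of the binding quadratic, as a fraction of
#' \code{P}.
#'
#' @param X total titrant (nM, vectorised).
#' @param P total fixed labeled species (nM).
#' @param Kd dissociation constant (nM).
#' @return bound fraction in [0, 1].
#' @export
bound_fraction_quadratic <- function(X, P, Kd) {
  stopifnot(P > 0, Kd > 0, all(X >= 0))
  b <- P + X + Kd
  (b - sqrt(b^2 - 4 * P * X)) / (2 * P)
}

#' Ternary system for the enzymatic activity assay
#'
#' Encodes the methyltransferase reaction composition: enzyme, cosubstrate
#' SAM (modelled as a cofactor-site competitor whose ternary complex with
#' the inhibitor is sterically disallowed by default), optional added MTA,
#' and a fixed fraction of the nominal SAM present as contaminating MTA.
#'
#' @param K_I inhibitor apo dissociation constant (nM).
#' @param alpha MTA cooperativity factor.
#' @param E_t total enzyme (nM); default 4.
#' @param sam_nominal nominal SAM concentration (nM); default 5000.
#' @param mta_added exogenously added MTA (nM); default 0.
#' @param K_C MTA dissociation constant (nM); default 5000.
#' @param K_S SAM dissociation constant (nM); default 5000.
#' @param sam_mta_contamination fraction of nominal SAM present as MTA.
#' @param alpha_S inhibitor cooperativity with SAM-bound enzyme; default 0
#'   (steric clash).
#' @return a \code{\link{ternary_system}} with \code{I_t = 0}.
#' @export
activity_system <- function(K_I, alpha, E_t = 4, sam_nominal = 5000,
                            mta_added = 0, K_C = 5000, K_S = 5000,
                            sam_mta_contamination = 0.03, alpha_S = 0) {
  f <- sam_mta_contamination
  ternary_system(E_t = E_t,
                 C_t = mta_added + f * sam_nominal,
                 I_t = 0,
                 K_C = K_C, K_I = K_I, alpha = alpha,
                 competitor = list(S_t = (1 - f) * sam_nominal, K_S = K_S,
                                   alpha_S = alpha_S))
}

#' Simulate an enzymatic inhibition dose--response experiment
#'
#' The luminescence signal is proportional to the catalytically productive
#' enzyme fraction (\code{\link{fraction_active}}) at each total inhibitor
#' concentration, scaled to \code{top} counts with additive Gaussian noise.
#' Inhibitor depletion by the enzyme is handled exactly by the equilibrium
#' solver, so tight-binding behaviour (the IC50 floor at \code{E_t/2})
#' emerges naturally.
#'
#' @param system a \code{\link{ternary_system}} template (its \code{I_t} is
#'   replaced by each titration point), e.g. from
#'   \code{\link{activity_system}}.
#' @param inhibitor_concs total inhibitor concentrations (nM, >= 0).
#' @param seed integer seed.
#' @param top signal scale (luminescence counts at full activity).
#' @param noise_sd additive noise SD (signal units).
#' @return a \code{\link{dose_response_curve}}.
#' @export
simulate_activity_assay <- function(system, inhibitor_concs, seed = 1L,
                                    top = 1000, noise_sd = 10) {
  stopifnot(inherits(system, "ternary_system"), all(inhibitor_concs >= 0),
            noise_sd >= 0)
  fa <- vapply(inhibitor_concs, function(I) {
    s <- system; s$I_t <- I
    fraction_active(s)
  }, numeric(1))
  y <- top * fa
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  dose_response_curve(inhibitor_concs, y, condition = "activity")
}

#' Calibrate the planted inhibitor K_I to a target fitted IC50
#'
#' Finds the apo K_I for which the noiseless simulated activity curve,
#' fitted with \code{\link{fit_4pl}}, returns the requested IC50 under the
#' assay composition of \code{\link{activity_system}}. Used to plant
#' generator truths that reproduce a published IC50 under the full
#' tight-binding, cofactor-competition model.
#'
#' @param ic50_target target fitted IC50 (nM); must exceed the Morrison
#'   floor \code{E_t/2}.
#' @param alpha MTA cooperativity factor of the inhibitor.
#' @param ... further arguments passed to \code{\link{activity_system}}.
#' @param inhibitor_concs titration used during calibration; default a
#'   two-fold ladder around the target plus a zero anchor.
#' @return calibrated apo K_I (nM).
#' @export
activity_ki_for_ic50 <- function(ic50_target, alpha, ...,
                                 inhibitor_concs = NULL) {
  sys0 <- activity_system(K_I = 1, alpha = alpha, ...)
  if (ic50_target <= sys0$E_t / 2)
    stop("target IC50 is at or below the tight-binding floor E_t/2")
  if (is.null(inhibitor_concs))
    inhibitor_concs <- c(0, ic50_target * 2^seq(-4, 5))
  fitted_ic50 <- function(log10_ki) {
    sys <- activity_system(K_I = 10^log10_ki, alpha = alpha, ...)
    crv <- simulate_activity_assay(sys, inhibitor_concs, noise_sd = 0)
    coef(fit_4pl(crv))[["ic50"]]
  }
  r <- stats::uniroot(function(lk) fitted_ic50(lk) - ic50_target,
                      interval = log10(ic50_target) + c(-3, 3),
                      extendInt = "upX", tol = 1e-10)
  10^r$root
}
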