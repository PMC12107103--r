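#' Cooperative ternary-complex equilibrium system
#'
#' Describes an enzyme--cofactor--inhibitor equilibrium under mass action,
#' with an optional second cofactor-site ligand (e.g. the cosubstrate SAM)
#' competing for the cofactor pocket. The cooperativity factor \code{alpha}
#' couples cofactor and inhibitor binding: the inhibitor dissociation
#' constant from the cofactor-bound enzyme is \code{K_I / alpha}, so
#' \code{alpha > 1} means cofactor-potentiated ("molecular glue") binding.
#'
#' Species considered: free enzyme E, binary complexes EC, EI, ES, ternary
#' complexes ECI and (if \code{alpha_S > 0}) ESI, plus free C, I, S. All
#' concentrations are in nM.
#'
#' @param E_t total enzyme (nM).
#' @param C_t total cofactor (nM), e.g. MTA.
#' @param I_t total inhibitor (nM).
#' @param K_C cofactor binary dissociation constant (nM).
#' @param K_I inhibitor binary dissociation constant for the apo enzyme (nM).
#' @param alpha cooperativity factor (> 0); \code{K_D(I | E.C) = K_I/alpha}.
#' @param competitor optional list with elements \code{S_t}, \code{K_S} and
#'   optionally \code{alpha_S} (default 0) describing a second cofactor-site
#'   ligand. \code{alpha_S = 0} forbids the S-containing ternary complex,
#'   encoding a steric clash between that ligand and the inhibitor.
#' @return an object of class \code{ternary_system}.
#' @examples
#' sys <- ternary_system(E_t = 4, C_t = 1000, I_t = 10,
#'                       K_C = 5000, K_I = 754, alpha = 19.84)
#' solve_equilibrium(sys)
#' @export
ternary_system <- function(E_t, C_t, I_t, K_C, K_I, alpha = 1,
                           competitor = NULL) {
  stopifnot(E_t >= 0, C_t >= 0, I_t >= 0, K_C > 0, K_I > 0, alpha > 0)
  if (!is.null(competitor)) {
    stopifnot(is.list(competitor), competitor$S_t >= 0, competitor$K_S > 0)
    if (is.null(competitor$alpha_S)) competitor$alpha_S <- 0
    stopifnot(competitor$alpha_S >= 0)
  }
  structure(list(E_t = E_t, C_t = C_t, I_t = I_t,
                 K_C = K_C, K_I = K_I, alpha = alpha,
                 competitor = competitor),
            class = "ternary_system")
}

#' @export
print.ternary_system <- function(x, ...) {
  cat("Ternary equilibrium system (nM)\n")
  cat(sprintf("  totals: E_t = %g, C_t = %g, I_t = %g\n", x$E_t, x$C_t, x$I_t))
  cat(sprintf("  constants: K_C = %g, K_I = %g, alpha = %g\n",
              x$K_C, x$K_I, x$alpha))
  if (!is.null(x$competitor))
    cat(sprintf("  competitor: S_t = %g, K_S = %g, alpha_S = %g\n",
                x$competitor$S_t, x$competitor$K_S, x$competitor$alpha_S))
  invisible(x)
}

# Concentrations of all complexes given free (E, C, I, S) under mass action.
.species_from_free <- function(sys, E, C, I, S) {
  aS <- if (is.null(sys$competitor)) 0 else sys$competitor$alpha_S
  KS <- if (is.null(sys$competitor)) Inf else sys$competitor$K_S
  list(E = E, C = C, I = I, S = S,
       EC  = E * C / sys$K_C,
       EI  = E * I / sys$K_I,
       ECI = sys$alpha * E * C * I / (sys$K_C * sys$K_I),
       ES  = if (is.finite(KS)) E * S / KS else 0,
       ESI = if (is.finite(KS)) aS * E * S * I / (KS * sys$K_I) else 0)
}

.mass_balance_residuals <- function(sys, sp) {
  S_t <- if (is.null(sys$competitor)) 0 else sys$competitor$S_t
  tot <- c(E = sys$E_t, C = sys$C_t, I = sys$I_t, S = S_t)
  got <- c(E = sp$E + sp$EC + sp$EI + sp$ECI + sp$ES + sp$ESI,
           C = sp$C + sp$EC + sp$ECI,
           I = sp$I + sp$EI + sp$ECI + sp$ESI,
           S = sp$S + sp$ES + sp$ESI)
  abs(got - tot) / pmax(tot, 1)     # relative where total >= 1 nM, absolute below
}

#' Solve the ternary-complex equilibrium
#'
#' Computes equilibrium concentrations of all species by a damped fixed-point
#' iteration on the free concentrations, with a nested root-bracketing
#' fallback. The mass-action system has a unique physical root; convergence is
#' declared when every mass-balance residual is below \code{tol} (relative for
#' totals above 1 nM, absolute below).
#'
#' @param sys a \code{\link{ternary_system}}.
#' @param tol residual tolerance; default \code{1e-12}, deliberately tighter
#'   than the \code{1e-9} the downstream contracts assume.
#' @param max_iter iteration cap for the fixed-point stage.
#' @return object of class \code{species_state}: equilibrium concentrations
#'   (nM) of \code{E, C, I, S, EC, EI, ECI, ES, ESI} plus the residuals.
#' @export
solve_equilibrium <- function(sys, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(sys, "ternary_system"))
  S_t <- if (is.null(sys$competitor)) 0 else sys$competitor$S_t
  KS  <- if (is.null(sys$competitor)) Inf else sys$competitor$K_S
  aS  <- if (is.null(sys$competitor)) 0 else sys$competitor$alpha_S
  KC <- sys$K_C; KI <- sys$K_I; a <- sys$alpha

  E <- sys$E_t; C <- sys$C_t; I <- sys$I_t; S <- S_t
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E_new <- if (sys$E_t == 0) 0 else
      sys$E_t / (1 + C / KC + I / KI + a * C * I / (KC * KI) +
                   (if (is.finite(KS)) S / KS + aS * S * I / (KS * KI) else 0))
    C_new <- if (sys$C_t == 0) 0 else
      sys$C_t / (1 + E_new / KC * (1 + a * I / KI))
    S_new <- if (S_t == 0) 0 else
      S_t / (1 + E_new / KS * (1 + aS * I / KI))
    I_new <- if (sys$I_t == 0) 0 else
      sys$I_t / (1 + E_new / KI + a * E_new * C_new / (KC * KI) +
                   (if (is.finite(KS)) aS * E_new * S_new / (KS * KI) else 0))
    # geometric damping keeps iterates positive and tames oscillation
    E <- if (E > 0 && E_new > 0) sqrt(E * E_new) else E_new
    C <- if (C > 0 && C_new > 0) sqrt(C * C_new) else C_new
    I <- if (I > 0 && I_new > 0) sqrt(I * I_new) else I_new
    S <- if (S > 0 && S_new > 0) sqrt(S * S_new) else S_new
    sp <- .species_from_free(sys, E, C, I, S)
    res <- .mass_balance_residuals(sys, sp)
    if (max(res) <= tol) { converged <- TRUE; break }
  }
  if (!converged) {
    out <- .solve_equilibrium_nested(sys, tol)
    sp <- out$sp; res <- out$res
    if (max(res) > 1e-9)
      stop(sprintf("equilibrium solver failed to converge (max residual %.3g)",
                   max(res)))
  }
  structure(c(sp, list(residuals = res,
                       converged = TRUE,
                       iterations = it)),
            class = "species_state")
}

# Fallback: outer root-bracketing on free E; inner on free I; C and S are
# closed-form given (E, I). Monotone in the bracket, so uniroot is safe.
.solve_equilibrium_nested <- function(sys, tol = 1e-12) {
  S_t <- if (is.null(sys$competitor)) 0 else sys$competitor$S_t
  KS  <- if (is.null(sys$competitor)) Inf else sys$competitor$K_S
  aS  <- if (is.null(sys$competitor)) 0 else sys$competitor$alpha_S
  KC <- sys$K_C; KI <- sys$K_I; a <- sys$alpha

  C_of <- function(E, I) if (sys$C_t == 0) 0 else
    sys$C_t / (1 + E / KC * (1 + a * I / KI))
  S_of <- function(E, I) if (S_t == 0) 0 else
    S_t / (1 + E / KS * (1 + aS * I / KI))
  I_free <- function(E) {
    if (sys$I_t == 0) return(0)
    g <- function(I)
      I * (1 + E / KI + a * E * C_of(E, I) / (KC * KI) +
             (if (is.finite(KS)) aS * E * S_of(E, I) / (KS * KI) else 0)) -
        sys$I_t
    stats::uniroot(g, c(0, sys$I_t), tol = .Machine$double.eps^0.9)$root
  }
  e_res <- function(E) {
    I <- I_free(E); C <- C_of(E, I); S <- S_of(E, I)
    E * (1 + C / KC + I / KI + a * C * I / (KC * KI) +
           (if (is.finite(KS)) S / KS + aS * S * I / (KS * KI) else 0)) - sys$E_t
  }
  E <- if (sys$E_t == 0) 0 else
    stats::uniroot(e_res, c(0, sys$E_t), tol = .Machine$double.eps^0.9)$root
  I <- I_free(E); C <- C_of(E, I); S <- S_of(E, I)
  sp <- .species_from_free(sys, E, C, I, S)
  list(sp = sp, res = .mass_balance_residuals(sys, sp))
}

#' @export
print.species_state <- function(x, digits = 4, ...) {
  cat("Equilibrium species (nM)\n")
  v <- unlist(x[c("E", "EC", "EI", "ECI", "ES", "ESI", "C", "I", "S")])
  print(signif(v, digits))
  cat(sprintf("max mass-balance residual: %.3g\n", max(x$residuals)))
  invisible(x)
}

#' Apparent inhibitor dissociation constant at a given free-cofactor level
#'
#' Closed form for the inhibitor K_D observed at free cofactor concentration
#' \code{C_free}:
#' \deqn{K_{D,app} = K_I \frac{1 + C/K_C}{1 + \alpha C/K_C}}
#' It interpolates between the apo value \code{K_I} (at C = 0) and the
#' cofactor-saturated value \code{K_I/alpha} (as C grows).
#'
#' @param K_I apo inhibitor dissociation constant (nM).
#' @param K_C cofactor dissociation constant (nM).
#' @param alpha cooperativity factor (> 0).
#' @param C_free free cofactor concentration (nM, >= 0). Vectorised.
#' @return apparent K_D (nM).
#' @export
apparent_kd <- function(K_I, K_C, alpha, C_free) {
  stopifnot(K_I > 0, K_C > 0, alpha > 0, all(C_free >= 0))
  K_I * (1 + C_free / K_C) / (1 + alpha * C_free / K_C)
}

# Generalisation used by the generators: several ligands share the cofactor
# site (e.g. MTA plus contaminating/competing SAM), each with its own K and
# cooperativity with the inhibitor.
.apparent_kd_multi <- function(K_I, conc, K, alpha) {
  stopifnot(length(conc) == length(K), length(K) == length(alpha))
  K_I * (1 + sum(conc / K)) / (1 + sum(alpha * conc / K))
}

#' Cooperativity factor from two dissociation constants
#'
#' \code{alpha = kd_apo / kd_saturated}: the fold-tightening of inhibitor
#' binding brought by cofactor occupancy. Scale-invariant; 1 means no
#' cooperativity.
#'
#' @param kd_apo K_D against the apo enzyme (nM, > 0).
#' @param kd_saturated K_D against the cofactor-saturated enzyme (nM, > 0).
#' @return the dimensionless cooperativity factor.
#' @examples
#' cooperativity_factor(754, 38)   # ~19.8
#' @export
cooperativity_factor <- function(kd_apo, kd_saturated) {
  if (any(kd_apo <= 0) || any(kd_saturated <= 0))
    stop("dissociation constants must be positive")
  kd_apo / kd_saturated
}

#' Fraction of catalytically productive enzyme
#'
#' Productive enzyme is the cosubstrate-bound, inhibitor-free species ES;
#' the activity readout of the enzymatic assay is taken proportional to
#' \code{ES / E_t} at pseudo-equilibrium.
#'
#' @param sys a \code{\link{ternary_system}} whose \code{competitor} slot
#'   holds the cosubstrate (S); required.
#' @return fraction in [0, 1].
#' @export
fraction_active <- function(sys) {
  stopifnot(inherits(sys, "ternary_system"))
  if (is.null(sys$competitor))
    stop("fraction_active requires a cosubstrate competitor in the system")
  if (sys$E_t <= 0) stop("E_t must be positive for an activity readout")
  st <- solve_equilibrium(sys)
  st$ES / sys$E_t
}

#' Tight-binding (Morrison) IC50 correction
#'
#' In the tight-binding regime the measured IC50 cannot fall below half the
#' enzyme concentration: \code{IC50 = K_D_app + E_t/2}.
#'
#' @param E_t total enzyme (nM, >= 0).
#' @param K_D_app apparent inhibitor dissociation constant (nM, >= 0).
#' @return predicted IC50 (nM).
#' @examples
#' morrison_ic50(4, 3)   # 5 nM
#' morrison_ic50(4, 0)   # 2 nM floor
#' @export
morrison_ic50 <- function(E_t, K_D_app) {
  stopifnot(all(E_t >= 0), all(K_D_app >= 0))
  K_D_app + E_t / 2
}
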