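#' Fluorescence-polarization time trace
#'
#' @param times observation times, strictly increasing; association traces
#'   must start at 0. At least 4 points.
#' @param mP millipolarization readings.
#' @param protein_conc protein concentration for the trace (nM).
#' @param condition label.
#' @param time_unit \code{"s"} (default) or \code{"min"}; minute input is
#'   converted to seconds on construction so downstream rates are s^-1.
#' @return object of class \code{fp_trace}.
#' @export
fp_trace <- function(times, mP, protein_conc = NA_real_, condition = "",
                     time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  if (time_unit == "min") times <- times * 60
  stopifnot(length(times) == length(mP), length(times) >= 4,
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, mP = mP, protein_conc = protein_conc,
                 condition = condition),
            class = "fp_trace")
}

#' Fit a single-exponential association or dissociation trace
#'
#' Association: \code{Y = Y0 + (Plateau - Y0)(1 - exp(-K t))}; dissociation:
#' \code{Y = (Y0 - Plateau) exp(-K t) + Plateau}. Both are the same
#' exponential approach \code{Y = Plateau + (Y0 - Plateau) exp(-K t)}; the
#' mode determines the interpretation of \code{K} (k_obs vs k_d). Fitted by
#' Levenberg--Marquardt least squares with a log-linear start for \code{K}.
#'
#' @param trace an \code{\link{fp_trace}}.
#' @param mode \code{"association"} or \code{"dissociation"}.
#' @return object of class \code{exponential_fit}: \code{Y0},
#'   \code{plateau}, \code{K} (s^-1), standard errors, residual sum of
#'   squares, and a \code{flag} that is non-NULL when K <= 0 at the optimum.
#' @export
fit_exponential <- function(trace, mode = c("association", "dissociation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fp_trace"))
  t <- trace$times; y <- trace$mP
  if (mode == "association" && t[1] != 0)
    stop("association traces must start at t = 0")
  y0_s <- y[1]; pl_s <- mean(y[t >= stats::quantile(t, 0.8)])
  span <- max(diff(range(y)), .Machine$double.eps)
  if (abs(pl_s - y0_s) < 0.05 * span)
    pl_s <- y0_s + sign(pl_s - y0_s + .Machine$double.eps) * 0.05 * span
  # log-linear start for K from the decaying residual amplitude
  z <- (y - pl_s) / (y0_s - pl_s)
  ok <- is.finite(z) & z > 1e-6 & t > 0
  t_pos <- t[t > 0]
  k_s <- if (sum(ok) >= 2) {
    -unname(stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2])
  } else 1 / max(t_pos)
  # keep the start inside the resolvable rate window of the time grid
  k_s <- min(max(k_s, 0.1 / max(t_pos), 1e-8), 5 / min(t_pos))
  one_fit <- function(ks) tryCatch(
    minpack.lm::nlsLM(
      y ~ plateau + (Y0 - plateau) * exp(-K * t),
      start = list(Y0 = y0_s, plateau = pl_s, K = ks),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  fit <- NULL
  for (ks in k_s * c(1, 0.1, 10, 0.01)) {
    cand <- one_fit(ks)
    if (!is.null(cand) &&
        (is.null(fit) ||
         sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2)))
      fit <- cand
  }
  if (is.null(fit)) stop("exponential fit failed to converge")
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, 3))
  flag <- if (cf[["K"]] <= 0) "nonpositive rate at optimum" else NULL
  if (!is.null(flag)) warning("fit_exponential: ", flag)
  structure(list(Y0 = cf[["Y0"]], plateau = cf[["plateau"]], K = cf[["K"]],
                 se = stats::setNames(se, c("Y0", "plateau", "K")),
                 rss = sum(stats::residuals(fit)^2), mode = mode,
                 flag = flag, trace = trace, nls = fit),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential %s fit: K = %.6g s^-1 (%.4g min^-1)\n",
              x$mode, x$K, per_s_to_per_min(x$K)))
  cat(sprintf("  Y0 = %.4g mP, plateau = %.4g mP, RSS = %.4g\n",
              x$Y0, x$plateau, x$rss))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.exponential_fit <- function(object, ...)
  c(Y0 = object$Y0, plateau = object$plateau, K = object$K)

#' @export
predict.exponential_fit <- function(object, times = object$trace$times, ...)
  object$plateau + (object$Y0 - object$plateau) * exp(-object$K * times)

#' @export
residuals.exponential_fit <- function(object, ...)
  object$trace$mP - predict(object)

#' @export
plot.exponential_fit <- function(x, ...) {
  graphics::plot(x$trace$times, x$trace$mP, xlab = "time (s)", ylab = "mP",
                 main = sprintf("%s, K = %.3g s^-1", x$mode, x$K), ...)
  tt <- seq(min(x$trace$times), max(x$trace$times), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Kinetic K_D from the k_obs-versus-concentration line
#'
#' Under pseudo-first-order conditions \code{k_obs = k_a [P] + k_d}; an
#' unweighted ordinary least-squares line through the per-concentration
#' \code{k_obs} values gives \code{k_a} (slope) and \code{k_d} (intercept),
#' and the equilibrium constant follows on dimensional grounds as
#' \code{K_D = k_d / k_a}. Standard errors are propagated to K_D by the
#' delta method.
#'
#' @param kobs_by_conc data.frame with columns \code{protein_nM} and
#'   \code{kobs} (s^-1); at least 3 concentrations (2 for an exact line).
#' @param weights optional per-point weights for weighted least squares.
#' @return object of class \code{kinetic_fit}: \code{k_a} (M^-1 s^-1),
#'   \code{k_d} (s^-1), \code{K_D} (nM), standard errors, and a flag when
#'   the intercept is negative (K_D undefined).
#' @export
kinetic_kd <- function(kobs_by_conc, weights = NULL) {
  stopifnot(is.data.frame(kobs_by_conc),
            all(c("protein_nM", "kobs") %in% names(kobs_by_conc)))
  if (nrow(kobs_by_conc) < 2) stop("need at least 2 concentrations")
  if (any(kobs_by_conc$kobs <= 0)) stop("k_obs values must be positive")
  fit <- stats::lm(kobs ~ protein_nM, data = kobs_by_conc, weights = weights)
  cf <- stats::coef(fit)
  k_d <- unname(cf[1])                       # s^-1
  slope <- unname(cf[2])                     # s^-1 per nM
  k_a <- slope * 1e9                         # M^-1 s^-1
  flag <- NULL
  if (slope <= 0) { flag <- "nonpositive slope; k_a undefined" }
  if (k_d < 0) { flag <- paste(c(flag, "negative intercept; K_D undefined"),
                               collapse = "; ") }
  K_D <- if (is.null(flag)) k_d / slope else NA_real_      # nM
  V <- tryCatch(suppressWarnings(stats::vcov(fit)),
                error = function(e) matrix(NA, 2, 2))
  se_kd <- if (is.null(flag) && all(is.finite(V))) {
    g <- c(1 / slope, -k_d / slope^2)        # d(K_D)/d(intercept, slope)
    sqrt(drop(t(g) %*% V %*% g))
  } else NA_real_
  if (!is.null(flag)) warning("kinetic_kd: ", flag)
  structure(list(k_a = k_a, k_d = k_d, K_D = K_D,
                 se = c(k_a = sqrt(V[2, 2]) * 1e9, k_d = sqrt(V[1, 1]),
                        K_D = se_kd),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 flag = flag, data = kobs_by_conc, lm = fit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic K_D from k_obs line\n")
  cat(sprintf("  k_a = %.4g M^-1 s^-1, k_d = %.4g s^-1, K_D = %.4g nM\n",
              x$k_a, x$k_d, x$K_D))
  cat(sprintf("  R^2 = %.5f over %d concentrations\n",
              x$r_squared, nrow(x$data)))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...)
  c(k_a = object$k_a, k_d = object$k_d, K_D = object$K_D)

#' @export
plot.kinetic_fit <- function(x, ...) {
  graphics::plot(x$data$protein_nM, x$data$kobs, xlab = "[protein] (nM)",
                 ylab = expression(k[obs] ~ (s^-1)),
                 main = sprintf("K_D = %.3g nM", x$K_D), ...)
  graphics::abline(x$lm)
  invisible(x)
}

#' Fit a saturation binding isotherm
#'
#' \code{model = "simple"}: the one-site hyperbola
#' \code{Y = Bmax X / (Kd + X)} in total titrant. \code{model =
#' "depletion"}: the exact pairwise-binding quadratic at fixed labeled
#' species \code{probe_conc}, required whenever Kd is not well above the
#' probe concentration (a warning is raised if the simple model is used in
#' that regime). \code{model = "double_reciprocal"}: the linearised
#' double-reciprocal (Lineweaver--Burk-style) fit, offered as a diagnostic.
#'
#' @param curve a \code{\link{dose_response_curve}} (x = titrant nM,
#'   y = specific signal).
#' @param probe_conc fixed labeled-species concentration (nM); needed for
#'   the depletion model and the bias warning.
#' @param model \code{"simple"}, \code{"depletion"} or
#'   \code{"double_reciprocal"}.
#' @return object of class \code{saturation_fit}: \code{Kd} (nM),
#'   \code{Bmax}, standard errors, residual sum of squares, model used.
#' @export
fit_saturation <- function(curve, probe_conc = NULL,
                           model = c("simple", "depletion",
                                     "double_reciprocal")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "dose_response_curve"))
  X <- curve$concentrations; Y <- curve$responses
  if (length(unique(X)) < 4) stop("need at least 4 distinct concentrations")
  if (diff(range(Y)) < .Machine$double.eps * 100 * max(1, abs(mean(Y))))
    stop("no binding signal (responses are constant)")
  if (model == "depletion" && is.null(probe_conc))
    stop("depletion model needs probe_conc")

  if (model == "double_reciprocal") {
    ok <- X > 0 & Y > 0
    lf <- stats::lm(I(1 / Y[ok]) ~ I(1 / X[ok]))
    Bmax <- 1 / unname(stats::coef(lf)[1])
    Kd <- unname(stats::coef(lf)[2]) * Bmax
    return(structure(list(Kd = Kd, Bmax = Bmax, se = c(Kd = NA, Bmax = NA),
                          rss = sum(stats::residuals(lf)^2), model = model,
                          probe_conc = probe_conc, curve = curve),
                     class = "saturation_fit"))
  }

  kd_s <- max(min(X[X > 0]),
              X[which.min(abs(Y - max(Y) / 2))])
  bm_s <- max(Y)
  fit <- if (model == "simple") {
    minpack.lm::nlsLM(Y ~ Bmax * X / (Kd + X),
                      start = list(Bmax = bm_s, Kd = kd_s),
                      lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15,
                                                           ptol = 1e-15))
  } else {
    minpack.lm::nlsLM(
      Y ~ Bmax * bound_fraction_quadratic(X, probe_conc, Kd),
      start = list(Bmax = bm_s, Kd = kd_s),
      lower = c(0, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, 2))
  if (model == "simple" && !is.null(probe_conc) && cf[["Kd"]] < 3 * probe_conc)
    warning(sprintf(paste("fitted Kd (%.3g nM) is not well above the probe",
                          "concentration (%.3g nM); use the depletion model"),
                    cf[["Kd"]], probe_conc))
  structure(list(Kd = cf[["Kd"]], Bmax = cf[["Bmax"]],
                 se = stats::setNames(se, c("Bmax", "Kd")),
                 rss = sum(stats::residuals(fit)^2), model = model,
                 probe_conc = probe_conc, curve = curve, nls = fit),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation binding fit (%s model)\n", x$model))
  cat(sprintf("  Kd = %.4g nM, Bmax = %.4g, RSS = %.4g\n",
              x$Kd, x$Bmax, x$rss))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...)
  c(Kd = object$Kd, Bmax = object$Bmax)

#' @export
predict.saturation_fit <- function(object, X = object$curve$concentrations,
                                   ...) {
  if (object$model == "depletion")
    object$Bmax * bound_fraction_quadratic(X, object$probe_conc, object$Kd)
  else object$Bmax * X / (object$Kd + X)
}

#' @export
residuals.saturation_fit <- function(object, ...)
  object$curve$responses - predict(object)

#' @export
plot.saturation_fit <- function(x, ...) {
  graphics::plot(x$curve$concentrations, x$curve$responses,
                 xlab = "[titrant] (nM)", ylab = "signal",
                 main = sprintf("Kd = %.3g nM (%s)", x$Kd, x$model), ...)
  xx <- seq(0, max(x$curve$concentrations), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  invisible(x)
}

#' Concordance report across independent K_D determinations
#'
#' The orthogonal routes to K_D (saturation isotherm, k_obs kinetics,
#' dissociation-by-displacement) should agree; this reports their geometric
#' mean, the maximum pairwise fold-difference, and a pass flag at a fold
#' threshold.
#'
#' @param kds named or unnamed numeric vector of K_D estimates (nM, > 0);
#'   at least 2.
#' @param fold_threshold maximum acceptable pairwise fold-difference;
#'   default 2.
#' @return object of class \code{kd_concordance}: \code{geometric_mean_nM},
#'   \code{max_fold_difference}, \code{pass}.
#' @export
kd_concordance <- function(kds, fold_threshold = 2) {
  stopifnot(length(kds) >= 2, all(kds > 0), fold_threshold >= 1)
  fold <- max(kds) / min(kds)
  structure(list(kds = kds,
                 geometric_mean_nM = exp(mean(log(kds))),
                 max_fold_difference = fold,
                 fold_threshold = fold_threshold,
                 pass = fold <= fold_threshold),
            class = "kd_concordance")
}

#' @export
print.kd_concordance <- function(x, ...) {
  cat("K_D concordance across methods\n")
  nm <- if (is.null(names(x$kds))) seq_along(x$kds) else names(x$kds)
  cat(" ", paste(sprintf("%s = %.3g nM", nm, x$kds), collapse = ", "), "\n")
  cat(sprintf("  geometric mean %.3g nM; max fold-difference %.3g (%s at %gx)\n",
              x$geometric_mean_nM, x$max_fold_difference,
              if (x$pass) "PASS" else "FAIL", x$fold_threshold))
  invisible(x)
}
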