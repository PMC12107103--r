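#' Thermal melt curve
#'
#' @param temperatures deg C, strictly increasing, at least 20 points.
#' @param fluorescence dye signal (arbitrary units).
#' @param condition label, e.g. \code{"apo"} or \code{"MTA+compound"}.
#' @return object of class \code{melt_curve}.
#' @export
melt_curve <- function(temperatures, fluorescence, condition = "") {
  stopifnot(length(temperatures) == length(fluorescence),
            length(temperatures) >= 20,
            !is.unsorted(temperatures, strictly = TRUE))
  structure(list(temperatures = temperatures, fluorescence = fluorescence,
                 condition = condition),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve '%s': %d points, %.1f-%.1f degC\n", x$condition,
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures)))
  invisible(x)
}

# Smoothed first derivative of fluorescence w.r.t. temperature on a fine
# grid, via a smoothing spline. Returns list(T, dF).
.melt_derivative <- function(curve, n_grid = 2001) {
  sp <- stats::smooth.spline(curve$temperatures, curve$fluorescence)
  tt <- seq(min(curve$temperatures), max(curve$temperatures),
            length.out = n_grid)
  list(T = tt, dF = stats::predict(sp, tt, deriv = 1)$y)
}

# Local maxima of the derivative above frac * global max, for multiphasic
# detection. Returns data.frame(T, height).
.derivative_peaks <- function(d, frac = 0.3) {
  y <- d$dF
  imax <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) imax <- c(1L, imax)
  n <- length(y)
  if (y[n] > y[n - 1]) imax <- c(imax, n)
  imax <- imax[y[imax] > frac * max(y)]
  # merge peaks closer than 2 degC (spline ripple)
  if (length(imax) > 1) {
    keep <- c(TRUE, diff(d$T[imax]) > 2)
    grp <- cumsum(keep)
    imax <- vapply(split(imax, grp), function(ix) ix[which.max(y[ix])], 1L)
  }
  data.frame(T = d$T[imax], height = y[imax])
}

#' Call the melting temperature from a melt curve
#'
#' Primary method: Boltzmann sigmoid
#' \code{F(T) = F_f + (F_u - F_f) / (1 + exp((Tm - T)/slope))} fitted to the
#' rising transition, with the post-peak region (dye-release decay above the
#' fluorescence maximum) trimmed before fitting. Fallback/alternative:
#' maximum of the smoothed first derivative. Curves with no transition above
#' the noise floor raise an error; curves with two derivative peaks above
#' threshold are flagged multiphasic and the Tm of the larger-amplitude
#' transition is reported.
#'
#' @param curve a \code{\link{melt_curve}}.
#' @param method \code{"boltzmann"} (default) or \code{"derivative"}.
#' @return object of class \code{tm_result}: \code{tm} (deg C),
#'   \code{method}, \code{slope}, \code{amplitude}, \code{r_squared},
#'   \code{multiphasic}.
#' @export
call_tm <- function(curve, method = c("boltzmann", "derivative")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "melt_curve"))
  Tv <- curve$temperatures; Fv <- curve$fluorescence
  noise <- stats::mad(diff(Fv)) / sqrt(2)
  amplitude <- diff(range(Fv))
  if (amplitude <= 0 || amplitude < 8 * max(noise, .Machine$double.eps))
    stop("no transition in melt curve '", curve$condition, "'")

  d <- .melt_derivative(curve)
  peaks <- .derivative_peaks(d)
  multiphasic <- nrow(peaks) >= 2
  main_peak <- peaks$T[which.max(peaks$height)]

  if (method == "derivative" || multiphasic) {
    res <- structure(list(tm = main_peak,
                          method = if (multiphasic) "derivative" else method,
                          slope = NA_real_, amplitude = amplitude,
                          r_squared = NA_real_, multiphasic = multiphasic,
                          curve = curve),
                     class = "tm_result")
    if (method == "derivative" || multiphasic) return(res)
  }

  # trim the post-transition aggregation decay: keep up to the smoothed max
  sm <- stats::fitted(stats::smooth.spline(Tv, Fv))
  imax <- which.max(sm)
  keep <- seq_len(max(imax, 20L))
  Tt <- Tv[keep]; Ft <- Fv[keep]
  tm_s <- main_peak
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Ft ~ Ff + (Fu - Ff) / (1 + exp((Tm - Tt) / slope)),
      start = list(Ff = min(Ft), Fu = max(Ft), Tm = tm_s, slope = 2),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("Boltzmann fit failed for melt curve '", curve$condition, "'")
  cf <- stats::coef(fit)
  if (abs(cf[["Fu"]] - cf[["Ff"]]) < 8 * max(noise, .Machine$double.eps))
    stop("no transition in melt curve '", curve$condition, "'")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((Ft - mean(Ft))^2)
  tm <- cf[["Tm"]]
  if (tm < min(Tv) || tm > max(Tv))
    stop("fitted Tm outside the data span for '", curve$condition, "'")
  structure(list(tm = tm, method = "boltzmann", slope = cf[["slope"]],
                 amplitude = abs(cf[["Fu"]] - cf[["Ff"]]),
                 r_squared = r2, multiphasic = multiphasic, curve = curve,
                 nls = fit),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s method)%s\n", x$tm, x$method,
              if (x$multiphasic) " [multiphasic]" else ""))
  if (is.finite(x$r_squared))
    cat(sprintf("  transition width %.2f K, amplitude %.3g, R^2 = %.5f\n",
                x$slope, x$amplitude, x$r_squared))
  invisible(x)
}

#' @export
coef.tm_result <- function(object, ...)
  c(tm = object$tm, slope = object$slope, amplitude = object$amplitude)

#' @export
plot.tm_result <- function(x, ...) {
  graphics::plot(x$curve$temperatures, x$curve$fluorescence,
                 xlab = "T (degC)", ylab = "fluorescence",
                 main = sprintf("Tm = %.2f degC", x$tm), ...)
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Thermal stabilization (delta-Tm) matrix against a reference condition
#'
#' Calls Tm on every curve and reports \code{dTm = Tm(condition) -
#' Tm(reference)} in kelvin; the reference row is 0 by construction.
#'
#' @param curves list of \code{\link{melt_curve}}s with distinct condition
#'   labels.
#' @param reference_condition the condition to subtract.
#' @param method Tm-calling method, see \code{\link{call_tm}}.
#' @return data.frame: \code{condition}, \code{tm}, \code{delta_tm} (K),
#'   with the reference condition in attribute \code{"reference"}.
#' @export
delta_tm_matrix <- function(curves, reference_condition,
                            method = "boltzmann") {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "melt_curve")))
  conds <- vapply(curves, `[[`, "", "condition")
  if (anyDuplicated(conds)) stop("duplicate condition labels")
  if (!reference_condition %in% conds)
    stop("reference condition '", reference_condition, "' not among curves")
  tms <- vapply(curves, function(cv) call_tm(cv, method = method)$tm,
                numeric(1))
  ref <- tms[conds == reference_condition]
  out <- data.frame(condition = conds, tm = tms, delta_tm = tms - ref,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- reference_condition
  out
}
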