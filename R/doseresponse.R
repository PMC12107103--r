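#' Concentration--response curve
#'
#' @param concentrations doses (nM, >= 0); at least 5 distinct values
#'   including 0 or a low anchor are expected for 4PL fitting.
#' @param responses signal values.
#' @param condition label.
#' @return object of class \code{dose_response_curve}.
#' @export
dose_response_curve <- function(concentrations, responses, condition = "") {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations >= 0))
  structure(list(concentrations = concentrations, responses = responses,
                 condition = condition),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve '%s': %d points, %.3g-%.3g nM\n",
              x$condition, length(x$concentrations),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

# 4PL in the log-concentration domain:
#   y = bottom + (top - bottom) / (1 + exp(hill * (log(x) - log(ic50))))
# (inhibition orientation: hill > 0 means response falls with dose).
# Zero doses enter as lx = -Inf, the exact x -> 0 limit (top for hill > 0).
.fourpl_response <- function(lx, top, bottom, lic50, hill) {
  z <- exp(hill * (lx - lic50))
  z[is.nan(z)] <- 0          # hill * (-Inf) at hill == 0
  bottom + (top - bottom) / (1 + z)
}

#' Fit a four-parameter logistic dose--response model
#'
#' \code{y = bottom + (top - bottom) / (1 + (x / IC50)^hill)}, fitted in the
#' log-concentration domain by Levenberg--Marquardt least squares. Zero
#' concentrations enter as the exact zero-dose limit of the model (the
#' \code{top} asymptote for an inhibition curve), so noiseless curves that
#' include an untreated anchor are recovered exactly. Initialisation: top/bottom from the 5th/95th response percentiles, IC50
#' from the dose nearest half-response, hill = 1; the fit is restarted from
#' three deterministic jitters of that start and the lowest residual sum
#' wins. The fitted IC50 is the curve midpoint (relative IC50); because top
#' and bottom are free this is reported alongside the asymptotes so an
#' absolute potency can be read off when wanted.
#'
#' @param curve a \code{\link{dose_response_curve}}.
#' @param fix_hill optional fixed hill slope (e.g. 1); default free.
#' @return object of class \code{fourpl_fit}: \code{ic50} (nM), \code{hill},
#'   \code{top}, \code{bottom}, standard errors, residual sum of squares.
#' @export
fit_4pl <- function(curve, fix_hill = NULL) {
  stopifnot(inherits(curve, "dose_response_curve"))
  x <- curve$concentrations; y <- curve$responses
  if (length(unique(x)) < 5) stop("need at least 5 distinct concentrations")
  if (diff(range(y)) < .Machine$double.eps * 100 * max(1, abs(mean(y))))
    stop("degenerate curve: responses are constant")
  min_pos <- min(x[x > 0])
  lx <- ifelse(x > 0, log(x), -Inf)

  qs <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  bottom_s <- qs[1]; top_s <- qs[2]
  ic50_s <- x[which.min(abs(y - (top_s + bottom_s) / 2))]
  if (ic50_s <= 0) ic50_s <- min_pos
  starts <- list(c(ic50 = 1,   hill = 1),
                 c(ic50 = 0.4, hill = 0.7),
                 c(ic50 = 2.5, hill = 1.6))

  controls <- list(minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                              ptol = 1e-12),
                   minpack.lm::nls.lm.control(maxiter = 1000))
  one_try <- function(st, ctl) tryCatch({
    if (is.null(fix_hill)) {
      minpack.lm::nlsLM(
        y ~ .fourpl_response(lx, top, bottom, lic50, hill),
        start = list(top = top_s, bottom = bottom_s,
                     lic50 = log(ic50_s * st[["ic50"]]),
                     hill = st[["hill"]]),
        control = ctl)
    } else {
      minpack.lm::nlsLM(
        y ~ .fourpl_response(lx, top, bottom, lic50, fix_hill),
        start = list(top = top_s, bottom = bottom_s,
                     lic50 = log(ic50_s * st[["ic50"]])),
        control = ctl)
    }
  }, error = function(e) NULL)
  best <- NULL
  for (st in starts) {
    fit <- NULL
    for (ctl in controls) {
      fit <- one_try(st, ctl)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed to converge")
  fit <- best$fit
  cf <- stats::coef(fit)
  hill <- if (is.null(fix_hill)) cf[["hill"]] else fix_hill
  ic50 <- exp(cf[["lic50"]])
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  se_ic50 <- if (is.finite(se[["lic50"]])) ic50 * se[["lic50"]] else NA_real_
  structure(list(ic50 = ic50, hill = hill, top = cf[["top"]],
                 bottom = cf[["bottom"]],
                 se = c(ic50 = se_ic50,
                        hill = if (is.null(fix_hill)) se[["hill"]] else 0,
                        top = se[["top"]], bottom = se[["bottom"]]),
                 rss = best$rss, hill_fixed = !is.null(fix_hill),
                 curve = curve, nls = fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 = %.4g nM, hill = %.3g%s\n", x$ic50, x$hill,
              if (x$hill_fixed) " (fixed)" else ""))
  cat(sprintf("  top = %.4g, bottom = %.4g, RSS = %.4g\n",
              x$top, x$bottom, x$rss))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...)
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)

#' @export
summary.fourpl_fit <- function(object, ...) {
  out <- data.frame(estimate = coef(object),
                    std_error = object$se[c("ic50", "hill", "top", "bottom")])
  cat(sprintf("Four-parameter logistic fit ('%s', %d doses)\n",
              object$curve$condition, length(object$curve$concentrations)))
  print(out)
  invisible(out)
}

#' @export
predict.fourpl_fit <- function(object, concentrations =
                                 object$curve$concentrations, ...) {
  x <- concentrations
  lx <- ifelse(x > 0, log(x), -Inf)
  .fourpl_response(lx, object$top, object$bottom, log(object$ic50),
                   object$hill)
}

#' @export
residuals.fourpl_fit <- function(object, ...)
  object$curve$responses - predict(object)

#' @export
plot.fourpl_fit <- function(x, ...) {
  cc <- x$curve$concentrations
  min_pos <- min(cc[cc > 0])
  xx <- ifelse(cc > 0, cc, min_pos / 10)
  graphics::plot(xx, x$curve$responses, log = "x", xlab = "dose (nM)",
                 ylab = "response",
                 main = sprintf("IC50 = %.3g nM", x$ic50), ...)
  gg <- exp(seq(log(min_pos / 10), log(max(cc)), length.out = 200))
  graphics::lines(gg, predict(x, gg))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' Potency ratio between two IC50s
#'
#' \code{ic50_ref / ic50_test}: values above 1 mean the test condition is
#' the more potent one (e.g. potentiation by cofactor addition, or
#' selectivity toward one cell background).
#'
#' @param ic50_ref,ic50_test IC50s (same units, > 0).
#' @return fold ratio.
#' @examples
#' potency_ratio(40, 5)    # 8-fold potentiation
#' potency_ratio(520, 160) # 3.25-fold
#' @export
potency_ratio <- function(ic50_ref, ic50_test) {
  if (any(ic50_ref <= 0) || any(ic50_test <= 0))
    stop("IC50s must be positive")
  ic50_ref / ic50_test
}

#' Write / read curve CSVs
#'
#' Shared delimited format for the plate-style inputs: columns \code{x},
#' \code{y} and optional \code{condition}. Used for melt curves
#' (temperature, fluorescence), FP traces (time, mP) and dose--response
#' data (concentration, response).
#'
#' @param x_values,y_values numeric columns to write.
#' @param path file path.
#' @param condition optional condition column (recycled).
#' @return \code{write_curve_csv}: \code{path} invisibly;
#'   \code{read_curve_csv}: data.frame with columns \code{x}, \code{y} and
#'   (if present) \code{condition}.
#' @export
write_curve_csv <- function(x_values, y_values, path, condition = NULL) {
  df <- data.frame(x = x_values, y = y_values)
  if (!is.null(condition)) df$condition <- condition
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("curve CSV must have columns x and y")
  df
}
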