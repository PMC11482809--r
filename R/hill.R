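# Hill-equation fitting of saturation binding curves, in the classic R
# modelling idiom: a fitting function returning a classed object with
# print/summary/coef/predict/plot/residuals/simulate methods.

#' Construct a binding curve
#'
#' Concentration versus fraction-bound data for saturation binding
#' analysis. Concentrations must be strictly positive and strictly
#' increasing; at least 4 points are required for fitting.
#'
#' @param concentration ligand concentrations, micromolar.
#' @param fraction_bound bound fractions in `[0, 1]`.
#' @return Object of class `binding_curve` (a data frame).
#' @export
binding_curve <- function(concentration, fraction_bound) {
  concentration <- as.numeric(concentration)
  fraction_bound <- as.numeric(fraction_bound)
  stopifnot(length(concentration) == length(fraction_bound))
  if (any(concentration <= 0)) stop("concentrations must be strictly positive")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(fraction_bound < 0 | fraction_bound > 1.2))
    stop("fraction_bound outside [0, 1.2]")
  out <- data.frame(concentration = concentration,
                    fraction_bound = fraction_bound)
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Hill equation
#'
#' `f(c) = amplitude * c^n / (kd^n + c^n)`: the fraction of sites bound
#' at ligand concentration `c` for a cooperative binding equilibrium with
#' half-saturation constant `kd` and Hill coefficient `n` (`n > 1`
#' indicates cooperativity).
#'
#' @param concentration concentrations, micromolar.
#' @param kd half-saturation constant, micromolar.
#' @param n Hill coefficient.
#' @param amplitude saturating bound fraction.
#' @return Predicted bound fractions.
#' @export
hill_equation <- function(concentration, kd, n, amplitude = 1) {
  amplitude * concentration^n / (kd^n + concentration^n)
}

#' Fit the Hill equation to a binding curve
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt) of
#' `amplitude * c^n / (kd^n + c^n)` to concentration versus
#' fraction-bound data. Initialization: `amplitude = max(fraction_bound)`,
#' `kd` at the half-maximum concentration by linear interpolation,
#' `n = 1`. Bounds: `kd` in (0, 100], `n` in (0.1, 10], `amplitude` in
#' (0, 1.2]; the amplitude may instead be fixed at a known saturation
#' value.
#'
#' @param curve a `binding_curve`, or anything coercible via
#'   `binding_curve()` when `fraction_bound` is also given.
#' @param fraction_bound optional; if `curve` is a plain concentration
#'   vector, the matching bound fractions.
#' @param fix_amplitude optional numeric; fixes the amplitude instead of
#'   fitting it.
#' @return An object of class `hill_fit` with components `coefficients`
#'   (`kd`, `n`, `amplitude`), `rss`, `fitted`, `residuals`, `curve`,
#'   `fixed_amplitude` and the underlying `nls` fit.
#' @examples
#' conc <- 10^seq(-1.5, 1, length.out = 8)
#' fit <- fit_hill(binding_curve(conc, hill_equation(conc, 0.94, 2.7)))
#' coef(fit)
#' @export
fit_hill <- function(curve, fraction_bound = NULL, fix_amplitude = NULL) {
  if (!inherits(curve, "binding_curve"))
    curve <- binding_curve(curve, fraction_bound)
  if (nrow(curve) < 4)
    stop("Hill fitting needs at least 4 concentration points")
  conc <- curve$concentration
  fb <- curve$fraction_bound

  amp0 <- if (is.null(fix_amplitude)) max(fb) else fix_amplitude
  half <- amp0 / 2
  kd0 <- if (all(fb < half)) {
    max(conc)
  } else if (fb[1] >= half) {
    conc[1]
  } else {
    i <- which(fb >= half)[1]
    stats::approx(fb[c(i - 1, i)], conc[c(i - 1, i)], xout = half,
                  ties = "ordered")$y
  }
  kd0 <- min(max(kd0, 1e-3), 100)
  init <- list(kd = kd0, n = 1)
  lower <- c(kd = 1e-6, n = 0.1)
  upper <- c(kd = 100, n = 10)
  if (is.null(fix_amplitude)) {
    form <- fb ~ amplitude * conc^n / (kd^n + conc^n)
    init$amplitude <- max(amp0, 1e-3)
    lower <- c(lower, amplitude = 1e-6)
    upper <- c(upper, amplitude = 1.2)
  } else {
    form <- fb ~ fix_amplitude * conc^n / (kd^n + conc^n)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(conc = conc, fb = fb),
                      start = init, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("Hill fit did not converge (init kd=%.4g, n=1, amplitude=%.4g): %s",
                   kd0, amp0, conditionMessage(e))))
  cf <- stats::coef(fit)
  coefficients <- c(kd = unname(cf["kd"]), n = unname(cf["n"]),
                    amplitude = if (is.null(fix_amplitude))
                      unname(cf["amplitude"]) else fix_amplitude)
  fitted <- hill_equation(conc, coefficients["kd"], coefficients["n"],
                          coefficients["amplitude"])
  structure(list(coefficients = coefficients,
                 rss = sum((fb - fitted)^2),
                 fitted = fitted, residuals = fb - fitted,
                 curve = curve,
                 fixed_amplitude = fix_amplitude,
                 nls = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("Hill-equation fit: f(c) = A * c^n / (Kd^n + c^n)\n")
  cat(sprintf("  Kd        = %.*g uM\n", digits, x$coefficients["kd"]))
  cat(sprintf("  Hill n    = %.*g%s\n", digits, x$coefficients["n"],
              if (x$coefficients["n"] > 1) "  (cooperative)" else ""))
  cat(sprintf("  amplitude = %.*g%s\n", digits, x$coefficients["amplitude"],
              if (!is.null(x$fixed_amplitude)) "  (fixed)" else ""))
  cat(sprintf("  RSS = %.*g over %d points\n", digits, x$rss,
              nrow(x$curve)))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$curve$concentration
          else if (is.list(newdata)) newdata$concentration
          else as.numeric(newdata)
  hill_equation(conc, object$coefficients["kd"], object$coefficients["n"],
                object$coefficients["amplitude"])
}

#' @export
summary.hill_fit <- function(object, ...) {
  s <- summary(object$nls)
  out <- list(coefficients = object$coefficients, rss = object$rss,
              n_points = nrow(object$curve),
              parameter_table = s$coefficients,
              sigma = s$sigma)
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit over %d concentrations; residual sigma %.4g\n",
              x$n_points, x$sigma))
  print(x$parameter_table)
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  conc <- x$curve$concentration
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 200))
  graphics::plot(conc, x$curve$fraction_bound, log = "x",
                 xlab = "concentration (uM)", ylab = "fraction bound",
                 ylim = c(0, max(1, x$curve$fraction_bound)), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$coefficients["kd"], lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate binding curves from a Hill fit
#'
#' Parametric simulation: the fitted Hill curve evaluated at the
#' original concentrations plus i.i.d. Gaussian noise.
#'
#' @param object a `hill_fit`.
#' @param nsim number of simulated curves.
#' @param seed integer RNG seed.
#' @param sd noise standard deviation (default: residual standard
#'   deviation of the fit).
#' @param ... unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL,
                              sd = NULL, ...) {
  if (is.null(sd))
    sd <- sqrt(object$rss / max(1, nrow(object$curve) - 3))
  gen <- function() pmin(pmax(object$fitted +
                                stats::rnorm(length(object$fitted), 0, sd),
                              0), 1.2)
  sims <- if (is.null(seed)) replicate(nsim, gen())
          else .with_seed(seed, replicate(nsim, gen()))
  as.data.frame(sims)
}
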