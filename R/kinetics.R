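# Kinetic and colorimetric-assay statistics: Michaelis-Menten and Hill
# fitting by nonlinear least squares, observed-rate and efficiency
# derivations, background-subtracted signal ratios, turnover counting,
# detection limits and Beer-Lambert conversion.

# Levenberg-Marquardt least squares with parameters on the log scale.
# resid_fn receives natural-scale parameters. Returns natural-scale
# estimates with delta-method standard errors (NA when the Jacobian is
# numerically singular, e.g. under non-identifiability).
lm_fit_log <- function(par0, resid_fn) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = function(lp) resid_fn(exp(lp)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(out) || !(out$info %in% 1:4)) {
    return(list(converged = FALSE, estimate = NULL, se = NULL, raw = out))
  }
  est <- exp(out$par)
  n <- length(resid_fn(est))
  p <- length(est)
  se <- rep(NA_real_, p)
  if (n > p) {
    sigma2 <- out$deviance / (n - p)
    cov_log <- tryCatch(sigma2 * solve(out$hessian),
                        error = function(e) NULL)
    if (!is.null(cov_log)) {
      d <- diag(cov_log)
      se <- ifelse(d >= 0, est * sqrt(d), NA_real_)  # delta method
    }
  }
  list(converged = TRUE, estimate = est, se = se, raw = out)
}

#' Michaelis-Menten initial rate
#'
#' `v0 = vmax * s / (km + s)`.
#'
#' @param vmax Maximal velocity (concentration/time).
#' @param km Michaelis constant (concentration).
#' @param s Substrate concentration(s).
#' @return Initial rate(s), same units as `vmax`.
#' @export
mm_v0 <- function(vmax, km, s) {
  if (any(c(vmax, km) <= 0) || any(s < 0)) {
    abort("`vmax` and `km` must be positive and `s` non-negative")
  }
  vmax * s / (km + s)
}

#' Simulate an initial-rate kinetic dataset
#'
#' Rates are `mm_v0([S]) * (1 + N(0, noise_sd_frac))`, truncated at zero.
#'
#' @param preset A list with `vmax`, `km`, `enzyme_conc` (see
#'   [apollon_kinetic_preset()]).
#' @param concentrations Substrate concentrations (same units as `km`).
#' @param noise_sd_frac Relative Gaussian noise SD (0 = exact curve).
#' @param seed Integer seed.
#' @return A tibble with columns `s`, `v0`; `enzyme_conc` is kept as an
#'   attribute.
#' @export
simulate_kinetics <- function(preset, concentrations, noise_sd_frac = 0.05,
                              seed = 1L) {
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (noise_sd_frac < 0) abort("`noise_sd_frac` must be >= 0")
  set.seed(seed)
  v <- mm_v0(preset$vmax, preset$km, concentrations)
  v <- pmax(0, v * (1 + rnorm(length(v), 0, noise_sd_frac)))
  out <- tibble(s = concentrations, v0 = v)
  attr(out, "enzyme_conc") <- preset$enzyme_conc
  out
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Nonlinear least squares on `v0 = vmax*s/(km+s)` (Levenberg-Marquardt,
#' positivity bounds, starting from `vmax0 = max(v0)`, `km0 = median(s)`).
#' `kcat = vmax / [E]`. When the fitted Km exceeds the largest tested
#' substrate concentration the data never saturated and only `kcat/km` is
#' well identified; this is flagged in `non_saturating`.
#'
#' @param data A data frame with columns `s`, `v0` (at least 3 distinct
#'   `s`).
#' @param enzyme_conc Enzyme concentration `[E]`; defaults to the
#'   `enzyme_conc` attribute of `data`.
#' @return An object of class `mm_fit`: a list with `vmax`, `km`, `kcat`,
#'   `efficiency` (kcat/km), standard errors, `converged`, `boundary`,
#'   `non_saturating`, `data` and the underlying `fit`.
#' @export
fit_mm <- function(data, enzyme_conc = attr(data, "enzyme_conc")) {
  if (length(unique(data$s)) < 3L) abort("need at least 3 distinct [S]")
  if (is.null(enzyme_conc)) abort("`enzyme_conc` is required")
  if (any(data$s <= 0) || any(data$v0 < 0)) {
    abort("[S] must be positive and rates non-negative")
  }
  # Positivity is enforced by fitting on the log scale; Levenberg-Marquardt
  # on the raw residuals keeps the fit usable even in the non-saturating
  # regime where vmax and km are individually ill-determined.
  fit <- lm_fit_log(
    par0 = c(vmax = log(max(data$v0[data$v0 > 0])), km = log(median(data$s))),
    resid_fn = function(p) data$v0 - p[["vmax"]] * data$s /
      (p[["km"]] + data$s))
  if (!fit$converged) {
    return(structure(list(vmax = NA_real_, km = NA_real_, kcat = NA_real_,
                          efficiency = NA_real_, vmax_se = NA_real_,
                          km_se = NA_real_, enzyme_conc = enzyme_conc,
                          converged = FALSE, boundary = FALSE,
                          non_saturating = NA, data = as_tibble(data),
                          fit = NULL),
                     class = "mm_fit"))
  }
  cf <- fit$estimate
  boundary <- cf[["km"]] <= 1e-6 * median(data$s)
  structure(list(vmax = cf[["vmax"]], km = cf[["km"]],
                 kcat = cf[["vmax"]] / enzyme_conc,
                 efficiency = cf[["vmax"]] / enzyme_conc / cf[["km"]],
                 vmax_se = fit$se[[1]], km_se = fit$se[[2]],
                 enzyme_conc = enzyme_conc, converged = TRUE,
                 boundary = boundary,
                 non_saturating = cf[["km"]] > max(data$s),
                 data = as_tibble(data), fit = fit$raw),
            class = "mm_fit")
}

#' Observed rate at a substrate concentration
#'
#' `kobs(S) = kcat * S / (Km + S)` from a fitted Michaelis-Menten model.
#'
#' @param fit An `mm_fit` object.
#' @param s Substrate concentration(s).
#' @return Observed first-order rate(s) (1/time).
#' @export
kobs_at <- function(fit, s) {
  if (!inherits(fit, "mm_fit")) abort("`fit` must be an mm_fit")
  fit$kcat * s / (fit$km + s)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>\n")
  cat(sprintf("  vmax = %.4g (SE %.3g)\n  Km   = %.4g (SE %.3g)\n",
              x$vmax, x$vmax_se, x$km, x$km_se))
  cat(sprintf("  kcat = %.4g   kcat/Km = %.4g\n", x$kcat, x$efficiency))
  if (isTRUE(x$non_saturating)) {
    cat("  note: Km exceeds the largest tested [S] (non-saturating data)\n")
  }
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("vmax", "km"),
         estimate = c(x$vmax, x$km),
         std.error = c(x$vmax_se, x$km_se))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(kcat = x$kcat, efficiency = x$efficiency,
         enzyme_conc = x$enzyme_conc, converged = x$converged,
         boundary = x$boundary, non_saturating = x$non_saturating,
         nobs = nrow(x$data))
}

#' Fit a Hill dose-response curve
#'
#' `y = top * x^n / (k_half^n + x^n)` with the bottom fixed at zero, by
#' Levenberg-Marquardt least squares with positivity bounds. A Hill
#' coefficient n > 1 indicates cooperative activation (e.g. multiple metal
#' ions required for folding or catalysis).
#'
#' @param data A data frame with columns `x` (dose) and `y` (response), at
#'   least 4 distinct doses.
#' @return An object of class `hill_fit` with `top`, `k_half`, `n_hill`,
#'   standard errors and `converged`.
#' @export
fit_hill <- function(data) {
  if (length(unique(data$x)) < 4L) abort("need at least 4 distinct doses")
  if (any(data$x <= 0)) abort("doses must be positive")
  fit <- lm_fit_log(
    par0 = c(top = log(max(data$y[data$y > 0])),
             k_half = log(median(data$x)), n = log(1.5)),
    resid_fn = function(p) data$y - p[["top"]] * data$x^p[["n"]] /
      (p[["k_half"]]^p[["n"]] + data$x^p[["n"]]))
  if (!fit$converged) {
    return(structure(list(top = NA_real_, k_half = NA_real_,
                          n_hill = NA_real_, top_se = NA_real_,
                          k_half_se = NA_real_, n_se = NA_real_,
                          converged = FALSE, data = as_tibble(data),
                          fit = NULL),
                     class = "hill_fit"))
  }
  cf <- fit$estimate
  structure(list(top = cf[["top"]], k_half = cf[["k_half"]],
                 n_hill = cf[["n"]], top_se = fit$se[[1]],
                 k_half_se = fit$se[[2]], n_se = fit$se[[3]],
                 converged = TRUE, data = as_tibble(data), fit = fit$raw),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> top = %.4g, k_half = %.4g, n = %.3g\n",
              x$top, x$k_half, x$n_hill))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("top", "k_half", "n_hill"),
         estimate = c(x$top, x$k_half, x$n_hill),
         std.error = c(x$top_se, x$k_half_se, x$n_se))
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble(n_hill = x$n_hill, k_half = x$k_half, top = x$top,
         converged = x$converged, nobs = nrow(x$data))
}

#' Background-subtracted signal-to-noise ratio
#'
#' `(A_sample - A_buffer) / (A_no_enzyme - A_buffer)`: the buffer blank (the
#' 405 nm absorbance of reaction buffer alone) is subtracted from both the
#' enzyme-containing sample and the no-enzyme control before taking the
#' ratio.
#'
#' @param a405_sample Absorbance with deoxyribozyme.
#' @param a405_no_enzyme Absorbance without deoxyribozyme.
#' @param a405_buffer Absorbance of buffer alone.
#' @return A one-row tibble with `ratio` and `defined` (`FALSE`, with `NA`
#'   ratio, when the background-subtracted denominator is not positive).
#' @export
signal_to_noise <- function(a405_sample, a405_no_enzyme, a405_buffer = 0) {
  if (any(c(a405_sample, a405_no_enzyme, a405_buffer) < 0)) {
    abort("absorbances must be non-negative")
  }
  denom <- a405_no_enzyme - a405_buffer
  if (denom <= 0) {
    return(tibble(ratio = NA_real_, defined = FALSE))
  }
  tibble(ratio = (a405_sample - a405_buffer) / denom, defined = TRUE)
}

#' Fold-activation of a sensor by its input
#'
#' Same background-subtracted ratio as [signal_to_noise()], with the signal
#' in the presence of the activating input in the numerator and the signal
#' without the input in the denominator.
#'
#' @param signal_with_input,signal_without_input,buffer Absorbances.
#' @return A one-row tibble with `ratio` and `defined`.
#' @export
fold_activation <- function(signal_with_input, signal_without_input,
                            buffer = 0) {
  signal_to_noise(signal_with_input, signal_without_input, buffer)
}

#' Turnover count of a bimolecular construct
#'
#' Ratio of the (background-subtracted) signal of the multiple-turnover
#' bimolecular reaction to that of the single-turnover unimolecular control
#' at matched enzyme concentration; a ratio of 10 means ten turnovers.
#'
#' @param bimolecular_signal,unimolecular_control_signal Background-
#'   subtracted signals.
#' @return Number of turnovers.
#' @export
turnovers <- function(bimolecular_signal, unimolecular_control_signal) {
  if (unimolecular_control_signal <= 0) {
    abort("the unimolecular control signal must be positive")
  }
  if (bimolecular_signal < 0) abort("signals must be non-negative")
  bimolecular_signal / unimolecular_control_signal
}

#' Detection limit from a titration
#'
#' Smallest tested concentration whose mean signal exceeds
#' `blank_mean + 3 * blank_sd`.
#'
#' @param blank_mean,blank_sd Blank signal statistics.
#' @param titration A data frame with columns `concentration` and `signal`
#'   (mean signal per tested concentration), sorted by concentration.
#' @return A one-row tibble with `limit` (`NA` when nothing exceeds the
#'   threshold), `threshold` and `detected`.
#' @export
detection_limit <- function(blank_mean, blank_sd, titration) {
  if (!all(c("concentration", "signal") %in% names(titration))) {
    abort("`titration` needs columns `concentration` and `signal`")
  }
  if (nrow(titration) < 2L) abort("need at least 2 titration points")
  if (is.unsorted(titration$concentration)) {
    abort("`titration` must be sorted by concentration")
  }
  threshold <- blank_mean + 3 * blank_sd
  hit <- which(titration$signal > threshold)
  tibble(limit = if (length(hit) > 0L) titration$concentration[[min(hit)]]
         else NA_real_,
         threshold = threshold, detected = length(hit) > 0L)
}

#' Convert 405 nm absorbance to product concentration
#'
#' Beer-Lambert: `c = A / (epsilon * path)`. No molar absorptivity is
#' hard-coded; supply the value appropriate for the product and buffer.
#'
#' @param a405 Absorbance at 405 nm.
#' @param epsilon Molar absorptivity (1/(M cm)).
#' @param path Path length (cm).
#' @return Concentration (M).
#' @export
a405_to_conc <- function(a405, epsilon, path = 1) {
  if (epsilon <= 0 || path <= 0) abort("`epsilon` and `path` must be positive")
  a405 / (epsilon * path)
}
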