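# Michaelis-Menten and competitive-inhibition models, initial rates and
# dose-response fitting. Responses keep their native sign (inward currents
# negative); the fitters work on magnitudes internally and restore signs on
# output.

#' Build a dose-response set
#'
#' @param substrate Substrate name.
#' @param concentration Concentrations in mol/L; non-negative and unique.
#' @param response Responses in assay units (inward currents negative).
#' @param unit Response unit label (default `"nA"`).
#' @return An object of class `dose_response` (a data frame with attributes).
#' @export
dose_response <- function(substrate, concentration, response, unit = "nA") {
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  if (anyDuplicated(concentration)) stop("concentrations must be unique")
  df <- data.frame(concentration = concentration, response = response)
  df <- df[order(df$concentration), ]
  rownames(df) <- NULL
  structure(df, class = c("dose_response", "data.frame"),
            substrate = substrate, unit = unit)
}

#' Michaelis-Menten velocity
#'
#' @param S Substrate concentration in mol/L; non-negative.
#' @param K_M Michaelis constant in mol/L; positive.
#' @param v_max Maximal velocity in assay units (may be negative for inward
#'   currents).
#' @return `v_max * S / (K_M + S)`.
#' @export
mm_velocity <- function(S, K_M, v_max) {
  if (any(S < 0)) stop("S must be >= 0")
  if (K_M <= 0) stop("K_M must be > 0")
  v_max * S / (K_M + S)
}

#' Competitive-inhibition velocity
#'
#' @inheritParams mm_velocity
#' @param I Inhibitor concentration in mol/L; non-negative.
#' @param K_I Inhibition constant in mol/L; positive.
#' @return `v_max * S / (K_M * (1 + I/K_I) + S)`; reduces to [mm_velocity()]
#'   at `I = 0`.
#' @export
inhibition_velocity <- function(S, I, K_M, K_I, v_max) {
  if (any(S < 0) || any(I < 0)) stop("concentrations must be >= 0")
  if (K_M <= 0 || K_I <= 0) stop("K_M and K_I must be > 0")
  v_max * S / (K_M * (1 + I / K_I) + S)
}

#' Invert fractional inhibition to a competitive K_I
#'
#' For a competitive inhibitor, the fractional inhibition of the substrate
#' response `phi = 1 - v_I/v_0` inverts algebraically to
#' `K_I = K_M * I * (1 - phi) / ((K_M + S) * phi)`.
#'
#' @param phi Fractional inhibition in (0, 1). `phi = 1` ("abolished") returns
#'   a lower bound of 0 with attribute `lower_bound = TRUE`.
#' @param S Substrate concentration (mol/L).
#' @param I Inhibitor concentration (mol/L).
#' @param K_M Substrate Michaelis constant (mol/L).
#' @return K_I in mol/L.
#' @examples
#' # 20 mM Ala-Ala inhibiting 3 mM Lys-Ala (K_M 2.6 mM) by 66%
#' ki_from_fractional_inhibition(0.66, 3e-3, 20e-3, 2.6e-3)  # ~4.8e-3
#' @export
ki_from_fractional_inhibition <- function(phi, S, I, K_M) {
  if (!is.finite(phi) || phi <= 0 || phi > 1)
    stop("phi must lie in (0, 1]")
  if (phi == 1)
    return(structure(0, lower_bound = TRUE))
  K_M * I * (1 - phi) / ((K_M + S) * phi)
}

#' Fit the Michaelis-Menten model to a dose-response set
#'
#' Nonlinear least squares on response magnitudes with a single deterministic
#' start: `v_max` initialised to the largest magnitude, `K_M` to the smallest
#' dose whose magnitude reaches half of it, with `K_M` bounded within
#' \[min dose / 10, max dose x 10\]. The fitted `v_max` is reported with the
#' sign of the raw responses.
#'
#' @param data A [dose_response()] with >= 4 points; a warning is issued when
#'   the doses do not span the fitted K_M.
#' @return An object of class `kinetics_fit` with `K_M`, `v_max`, standard
#'   errors, residual summary and a convergence flag. Under-determined input
#'   (< 4 points) yields a flagged, estimate-free result.
#' @export
fit_michaelis_menten <- function(data) {
  stopifnot(inherits(data, "dose_response"))
  failed <- structure(list(K_M = NA_real_, v_max = NA_real_,
                           K_M_se = NA_real_, v_max_se = NA_real_,
                           residual_sd = NA_real_, converged = FALSE,
                           substrate = attr(data, "substrate"),
                           n = nrow(data)),
                      class = "kinetics_fit")
  if (nrow(data) < 4) {
    warning("need >= 4 dose points for a Michaelis-Menten fit")
    return(failed)
  }
  sgn <- if (sum(sign(data$response[data$concentration > 0])) < 0) -1 else 1
  y <- abs(data$response)
  S <- data$concentration
  v0 <- max(y)
  half <- which(y >= v0 / 2)
  km0 <- S[min(half)]
  if (km0 <= 0) km0 <- min(S[S > 0])
  lo <- min(S[S > 0]) / 10
  hi <- max(S) * 10
  km0 <- min(max(km0, lo), hi)
  fit <- try(minpack.lm::nlsLM(
    y ~ vmax * S / (km + S),
    start = list(vmax = v0, km = km0),
    lower = c(vmax = 0, km = lo), upper = c(vmax = Inf, km = hi),
    data = data.frame(S = S, y = y),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(failed)
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(vmax = NA_real_, km = NA_real_))
  if (cf[["km"]] < min(S[S > 0]) || cf[["km"]] > max(S))
    warning("doses do not span the fitted K_M; estimate is an extrapolation")
  structure(list(K_M = unname(cf[["km"]]), v_max = sgn * unname(cf[["vmax"]]),
                 K_M_se = unname(se[["km"]]), v_max_se = unname(se[["vmax"]]),
                 residual_sd = stats::sigma(fit), converged = TRUE,
                 substrate = attr(data, "substrate"), n = nrow(data)),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit (", x$substrate, "): not converged\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Michaelis-Menten fit (%s, n = %d)\n", x$substrate, x$n))
  cat(sprintf("  K_M   = %.4g +/- %.2g mol/L\n", x$K_M, x$K_M_se))
  cat(sprintf("  v_max = %.4g +/- %.2g\n", x$v_max, x$v_max_se))
  cat(sprintf("  residual sd %.3g\n", x$residual_sd))
  invisible(x)
}

#' Initial rate of a time series by ordinary least squares
#'
#' Slope of the response over an explicit time window, the estimator used for
#' uptake velocities in the linear range of an uptake curve.
#'
#' @param time Time in seconds.
#' @param response Response values (same length as `time`).
#' @param window Length-2 numeric `c(start, end)` in seconds; at least 5
#'   samples must fall inside.
#' @return List with `slope` (response units per second), `se`, `n`.
#' @export
initial_rate <- function(time, response, window) {
  if (length(time) != length(response)) stop("time/response length mismatch")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start, end) with end > start")
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 5) stop("need >= 5 samples in the rate window")
  fit <- stats::lm(response[keep] ~ time[keep])
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]), n = sum(keep))
}
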