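# nanoDSF melt-curve simulation, T_m extraction and K_D estimation from
# ligand-dependent thermal stabilization.

#' Simulate a two-state melt curve
#'
#' Two-state unfolding with sloped native and unfolded baselines. The unfolding
#' equilibrium constant is `K(T) = exp(-dH * (1 - T/T_m) / (R T))` (T in
#' kelvin, constant-enthalpy approximation, dCp neglected), the unfolded
#' fraction `K/(1+K)`, and the fluorescence ratio the population-weighted
#' baseline mix plus seeded Gaussian noise.
#'
#' @param t_m Melting temperature in degrees C; must lie inside the grid.
#' @param enthalpy Unfolding enthalpy in kJ/mol; positive. Default 300 kJ/mol,
#'   a typical value for a small membrane-protein/detergent system.
#' @param baselines Named list with `native_intercept`, `native_slope`,
#'   `unfolded_intercept`, `unfolded_slope` (ratio units and ratio units per
#'   degree C).
#' @param noise_sd Gaussian noise standard deviation in ratio units (default
#'   0.002, about 1 percent of a typical transition amplitude).
#' @param seed Integer seed; identical seeds give identical curves.
#' @param temperature Temperature grid in degrees C, strictly increasing,
#'   >= 50 points (default 20 to 95 in 0.5 steps).
#' @param ligand,conc_M,replicate Metadata carried on the curve.
#' @return An object of class `melt_curve`: data frame with columns
#'   `temperature_C` and `ratio` plus metadata attributes.
#' @export
simulate_melt_curve <- function(t_m, enthalpy = 300,
                                baselines = list(native_intercept = 0.80,
                                                 native_slope = 5e-4,
                                                 unfolded_intercept = 0.95,
                                                 unfolded_slope = 1.5e-3),
                                noise_sd = 0.002, seed = 1,
                                temperature = seq(20, 95, by = 0.5),
                                ligand = "apo", conc_M = 0, replicate = 1L) {
  if (any(diff(temperature) <= 0)) stop("temperature grid must be increasing")
  if (length(temperature) < 50) stop("need >= 50 temperature points")
  if (t_m < min(temperature) || t_m > max(temperature))
    stop("t_m must lie inside the temperature grid")
  if (enthalpy <= 0) stop("enthalpy must be positive (kJ/mol)")
  tk <- temperature + 273.15
  tmk <- t_m + 273.15
  R <- physical_constants()$gas_constant
  K <- exp(-enthalpy * 1e3 * (1 - tk / tmk) / (R * tk))
  fu <- K / (1 + K)
  native <- baselines$native_intercept + baselines$native_slope * temperature
  unf <- baselines$unfolded_intercept + baselines$unfolded_slope * temperature
  sig <- (1 - fu) * native + fu * unf
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  }
  structure(data.frame(temperature_C = temperature, ratio = sig),
            class = c("melt_curve", "data.frame"),
            ligand = ligand, conc_M = conc_M, replicate = replicate,
            truth = list(t_m = t_m, enthalpy = enthalpy))
}

two_state_signal <- function(tc, tm, dh, n0, n1, u0, u1) {
  tk <- tc + 273.15
  R <- physical_constants()$gas_constant
  K <- exp(-dh * 1e3 * (1 - tk / (tm + 273.15)) / (R * tk))
  fu <- K / (1 + K)
  (1 - fu) * (n0 + n1 * tc) + fu * (u0 + u1 * tc)
}

# centered moving average, window must be odd
moving_average <- function(x, window = 5L) {
  k <- rep(1 / window, window)
  n <- length(x)
  out <- stats::filter(x, k, sides = 2)
  half <- (window - 1L) %/% 2L
  for (i in seq_len(half)) {
    out[i] <- mean(x[1:(i + half)])
    out[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  as.numeric(out)
}

#' Extract the melting temperature from a melt curve
#'
#' `"derivative"` (default): the ratio is smoothed with a centered 5-point
#' moving average and differentiated by central differences; the derivative
#' peak locates the transition, which is then refined to the half-height
#' crossing of the baseline-normalized unfolded fraction (the exact melting
#' midpoint of a two-state curve, insensitive to baseline tilt). A curve
#' without a clear unfolding transition (derivative peak less than 5x the
#' median absolute derivative) is flagged and returns no T_m.
#' `"two_state_fit"`: nonlinear least-squares fit of the
#' [simulate_melt_curve()] model (T_m, enthalpy, four baseline parameters),
#' initialised from the derivative method.
#'
#' @param curve A `melt_curve` (any data frame with `temperature_C`, `ratio`).
#' @param method `"derivative"` or `"two_state_fit"`.
#' @return An object of class `melt_fit` with `t_m` (degrees C), `method`,
#'   `ok` flag, and for the model fit also `enthalpy` (kJ/mol) and baseline
#'   parameters.
#' @export
extract_tm <- function(curve, method = c("derivative", "two_state_fit")) {
  method <- match.arg(method)
  tc <- curve$temperature_C
  y <- curve$ratio
  if (length(tc) < 50) stop("need >= 50 temperature points")
  sm <- moving_average(y, 5L)
  d <- c(NA, (sm[-(1:2)] - sm[1:(length(sm) - 2)]) /
           (tc[-(1:2)] - tc[1:(length(tc) - 2)]), NA)
  dsm <- moving_average(ifelse(is.na(d), 0, d), 5L)
  inner <- 3:(length(tc) - 2)
  peak <- inner[which.max(abs(dsm[inner]))]
  prominence <- abs(dsm[peak]) / (stats::median(abs(dsm[inner])) + 1e-12)
  fail <- structure(list(t_m = NA_real_, method = method, ok = FALSE),
                    class = "melt_fit")
  if (prominence < 5) return(fail)
  # sub-grid refinement: estimate the native/unfolded baselines away from the
  # transition, normalize to the unfolded fraction and take its half-height
  # crossing (exactly T_m in the two-state model, unbiased by baseline tilt).
  tm_hat <- tc[peak]
  lo_mask <- tc <= tm_hat - 12
  hi_mask <- tc >= tm_hat + 12
  if (sum(lo_mask) > 4 && sum(hi_mask) > 4) {
    norm_fu <- function(lo, hi) {
      b_n <- stats::coef(stats::lm(sm[lo] ~ tc[lo]))
      b_u <- stats::coef(stats::lm(sm[hi] ~ tc[hi]))
      (sm - (b_n[1] + b_n[2] * tc)) /
        ((b_u[1] + b_u[2] * tc) - (b_n[1] + b_n[2] * tc))
    }
    fu <- norm_fu(lo_mask, hi_mask)
    # one re-estimation pass with transition tails excluded from the baselines
    lo2 <- lo_mask & fu < 0.02
    hi2 <- hi_mask & fu > 0.98
    if (sum(lo2) > 4 && sum(hi2) > 4) fu <- norm_fu(lo2, hi2)
    near <- which(abs(tc - tm_hat) <= 6)
    cross <- near[which(diff(sign(fu[near] - 0.5)) > 0)]
    if (length(cross)) {
      i <- cross[1]
      tm_hat <- tc[i] + (0.5 - fu[i]) / (fu[i + 1] - fu[i]) *
        (tc[i + 1] - tc[i])
    }
  }
  if (method == "derivative")
    return(structure(list(t_m = tm_hat, method = method, ok = TRUE),
                     class = "melt_fit"))
  lo_mask2 <- tc <= tm_hat - 10
  hi_mask2 <- tc >= tm_hat + 10
  b_n <- if (sum(lo_mask2) > 2)
    stats::coef(stats::lm(y[lo_mask2] ~ tc[lo_mask2])) else c(min(y), 0)
  b_u <- if (sum(hi_mask2) > 2)
    stats::coef(stats::lm(y[hi_mask2] ~ tc[hi_mask2])) else c(max(y), 0)
  fit <- try(minpack.lm::nlsLM(
    y ~ two_state_signal(tc, tm, dh, n0, n1, u0, u1),
    start = list(tm = tm_hat, dh = 300, n0 = unname(b_n[1]),
                 n1 = unname(b_n[2]), u0 = unname(b_u[1]),
                 u1 = unname(b_u[2])),
    lower = c(tm = min(tc), dh = 10, n0 = -Inf, n1 = -Inf, u0 = -Inf,
              u1 = -Inf),
    upper = c(tm = max(tc), dh = 5000, n0 = Inf, n1 = Inf, u0 = Inf,
              u1 = Inf),
    data = data.frame(tc = tc, y = y),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail)
  cf <- stats::coef(fit)
  structure(list(t_m = unname(cf[["tm"]]), enthalpy = unname(cf[["dh"]]),
                 baselines = list(native_intercept = unname(cf[["n0"]]),
                                  native_slope = unname(cf[["n1"]]),
                                  unfolded_intercept = unname(cf[["u0"]]),
                                  unfolded_slope = unname(cf[["u1"]])),
                 method = method, ok = TRUE),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (!x$ok) cat("T_m extraction (", x$method, "): no unfolding transition\n",
                 sep = "")
  else cat(sprintf("T_m = %.2f C (%s)\n", x$t_m, x$method))
  invisible(x)
}

#' Fit K_D from ligand-dependent thermal stabilization
#'
#' Fits the saturation model `dT_m(L) = dT_m_max * L / (K_D + L)` to
#' (concentration, T_m) pairs by nonlinear least squares, with dT_m measured
#' against the mean apo (zero-ligand) T_m. A warning is issued when the fitted
#' K_D falls outside the sampled concentration range; a titration with no
#' stabilization beyond `noise_floor` is flagged as a non-binder.
#'
#' @param concentration Ligand concentrations in mol/L; must include at least
#'   one zero (apo) point and >= 5 distinct non-zero concentrations spanning
#'   at least two orders of magnitude.
#' @param t_m Extracted melting temperatures in degrees C, same length.
#' @param noise_floor dT_m magnitude (degrees C) below which stabilization is
#'   indistinguishable from noise (default 0.5).
#' @return An object of class `binding_fit` with `K_D` (mol/L), `dT_m_max`
#'   (degrees C), standard errors, `converged` and `binder` flags.
#' @export
fit_kd_from_shifts <- function(concentration, t_m, noise_floor = 0.5) {
  if (length(concentration) != length(t_m)) stop("length mismatch")
  if (!any(concentration == 0)) stop("titration must include an apo point")
  nz <- sort(unique(concentration[concentration > 0]))
  if (length(nz) < 5) stop("need >= 5 non-zero concentrations")
  if (max(nz) / min(nz) < 100)
    warning("concentrations span less than two orders of magnitude")
  tm_apo <- mean(t_m[concentration == 0])
  dtm <- t_m - tm_apo
  non_binder <- structure(list(K_D = NA_real_, dT_m_max = NA_real_,
                               K_D_se = NA_real_, dT_m_max_se = NA_real_,
                               t_m_apo = tm_apo, converged = FALSE,
                               binder = FALSE), class = "binding_fit")
  if (all(dtm[concentration > 0] <= noise_floor)) return(non_binder)
  L <- concentration
  fit <- try(minpack.lm::nlsLM(
    dtm ~ dmax * L / (kd + L),
    start = list(dmax = max(dtm), kd = stats::median(nz)),
    lower = c(dmax = 0, kd = min(nz) / 100),
    upper = c(dmax = Inf, kd = max(nz) * 100),
    data = data.frame(L = L, dtm = dtm),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(non_binder)
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(dmax = NA_real_, kd = NA_real_))
  if (cf[["kd"]] < min(nz) || cf[["kd"]] > max(nz))
    warning("fitted K_D lies outside the sampled concentration range")
  structure(list(K_D = unname(cf[["kd"]]), dT_m_max = unname(cf[["dmax"]]),
                 K_D_se = unname(se[["kd"]]), dT_m_max_se = unname(se[["dmax"]]),
                 t_m_apo = tm_apo, converged = TRUE, binder = TRUE),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$binder) cat("Thermal-shift titration: non-binder (no stabilization)\n")
  else cat(sprintf(
    "K_D = %.4g +/- %.2g mol/L, dT_m_max = %.3g +/- %.2g C (apo T_m %.2f C)\n",
    x$K_D, x$K_D_se, x$dT_m_max, x$dT_m_max_se, x$t_m_apo))
  invisible(x)
}

#' Ligand screening table of thermal shifts
#'
#' Summarises a set of melt curves into mean dT_m per ligand relative to the
#' mean apo melting temperature.
#'
#' @param curves List of `melt_curve` objects (apo curves have ligand
#'   `"apo"`).
#' @param method T_m extraction method passed to [extract_tm()].
#' @return Data frame with columns `ligand`, `mean_dT_m`, `sd_dT_m`, `n`.
#' @export
screen_delta_tm <- function(curves, method = "derivative") {
  tm <- vapply(curves, function(cv) extract_tm(cv, method)$t_m, numeric(1))
  lig <- vapply(curves, function(cv) attr(cv, "ligand"), character(1))
  apo <- mean(tm[lig == "apo"])
  if (!is.finite(apo)) stop("screen requires apo curves labelled 'apo'")
  dt <- tm - apo
  out <- do.call(rbind, lapply(split(dt, lig), function(v)
    data.frame(mean_dT_m = mean(v), sd_dT_m = stats::sd(v), n = length(v))))
  out <- data.frame(ligand = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$mean_dT_m), ]
}
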