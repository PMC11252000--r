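# Measurement procedures on trace and table inputs: evoked currents,
# acidification slopes, the acidification/current ratio statistic, Faraday
# current-to-flux conversion, pyranine ratio processing and tracer
# quantification.
#
# Sign conventions: inward currents are negative at the trace level;
# acidification rates are reported positive for falling intracellular pH.

#' Uniform time-series container for assay traces
#'
#' @param time Time in seconds, strictly increasing, uniform grid.
#' @param channels Named list of numeric channels (`current_nA`,
#'   `electrode_mV`, `F415`, `F460`, ...), each the length of `time`.
#' @param events Data frame with columns `label`, `start_s`, `end_s`; every
#'   window must lie inside the time span.
#' @param metadata Named list (holding potential, pH_out, cell id, ...).
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(time, channels, events = NULL, metadata = list()) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!length(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list")
  for (nm in names(channels))
    if (length(channels[[nm]]) != length(time))
      stop("channel '", nm, "' length differs from time")
  if (!is.null(events)) {
    if (!all(c("label", "start_s", "end_s") %in% names(events)))
      stop("events need columns label, start_s, end_s")
    if (any(events$start_s < min(time) - 1e-9) ||
        any(events$end_s > max(time) + 1e-9))
      stop("event windows must lie inside the time span")
    if (any(events$end_s <= events$start_s))
      stop("event end must exceed its start")
  }
  structure(list(time = time, channels = channels, events = events,
                 metadata = metadata), class = "assay_trace")
}

#' @export
print.assay_trace <- function(x, ...) {
  cat(sprintf("Assay trace: %d samples, %.1f-%.1f s, channels: %s\n",
              length(x$time), min(x$time), max(x$time),
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$events))
    cat("  events:", paste(x$events$label, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.assay_trace <- function(x, channel = names(x$channels)[1], ...) {
  graphics::plot(x$time, x$channels[[channel]], type = "l",
                 xlab = "time (s)", ylab = channel, ...)
  if (!is.null(x$events))
    graphics::abline(v = c(x$events$start_s, x$events$end_s), lty = 3,
                     col = "grey50")
  invisible(x)
}

event_window <- function(trace, label) {
  ev <- trace$events
  i <- match(label, ev$label)
  if (is.na(i)) stop("no event labelled '", label, "'")
  c(ev$start_s[i], ev$end_s[i])
}

window_mask <- function(time, window)
  time >= window[1] & time <= window[2]

#' Substrate-evoked current from a clamped trace
#'
#' Mean current over the substrate plateau window minus the mean over the
#' baseline window; inward currents are negative.
#'
#' @param trace An [assay_trace()] with a `current_nA` channel.
#' @param substrate_event,baseline_event Event labels (or length-2 numeric
#'   windows in seconds); each window must cover >= 2 s and the two may not
#'   overlap.
#' @return Evoked current in nA.
#' @export
evoked_current <- function(trace, substrate_event, baseline_event) {
  stopifnot(inherits(trace, "assay_trace"))
  w_s <- if (is.character(substrate_event)) event_window(trace, substrate_event)
    else substrate_event
  w_b <- if (is.character(baseline_event)) event_window(trace, baseline_event)
    else baseline_event
  if (diff(w_s) < 2 || diff(w_b) < 2) stop("windows must cover >= 2 s")
  if (w_s[1] < w_b[2] && w_b[1] < w_s[2])
    stop("baseline and substrate windows overlap")
  i <- trace$channels$current_nA
  if (is.null(i)) stop("trace has no current_nA channel")
  mean(i[window_mask(trace$time, w_s)]) - mean(i[window_mask(trace$time, w_b)])
}

#' Acidification rate from an intracellular pH electrode trace
#'
#' Least-squares slope of the ion-selective electrode voltage over the window,
#' converted to a pH rate with the electrode calibration slope (default -59
#' mV per pH unit). The rate is reported positive for acidification, i.e.
#' `acid_rate = (dV/dt) / calibration_slope`: with the standard negative
#' calibration slope, a falling voltage trace reads as acidification.
#'
#' @param trace An [assay_trace()] with an `electrode_mV` channel.
#' @param window Event label or length-2 numeric window (>= 10 s).
#' @param electrode_slope_mV_per_pH Calibration slope in mV per pH unit;
#'   non-zero (default -59).
#' @return List with `pH_per_s` (positive = acidification), `mV_per_s` (raw
#'   slope) and `se_pH_per_s`.
#' @export
acidification_slope <- function(trace, window,
                                electrode_slope_mV_per_pH = -59) {
  stopifnot(inherits(trace, "assay_trace"))
  if (electrode_slope_mV_per_pH == 0) stop("calibration slope must be non-zero")
  w <- if (is.character(window)) event_window(trace, window) else window
  if (diff(w) < 10) stop("acidification window must cover >= 10 s")
  v <- trace$channels$electrode_mV
  if (is.null(v)) stop("trace has no electrode_mV channel")
  keep <- window_mask(trace$time, w)
  fit <- stats::lm(v[keep] ~ trace$time[keep])
  sm <- summary(fit)$coefficients
  mv_s <- unname(sm[2, 1])
  list(pH_per_s = mv_s / electrode_slope_mV_per_pH, mV_per_s = mv_s,
       se_pH_per_s = unname(sm[2, 2]) / abs(electrode_slope_mV_per_pH))
}

#' Acidification/current ratio per substrate, normalized within a cell
#'
#' Normalizes each substrate's evoked current and acidification rate to those
#' of a reference substrate measured in the same cell, and reports
#' `r_hat = (acid_X / acid_ref) / (I_X / I_ref)`, an estimate of the protons
#' released per translocated elementary charge. Because both signals are
#' normalized within the cell, the (unknown) buffering capacity cancels.
#' Results are valid only when the reference current magnitude exceeds the
#' proportionality threshold (~100 nA); the threshold flags validity and does
#' not exclude test substrates.
#'
#' @param cell_results Data frame with columns `substrate`, `current_nA`
#'   (signed, inward negative) and `acid_rate` (positive = acidification), one
#'   row per substrate from the same cell.
#' @param reference Reference substrate name; must be present.
#' @param threshold_nA Validity threshold on the reference current magnitude
#'   (default 100).
#' @return Data frame with columns `substrate`, `normalized_current`,
#'   `normalized_acidification`, `ratio`, `valid`. The reference row has
#'   ratio exactly 1.
#' @export
acid_current_ratio <- function(cell_results, reference, threshold_nA = 100) {
  need <- c("substrate", "current_nA", "acid_rate")
  if (!all(need %in% names(cell_results)))
    stop("cell_results needs columns ", paste(need, collapse = ", "))
  i_ref <- match(reference, cell_results$substrate)
  if (is.na(i_ref)) stop("reference substrate '", reference,
                         "' not measured in this cell")
  ref_i <- cell_results$current_nA[i_ref]
  ref_a <- cell_results$acid_rate[i_ref]
  valid <- abs(ref_i) >= threshold_nA
  if (!valid)
    warning("reference current below the ~", threshold_nA,
            " nA proportionality threshold; ratios flagged invalid")
  ni <- cell_results$current_nA / ref_i
  na_ <- cell_results$acid_rate / ref_a
  ratio <- ifelse(ni != 0, na_ / ni, NA_real_)
  ratio[i_ref] <- 1
  data.frame(substrate = cell_results$substrate, normalized_current = ni,
             normalized_acidification = na_, ratio = ratio, valid = valid,
             stringsAsFactors = FALSE)
}

#' Convert a transport current to a substrate flux
#'
#' `|I| / (|z| F)`, converted to pmol/s. Electroneutral transport (z = 0)
#' carries no current and is an error.
#'
#' @param I_nA Current in nA (sign ignored).
#' @param z Transported charge in elementary charges; non-zero.
#' @return Flux in pmol/s.
#' @examples
#' current_to_flux(-300, 1)  # ~3.11 pmol/s
#' @export
current_to_flux <- function(I_nA, z) {
  if (any(z == 0)) stop("z must be non-zero (electroneutral transport carries no current)")
  abs(I_nA) * 1e-9 / (abs(z) * physical_constants()$faraday) * 1e12
}

#' Normalized pyranine excitation ratio
#'
#' Divides the 415 nm-excitation fluorescence by the 460 nm-excitation
#' fluorescence and normalizes the ratio to its mean over the first 25 s after
#' peptide addition, so the normalized trace is 1.0 on that window by
#' construction.
#'
#' @param trace An [assay_trace()] with `F415` and `F460` channels.
#' @param peptide_event Event label or numeric start time of peptide addition;
#'   at least 25 s of trace must follow it.
#' @return Data frame with columns `time_s` and `F_norm`.
#' @export
pyranine_normalized_ratio <- function(trace, peptide_event = "peptide") {
  stopifnot(inherits(trace, "assay_trace"))
  f415 <- trace$channels$F415
  f460 <- trace$channels$F460
  if (is.null(f415) || is.null(f460))
    stop("trace needs F415 and F460 channels")
  t0 <- if (is.character(peptide_event))
    event_window(trace, peptide_event)[1] else peptide_event[1]
  if (max(trace$time) < t0 + 25)
    stop("need >= 25 s of trace after peptide addition")
  if (any(f460 == 0)) stop("zero samples in the denominator channel")
  ratio <- f415 / f460
  norm_mask <- trace$time >= t0 & trace$time <= t0 + 25
  data.frame(time_s = trace$time, F_norm = ratio / mean(ratio[norm_mask]))
}

#' Uptake rates as a percentage of a reference substrate
#'
#' @param rates Named numeric vector of initial uptake rates.
#' @param reference Name of the reference substrate; its rate must be
#'   non-zero.
#' @return Named numeric vector of percentages (reference = 100).
#' @export
uptake_rate_percent_of_reference <- function(rates, reference) {
  if (!reference %in% names(rates)) stop("reference rate missing")
  if (rates[[reference]] == 0) stop("reference rate must be non-zero")
  100 * rates / rates[[reference]]
}

#' Absolute tracer quantification against calibration standards
#'
#' Fits a linear calibration (with intercept, to absorb blank signal) through
#' known-amount standards for each analyte, interpolates sample peak areas to
#' absolute amounts, converts amounts to uptake rates over the incubation
#' duration, and reports released-product amount ratios.
#'
#' @param sample_areas Data frame with columns `analyte`, `sample_id`, `area`.
#' @param standards Data frame with columns `analyte`, `amount_pmol`, `area`;
#'   >= 4 standards per analyte spanning the sample range.
#' @param duration_s Incubation duration in seconds.
#' @param products Optional character pair `c(numerator, denominator)` of
#'   analyte names for the released-product ratio (e.g. Ala over the heavy
#'   leucine).
#' @return List with `amounts` (data frame adding `amount_pmol`,
#'   `rate_pmol_per_s`, `extrapolated`), `calibration` (per-analyte slope and
#'   intercept) and, when `products` is given, `product_ratio` (mean ratio of
#'   per-sample amounts) with `product_ratios` per sample.
#' @export
tracer_quantify <- function(sample_areas, standards, duration_s,
                            products = NULL) {
  need <- c("analyte", "sample_id", "area")
  if (!all(need %in% names(sample_areas)))
    stop("sample_areas needs columns ", paste(need, collapse = ", "))
  if (!all(c("analyte", "amount_pmol", "area") %in% names(standards)))
    stop("standards needs columns analyte, amount_pmol, area")
  if (duration_s <= 0) stop("duration_s must be positive")
  cal <- lapply(split(standards, standards$analyte), function(st) {
    if (nrow(st) < 4) stop("need >= 4 standards per analyte")
    fit <- stats::lm(area ~ amount_pmol, data = st)
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         range = range(st$amount_pmol))
  })
  out <- sample_areas
  out$amount_pmol <- NA_real_
  out$extrapolated <- FALSE
  for (k in seq_len(nrow(out))) {
    cc <- cal[[out$analyte[k]]]
    if (is.null(cc)) stop("no standards for analyte '", out$analyte[k], "'")
    amt <- (out$area[k] - cc$intercept) / cc$slope
    out$amount_pmol[k] <- amt
    out$extrapolated[k] <- amt < cc$range[1] || amt > cc$range[2]
  }
  if (any(out$extrapolated))
    warning("some samples fall outside the standard range (flagged)")
  out$rate_pmol_per_s <- out$amount_pmol / duration_s
  res <- list(amounts = out,
              calibration = do.call(rbind, lapply(names(cal), function(a)
                data.frame(analyte = a, intercept = cal[[a]]$intercept,
                           slope = cal[[a]]$slope,
                           stringsAsFactors = FALSE))))
  if (!is.null(products)) {
    stopifnot(length(products) == 2)
    num <- out[out$analyte == products[1], c("sample_id", "amount_pmol")]
    den <- out[out$analyte == products[2], c("sample_id", "amount_pmol")]
    m <- merge(num, den, by = "sample_id", suffixes = c("_num", "_den"))
    ratios <- m$amount_pmol_num / m$amount_pmol_den
    res$product_ratios <- stats::setNames(ratios, m$sample_id)
    res$product_ratio <- mean(ratios)
  }
  res
}
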