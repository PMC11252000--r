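make_square_trace <- function() {
  t <- seq(0, 120, by = 0.1)
  i <- ifelse(t >= 60 & t < 100, -300, 0)
  assay_trace(t, channels = list(current_nA = i),
              events = data.frame(label = c("sub", "base"),
                                  start_s = c(70, 30),
                                  end_s = c(95, 55)))
}

test_that("evoked currents are plateau-minus-baseline means", {
  expect_equal(evoked_current(make_square_trace(), "sub", "base"), -300)
  tr <- make_square_trace()
  expect_error(evoked_current(tr, c(40, 80), c(30, 55)), "overlap")
  expect_error(evoked_current(tr, c(70, 70.5), c(30, 55)), ">= 2 s")
  set.seed(1)
  noisy <- tr
  noisy$channels$current_nA <- noisy$channels$current_nA +
    0.01 * noisy$time + rnorm(length(noisy$time), 0, 5)
  expect_equal(evoked_current(noisy, "sub", "base"), -300,
               tolerance = 0.1 * 300 / 300)
})

test_that("acidification slopes convert electrode voltage by the calibration", {
  t <- seq(0, 100, by = 0.1)
  v <- 10 - 0.059 * t  # falls 5.9 mV over 100 s
  tr <- assay_trace(t, channels = list(electrode_mV = v))
  a <- acidification_slope(tr, c(0, 100), -59)
  expect_equal(a$pH_per_s, 1e-3, tolerance = 1e-9)
  expect_equal(a$mV_per_s, -0.059, tolerance = 1e-9)
  # doubling the calibration slope halves the pH rate
  expect_equal(acidification_slope(tr, c(0, 100), -118)$pH_per_s, 0.5e-3,
               tolerance = 1e-9)
  # flat trace: zero rate
  flat <- assay_trace(t, channels = list(electrode_mV = rep(1, length(t))))
  expect_equal(acidification_slope(flat, c(0, 100))$pH_per_s, 0)
  expect_error(acidification_slope(tr, c(0, 5)), ">= 10 s")
  expect_error(acidification_slope(tr, c(0, 100), 0), "non-zero")
})

test_that("acidification/current ratios normalize within the cell", {
  cell <- data.frame(
    substrate = c("His-Ala", "His-Ser", "Lys-Ala", "His-Glu"),
    current_nA = c(-300, -250, -280, -240),
    acid_rate = c(2e-4, 2e-4 * 250 / 300, 0, 2 * 2e-4 * 240 / 300))
  rs <- acid_current_ratio(cell, "His-Ala")
  expect_equal(rs$ratio[rs$substrate == "His-Ala"], 1)
  expect_equal(rs$ratio[rs$substrate == "His-Ser"], 1, tolerance = 1e-9)
  expect_equal(rs$ratio[rs$substrate == "Lys-Ala"], 0, tolerance = 1e-9)
  expect_equal(rs$ratio[rs$substrate == "His-Glu"], 2, tolerance = 1e-9)
  expect_true(all(rs$valid))
  # sub-threshold reference flags everything invalid
  weak <- cell
  weak$current_nA[1] <- -50
  expect_warning(rs2 <- acid_current_ratio(weak, "His-Ala"), "threshold")
  expect_false(any(rs2$valid))
  expect_error(acid_current_ratio(cell, "Gly-Gly"), "reference")
})

test_that("Faraday conversion turns currents into molar fluxes", {
  expect_equal(current_to_flux(-300, 1), 3.11, tolerance = 1e-3)
  expect_equal(current_to_flux(-96.485332, 1), 1.0, tolerance = 1e-9)
  expect_equal(current_to_flux(-300, 2), current_to_flux(-300, 1) / 2)
  # round-trip with the flux -> current map
  flux <- 3.11
  expect_equal(current_to_flux(flux * 1 * 96485.332 * 1e-3, 1), flux,
               tolerance = 1e-12)
  expect_error(current_to_flux(-300, 0), "non-zero")
})

test_that("pyranine normalization fixes the post-peptide window at 1", {
  t <- seq(0, 300, by = 0.5)
  ev <- data.frame(label = c("peptide", "valinomycin"),
                   start_s = c(30, 60), end_s = c(31, 61))
  # constant channels: constant 1.0
  tr <- assay_trace(t, channels = list(F415 = rep(1200, length(t)),
                                       F460 = rep(1000, length(t))),
                    events = ev)
  fn <- pyranine_normalized_ratio(tr, "peptide")
  expect_equal(fn$F_norm, rep(1, length(t)))
  # declining ratio: normalization window mean is exactly 1
  decl <- 1 - 0.001 * pmax(t - 60, 0)
  tr2 <- assay_trace(t, channels = list(F415 = 1200 * decl,
                                        F460 = rep(1000, length(t))),
                     events = ev)
  fn2 <- pyranine_normalized_ratio(tr2, "peptide")
  expect_equal(mean(fn2$F_norm[t >= 30 & t <= 55]), 1, tolerance = 1e-12)
  expect_lt(fn2$F_norm[length(t)], 0.8)
  expect_error(pyranine_normalized_ratio(tr, 290), "25 s")
})

test_that("rates normalize to percent of the reference substrate", {
  rates <- c("His-Ser" = -0.0016, "His-Ala" = -0.0008, "Lys-Ala" = 0)
  pct <- uptake_rate_percent_of_reference(rates, "His-Ser")
  expect_equal(unname(pct["His-Ser"]), 100)
  expect_equal(unname(pct["His-Ala"]), 50)
  expect_equal(unname(pct["Lys-Ala"]), 0)
  expect_error(uptake_rate_percent_of_reference(rates, "Gly-Gly"), "missing")
})

test_that("tracer quantification interpolates exact standards exactly", {
  std <- data.frame(analyte = "Ala", amount_pmol = c(10, 20, 40, 80),
                    area = 500 + 90 * c(10, 20, 40, 80))
  smp <- data.frame(analyte = "Ala", sample_id = "o1", area = 500 + 90 * 30)
  q <- tracer_quantify(smp, std, duration_s = 1200)
  expect_equal(q$amounts$amount_pmol, 30, tolerance = 1e-9)
  expect_equal(q$amounts$rate_pmol_per_s, 30 / 1200, tolerance = 1e-9)
  expect_false(q$amounts$extrapolated)
  # outside the standard range: flagged
  far <- data.frame(analyte = "Ala", sample_id = "o2", area = 500 + 90 * 500)
  expect_warning(q2 <- tracer_quantify(far, std, 1200), "outside")
  expect_true(q2$amounts$extrapolated)
  expect_error(tracer_quantify(smp, std[1:3, ], 1200), ">= 4 standards")
})
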