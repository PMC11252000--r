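test_that("simulated melt curves are deterministic two-state sigmoids", {
  cv <- simulate_melt_curve(40, noise_sd = 0)
  # derivative peaks at T_m within grid resolution
  d <- diff(cv$ratio) / diff(cv$temperature_C)
  expect_equal(cv$temperature_C[which.max(d)], 40, tolerance = 0.5)
  # unfolded fraction is 0.5 at T_m: signal midway between the baselines
  i <- which(cv$temperature_C == 40)
  nat <- 0.80 + 5e-4 * 40
  unf <- 0.95 + 1.5e-3 * 40
  expect_equal(cv$ratio[i], (nat + unf) / 2, tolerance = 1e-9)
  expect_identical(simulate_melt_curve(40, seed = 3)$ratio,
                   simulate_melt_curve(40, seed = 3)$ratio)
  expect_false(identical(simulate_melt_curve(40, seed = 3)$ratio,
                         simulate_melt_curve(40, seed = 4)$ratio))
  expect_error(simulate_melt_curve(10), "inside the temperature grid")
})

test_that("T_m extraction hits known melting temperatures", {
  # noiseless: both methods recover the apo-like T_m
  cv <- simulate_melt_curve(40.0, noise_sd = 0)
  expect_equal(extract_tm(cv, "derivative")$t_m, 40.0, tolerance = 0.1)
  expect_equal(extract_tm(cv, "two_state_fit")$t_m, 40.0, tolerance = 1e-3)
  # stabilized-mutant-like curve at default noise
  cv2 <- simulate_melt_curve(46.6, seed = 11)
  expect_equal(extract_tm(cv2, "two_state_fit")$t_m, 46.6, tolerance = 0.2)
  # a ligand-induced +12.1 C shift is recovered from curve pairs
  sh <- extract_tm(simulate_melt_curve(52.1, seed = 21))$t_m -
    extract_tm(simulate_melt_curve(40.0, seed = 22))$t_m
  expect_equal(sh, 12.1, tolerance = 0.5)
})

test_that("T_m extraction error stays within 0.2 C at default noise", {
  err <- vapply(1:100, function(s)
    extract_tm(simulate_melt_curve(40, seed = s))$t_m - 40, numeric(1))
  expect_lte(mean(abs(err)), 0.2)
  # apo replicates differ by ~0 dT_m
  expect_lte(abs(mean(err[1:5]) - mean(err[6:10])), 0.2)
})

test_that("featureless curves are flagged instead of yielding a T_m", {
  base <- simulate_melt_curve(40, noise_sd = 0)
  flat <- base
  set.seed(2)
  flat$ratio <- 0.9 + rnorm(nrow(flat), 0, 0.002)
  expect_false(extract_tm(flat)$ok)
  mono <- base
  mono$ratio <- 0.8 + 0.002 * mono$temperature_C
  expect_false(extract_tm(mono)$ok)
  expect_true(is.na(extract_tm(flat)$t_m))
})

test_that("K_D is recovered from thermal-stabilization titrations", {
  concs <- c(0, 10^seq(-5, -2, by = 0.5))
  # noiseless titration at the printed Pro-Arg-like affinity
  tm <- 40 + 12 * concs / (318e-6 + concs)
  fit <- fit_kd_from_shifts(concs, tm)
  expect_true(fit$binder)
  expect_equal(fit$K_D, 318e-6, tolerance = 0.01)
  expect_equal(fit$dT_m_max, 12, tolerance = 0.01)
  # no stabilization: flagged non-binder
  nb <- fit_kd_from_shifts(concs, rep(40, length(concs)))
  expect_false(nb$binder)
  expect_true(is.na(nb$K_D))
  expect_error(fit_kd_from_shifts(concs[-1], tm[-1]), "apo")
})

test_that("K_D recovery holds across seeded titrations with T_m noise", {
  concs <- c(0, 10^seq(-5, -2, by = 0.5))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    tm <- 40 + 12 * concs / (318e-6 + concs) + rnorm(length(concs), 0, 0.3)
    fit <- suppressWarnings(fit_kd_from_shifts(concs, tm))
    abs(fit$K_D - 318e-6) / 318e-6
  }, numeric(1))
  expect_lte(median(errs), 0.20)
})

test_that("the screening table reports mean shifts against apo", {
  curves <- c(
    lapply(1:2, function(i) simulate_melt_curve(40, seed = i)),
    lapply(3:4, function(i) simulate_melt_curve(52.1, seed = i,
                                                ligand = "Pro-Arg",
                                                conc_M = 5e-3)),
    lapply(5:6, function(i) simulate_melt_curve(54, seed = i,
                                                ligand = "Leu-Leu",
                                                conc_M = 5e-3)))
  scr <- screen_delta_tm(curves)
  expect_setequal(scr$ligand, c("apo", "Pro-Arg", "Leu-Leu"))
  expect_equal(scr$mean_dT_m[scr$ligand == "apo"], 0, tolerance = 0.25)
  expect_equal(scr$mean_dT_m[scr$ligand == "Pro-Arg"], 12.1, tolerance = 0.5)
  expect_gt(scr$mean_dT_m[scr$ligand == "Leu-Leu"],
            scr$mean_dT_m[scr$ligand == "Pro-Arg"])
})
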