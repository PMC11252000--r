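test_that("generators are pure functions of config and seed", {
  sc <- scenario_config(seed = 5)
  a <- generate_tevc_phin_experiment(sc)
  b <- generate_tevc_phin_experiment(sc)
  expect_identical(a$trace$channels, b$trace$channels)
  c_ <- generate_tevc_phin_experiment(sc, seed = 6)
  expect_false(identical(a$trace$channels$current_nA,
                         c_$trace$channels$current_nA))
  expect_identical(generate_tracer_experiment(sc)$sample_areas,
                   generate_tracer_experiment(sc)$sample_areas)
  expect_identical(generate_genotype_table(sc)$table,
                   generate_genotype_table(sc)$table)
})

test_that("zero-noise dual recording is recovered exactly downstream", {
  sc <- scenario_config(seed = 1,
                        noise = list(current_nA = 0, electrode_mV = 0,
                                     fluor_frac = 0, area_frac = 0),
                        drift_nA_per_s = 0)
  exp <- generate_tevc_phin_experiment(sc)
  res <- analyze_tevc_experiment(exp$trace)
  truth <- setNames(exp$truth$r, exp$truth$substrate)
  for (s in res$ratios$substrate)
    expect_equal(res$ratios$ratio[res$ratios$substrate == s],
                 unname(truth[s]), tolerance = 1e-6)
  # evoked currents match the Michaelis-Menten amplitudes
  amp <- setNames(exp$truth$amplitude_nA, exp$truth$substrate)
  for (s in res$cell_results$substrate)
    expect_equal(res$cell_results$current_nA[res$cell_results$substrate == s],
                 unname(amp[s]), tolerance = 1e-2)
})

test_that("the buffering constant kappa cancels from the ratio statistic", {
  base <- scenario_config(seed = 3)
  doubled <- scenario_config(seed = 3, kappa = base$kappa * 2)
  r1 <- analyze_tevc_experiment(generate_tevc_phin_experiment(base)$trace)
  r2 <- analyze_tevc_experiment(generate_tevc_phin_experiment(doubled)$trace)
  # acidification doubles for the proton-releasing substrates...
  his <- grep("^His", r1$cell_results$substrate)
  expect_equal(r2$cell_results$acid_rate[his] /
                 r1$cell_results$acid_rate[his],
               rep(2, length(his)), tolerance = 0.05)
  # ...but the normalized ratio statistic is unchanged
  expect_equal(r2$ratios$ratio, r1$ratios$ratio, tolerance = 0.02)
})

test_that("pyranine generation distinguishes carriers, non-carriers and empty", {
  sc <- scenario_config(seed = 2)
  py <- generate_pyranine_experiment(sc)
  # proton-carrying substrate in transporter liposomes declines
  hs <- py[["mmMFSD1:His-Ser"]]
  fn <- pyranine_normalized_ratio(hs$trace)
  t_val <- 60
  r <- initial_rate(fn$time_s, fn$F_norm, c(t_val, t_val + 60))
  expect_equal(r$slope, hs$truth$initial_rate_Fnorm_s, tolerance = 0.1)
  expect_equal(hs$truth$initial_rate_Fnorm_s,
               mm_velocity(2.5e-3, 24.4e-6, -0.001731), tolerance = 1e-9)
  # a substrate whose species carries no proton leaves the trace flat
  ka <- py[["mmMFSD1:Lys-Ala"]]
  fn_ka <- pyranine_normalized_ratio(ka$trace)
  expect_equal(ka$truth$initial_rate_Fnorm_s, 0)
  expect_lt(abs(initial_rate(fn_ka$time_s, fn_ka$F_norm,
                             c(t_val, t_val + 60))$slope), 1e-4)
  # empty liposomes stay at 1 within noise
  em <- py[["empty:His-Ala"]]
  fn_em <- pyranine_normalized_ratio(em$trace)
  expect_equal(mean(fn_em$F_norm), 1, tolerance = 0.01)
  expect_lt(abs(initial_rate(fn_em$time_s, fn_em$F_norm,
                             c(t_val, t_val + 60))$slope), 1e-4)
})

test_that("tracer pipeline recovers complete cleavage and the uptake rate", {
  sc <- scenario_config(seed = 4)
  tx <- generate_tracer_experiment(sc)
  transported <- tx$sample_areas[tx$sample_areas$arm == "MFSD1-GLMP", ]
  q <- tracer_quantify(transported, tx$standards, tx$duration_s,
                       products = c("Ala", "Leu(d3)"))
  expect_equal(q$product_ratio, 1.0, tolerance = 0.1)
  leu <- q$amounts[q$amounts$analyte == "Leu(d3)", ]
  expect_equal(mean(leu$rate_pmol_per_s), tx$truth$rate_pmol_s,
               tolerance = 0.1)
  # mock arm sits at blank level
  mock <- tx$sample_areas[tx$sample_areas$arm == "mock", ]
  qm <- suppressWarnings(tracer_quantify(mock, tx$standards, tx$duration_s))
  expect_lt(max(abs(qm$amounts$amount_pmol)),
            0.05 * tx$truth$rate_pmol_s * tx$duration_s)
  # cleavage 0 keeps all signal in the intact dipeptide
  sc0 <- scenario_config(seed = 4,
                         tracer = list(rate_pmol_s = 1.32, duration_s = 1200,
                                       cleavage = 0, n_oocytes = 4,
                                       bio_cv = 0.08))
  tx0 <- generate_tracer_experiment(sc0)
  t0 <- tx0$sample_areas[tx0$sample_areas$arm == "MFSD1-GLMP", ]
  q0 <- suppressWarnings(tracer_quantify(t0, tx0$standards, tx0$duration_s))
  intact <- q0$amounts[q0$amounts$analyte == "Leu(d3)-Ala", "amount_pmol"]
  prod <- q0$amounts[q0$amounts$analyte == "Leu(d3)", "amount_pmol"]
  expect_equal(mean(intact), 1.32 * 1200, tolerance = 0.15)
  expect_lt(max(abs(prod)), 0.1 * mean(intact))
})

test_that("genotype tables carry configured fold changes past normalization", {
  sc <- scenario_config(seed = 8)
  gt <- generate_genotype_table(sc)
  tbl <- gt$table
  # internal-standard normalization removes the per-sample scale exactly:
  # rescaling every measurement of a sample leaves `normalized` unchanged
  tbl2 <- tbl
  scale <- ifelse(tbl2$genotype == "KO", 3.7, 0.4)
  tbl2$raw_abundance <- tbl2$raw_abundance * scale
  tbl2$internal_standard <- tbl2$internal_standard * scale
  expect_equal(tbl2$raw_abundance / tbl2$internal_standard, tbl$normalized,
               tolerance = 1e-12)
  # a 4-fold configured increase is detectable by t-test in most seeds
  hits <- vapply(1:20, function(s) {
    g <- generate_genotype_table(sc, seed = s)$table
    g <- g[g$dipeptide == "Arg-Pro", ]
    stats::t.test(normalized ~ genotype, data = g)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
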