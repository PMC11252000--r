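# Seeded generators for every input the analysis pipelines consume. Each
# generator is a pure function of (config, seed): identical inputs give
# identical outputs, and the ground truth used for generation is returned
# alongside the data so downstream estimates can be scored.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Scenario configuration for the synthetic experiments
#'
#' Bundles the substrates (with their transported-species weights and
#' kinetics), the membrane condition, noise levels and coupling constants of
#' the synthetic assays. Defaults reproduce the dual TEVC/pH recording
#' scenario: four substrates applied sequentially to the same cell at 10 mM
#' and pH_out 5.0, each transported purely as its cationic species, with ideal
#' stoichiometries {His-Ala: 1, His-Ser: 1, Lys-Ala: 0, His-Glu(+): 2} and
#' His-Ala as the within-cell reference.
#'
#' @param seed Integer seed.
#' @param substrates List of substrate definitions; each a list with `name`,
#'   `residues`, `weights` (named transport weights over microstate labels),
#'   `K_M` (mol/L), `v_max` (nA, negative for inward currents) and `dose`
#'   (mol/L).
#' @param condition A [membrane_condition()].
#' @param reference Name of the within-cell reference substrate.
#' @param kappa Oocyte acidification coupling in pH units per pmol of protons;
#'   lumps buffering capacity and accessible volume. The ratio statistic is
#'   designed to cancel it.
#' @param electrode_slope_mV_per_pH Electrode calibration (default -59).
#' @param noise Named list: `current_nA` (default 5), `electrode_mV` (0.02),
#'   `fluor_frac` (0.005, relative), `area_frac` (0.05, relative), `tm_C`
#'   (melt-curve signal noise handled by [simulate_melt_curve()]).
#' @param drift_nA_per_s Slow linear drift on the current channel.
#' @param liposome Named list: `valinomycin_mV` (-100), `response_lambda`
#'   (1/600 per s, luminal pH equilibration rate), `v_max_Fnorm_s` (-0.001731),
#'   `K_M` (24.4e-6 mol/L), `dose` (2.5e-3 mol/L).
#' @param tracer Named list: `rate_pmol_s` (1.32), `duration_s` (1200),
#'   `cleavage` (1.0), `n_oocytes` (4), `bio_cv` (0.08).
#' @param titration Named list: `K_D` (318e-6 mol/L), `dT_m_max` (12 C),
#'   `t_m_apo` (40 C), `concentrations` (mol/L, with 0 = apo, replicated).
#' @param genotype Named list: `fold_changes` (named), `n_per_group` (5),
#'   `cv` (0.3), `is_cv` (0.1), `scale_cv` (0.2).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1,
    substrates = list(
      list(name = "His-Ala", residues = "HA", weights = c("His+-Ala" = 1),
           K_M = 2.6e-3, v_max = -300, dose = 10e-3),
      list(name = "His-Ser", residues = "HS", weights = c("His+-Ser" = 1),
           K_M = 2.6e-3, v_max = -280, dose = 10e-3),
      list(name = "Lys-Ala", residues = "KA", weights = c("Lys+-Ala" = 1),
           K_M = 2.6e-3, v_max = -300, dose = 10e-3),
      list(name = "His-Glu", residues = "HE", weights = c("His+-Glu0" = 1),
           K_M = 2.6e-3, v_max = -250, dose = 10e-3)),
    condition = membrane_condition(pH_lum = 5.0, pH_cyt = 7.2,
                                   delta_psi = -0.040),
    reference = "His-Ala",
    kappa = 5e-5,
    electrode_slope_mV_per_pH = -59,
    noise = list(current_nA = 5, electrode_mV = 0.02, fluor_frac = 0.005,
                 area_frac = 0.05),
    drift_nA_per_s = 0.01,
    liposome = list(valinomycin_mV = -100, response_lambda = 1 / 600,
                    v_max_Fnorm_s = -0.001731, K_M = 24.4e-6, dose = 2.5e-3),
    tracer = list(rate_pmol_s = 1.32, duration_s = 1200, cleavage = 1.0,
                  n_oocytes = 4, bio_cv = 0.08),
    titration = list(K_D = 318e-6, dT_m_max = 12, t_m_apo = 40,
                     concentrations = c(0, 0, 0, 10 ^ seq(-5, -2, by = 0.5))),
    genotype = list(fold_changes = c("Arg-Pro" = 4, "Pro-Lys" = 3,
                                     "anserine" = 2.5),
                    n_per_group = 5, cv = 0.3, is_cv = 0.1, scale_cv = 0.2)) {
  stopifnot(inherits(condition, "membrane_condition"))
  if (!reference %in% vapply(substrates, `[[`, "", "name"))
    stop("reference substrate '", reference, "' missing from substrates")
  structure(list(seed = seed, substrates = substrates, condition = condition,
                 reference = reference, kappa = kappa,
                 electrode_slope_mV_per_pH = electrode_slope_mV_per_pH,
                 noise = noise, drift_nA_per_s = drift_nA_per_s,
                 liposome = liposome, tracer = tracer, titration = titration,
                 genotype = genotype),
            class = "scenario_config")
}

# ensemble r for one substrate definition under the ideal stoichiometry model
substrate_truth <- function(sub, pH_cyt) {
  pep <- dipeptide(sub$residues, name = sub$name)
  ens <- predict_ensemble(sub$weights, pep, pH_cyt = pH_cyt, mode = "ideal")
  list(peptide = pep, r = if (ens$zero_current) 0 else ens$ratio,
       current_per_mole = ens$current_per_mole,
       protons_per_mole = ens$protons_per_mole)
}

#' Generate a combined TEVC / intracellular-pH experiment
#'
#' Applies each configured substrate sequentially to one synthetic cell:
#' 40 s baseline, 40 s application, 20 s washout per substrate. The current
#' channel carries Michaelis-Menten amplitudes with exponential onset, linear
#' drift and Gaussian noise. The proton influx is `h_per_mole * |I| / F`
#' (protons per mole of elementary charges from the ideal stoichiometry
#' model); intracellular pH integrates `-kappa` times that influx, and the
#' electrode channel renders the pH trajectory through the calibration slope.
#'
#' @param config A [scenario_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `trace` (an [assay_trace()] whose events follow the
#'   `<name>`/`<name>_baseline`/`<name>_acid` convention), and `truth`
#'   (per-substrate data frame with the generating amplitude, h per mole and
#'   r, plus `kappa`).
#' @export
generate_tevc_phin_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  dt <- 0.1
  n_sub <- length(config$substrates)
  t_base <- 40; t_app <- 40; t_wash <- 20
  t_block <- t_base + t_app + t_wash
  time <- seq(0, n_sub * t_block - dt, by = dt)
  current_clean <- numeric(length(time))
  flux_pmol_s <- numeric(length(time))
  events <- NULL
  truth <- NULL
  for (k in seq_len(n_sub)) {
    sub <- config$substrates[[k]]
    tr <- substrate_truth(sub, config$condition$pH_cyt)
    amp <- mm_velocity(sub$dose, sub$K_M, sub$v_max)
    t0 <- (k - 1) * t_block + t_base
    t1 <- t0 + t_app
    on_mask <- time >= t0 & time < t1
    wash_mask <- time >= t1 & time < t1 + t_wash
    shape <- numeric(length(time))
    shape[on_mask] <- 1 - exp(-(time[on_mask] - t0) / 2)
    shape[wash_mask] <- exp(-(time[wash_mask] - t1) / 2) *
      (1 - exp(-t_app / 2))
    i_sub <- amp * shape
    current_clean <- current_clean + i_sub
    # protons per second: (protons per mole substrate) * (mol substrate / s);
    # mol/s = |I| / (|current per mole| * F) for charged ensembles
    if (tr$current_per_mole != 0) {
      mol_per_s <- abs(i_sub) * 1e-9 /
        (abs(tr$current_per_mole) * physical_constants()$faraday) * 1e12
      flux_pmol_s <- flux_pmol_s + tr$protons_per_mole * mol_per_s
    }
    events <- rbind(events, data.frame(
      label = c(sub$name, paste0(sub$name, "_baseline"),
                paste0(sub$name, "_acid")),
      start_s = c(t1 - 20, t0 - 20, t0),
      end_s = c(t1, t0, t0 + 30)))
    truth <- rbind(truth, data.frame(
      substrate = sub$name, amplitude_nA = amp,
      protons_per_mole = tr$protons_per_mole,
      current_per_mole = tr$current_per_mole, r = tr$r,
      stringsAsFactors = FALSE))
  }
  ph <- config$condition$pH_cyt - config$kappa * cumsum(flux_pmol_s) * dt
  with_seed(seed, {
    current <- current_clean + config$drift_nA_per_s * time +
      stats::rnorm(length(time), 0, config$noise$current_nA)
    electrode <- config$electrode_slope_mV_per_pH *
      (config$condition$pH_cyt - ph) +
      stats::rnorm(length(time), 0, config$noise$electrode_mV)
  })
  trace <- assay_trace(time,
                       channels = list(current_nA = current,
                                       electrode_mV = electrode),
                       events = events,
                       metadata = list(holding_potential_V = -0.040,
                                       pH_out = config$condition$pH_lum,
                                       reference = config$reference,
                                       electrode_slope_mV_per_pH =
                                         config$electrode_slope_mV_per_pH))
  list(trace = trace, truth = truth, kappa = config$kappa)
}

#' Analyze a dual-recording trace into per-substrate ratio statistics
#'
#' Companion pipeline to [generate_tevc_phin_experiment()] (or any trace
#' following the same event schema): for every substrate event it measures the
#' evoked current against the paired baseline window and the acidification
#' slope over the `_acid` window, then forms within-cell normalized
#' acidification/current ratios against the reference substrate.
#'
#' @param trace An [assay_trace()] with `<name>`, `<name>_baseline` and
#'   `<name>_acid` events.
#' @param reference Reference substrate; defaults to the trace metadata.
#' @param electrode_slope_mV_per_pH Calibration slope; defaults to the trace
#'   metadata, else -59.
#' @param threshold_nA Reference-current validity threshold (default 100).
#' @return List with `cell_results` (currents and acidification rates) and
#'   `ratios` (the [acid_current_ratio()] table).
#' @export
analyze_tevc_experiment <- function(trace, reference = NULL,
                                    electrode_slope_mV_per_pH = NULL,
                                    threshold_nA = 100) {
  stopifnot(inherits(trace, "assay_trace"))
  if (is.null(reference)) reference <- trace$metadata$reference
  if (is.null(electrode_slope_mV_per_pH))
    electrode_slope_mV_per_pH <-
      trace$metadata$electrode_slope_mV_per_pH %||% -59
  labs <- trace$events$label
  subs <- labs[!grepl("_(baseline|acid)$", labs)]
  cell <- do.call(rbind, lapply(subs, function(s) {
    data.frame(
      substrate = s,
      current_nA = evoked_current(trace, s, paste0(s, "_baseline")),
      acid_rate = acidification_slope(trace, paste0(s, "_acid"),
                                      electrode_slope_mV_per_pH)$pH_per_s,
      stringsAsFactors = FALSE)
  }))
  list(cell_results = cell,
       ratios = acid_current_ratio(cell, reference, threshold_nA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a pyranine proteoliposome experiment
#'
#' One dual-wavelength fluorescence trace per condition: reconstituted
#' transporter with each configured substrate, plus an empty-liposome control.
#' Peptide is added at 30 s and valinomycin (clamping the membrane potential)
#' at 60 s; from then on, luminal pH falls only for substrates whose
#' transported species carries a titratable proton (ideal stoichiometry), and
#' the 415/460 excitation ratio declines with initial slope `v` saturating
#' with rate constant `response_lambda`. Empty liposomes stay flat.
#'
#' @param config A [scenario_config()]; `config$liposome` sets the kinetics.
#' @param seed Optional override of `config$seed`.
#' @param duration_s Trace length (default 600 s, 0.5 s sampling).
#' @return List of per-condition entries, each with `trace` (channels `F415`,
#'   `F460`; events `peptide`, `valinomycin`) and `truth` (the generating
#'   initial rate in F_norm/s); plus an `empty` control entry.
#' @export
generate_pyranine_experiment <- function(config, seed = config$seed,
                                         duration_s = 600) {
  stopifnot(inherits(config, "scenario_config"))
  lp <- config$liposome
  time <- seq(0, duration_s, by = 0.5)
  t_pep <- 30; t_val <- 60
  events <- data.frame(label = c("peptide", "valinomycin"),
                       start_s = c(t_pep, t_val),
                       end_s = c(t_pep + 1, t_val + 1))
  conditions <- lapply(config$substrates, function(sub) {
    tr <- substrate_truth(sub, 7.0)
    carries_proton <- tr$protons_per_mole > 0
    v <- if (carries_proton)
      mm_velocity(lp$dose, lp$K_M, lp$v_max_Fnorm_s) else 0
    list(name = sub$name, protein = "mmMFSD1", v = v)
  })
  conditions <- c(conditions,
                  list(list(name = config$substrates[[1]]$name,
                            protein = "empty", v = 0)))
  out <- lapply(seq_along(conditions), function(k) {
    cond <- conditions[[k]]
    g <- rep(1, length(time))
    post <- time >= t_val
    g[post] <- 1 + cond$v / lp$response_lambda *
      (1 - exp(-lp$response_lambda * (time[post] - t_val)))
    with_seed(seed * 131 + k, {
      f460 <- 40000 * (1 + stats::rnorm(length(time), 0,
                                        config$noise$fluor_frac))
      f415 <- 1.2 * g * 40000 * (1 + stats::rnorm(length(time), 0,
                                                  config$noise$fluor_frac))
    })
    trace <- assay_trace(time, channels = list(F415 = f415, F460 = f460),
                         events = events,
                         metadata = list(protein = cond$protein,
                                         substrate = cond$name,
                                         valinomycin_mV = lp$valinomycin_mV))
    list(trace = trace,
         truth = list(initial_rate_Fnorm_s = cond$v, protein = cond$protein,
                      substrate = cond$name, t_val = t_val))
  })
  names(out) <- vapply(conditions, function(cond)
    paste(cond$protein, cond$name, sep = ":"), character(1))
  out
}

#' Generate a stable-isotope tracer experiment
#'
#' Emulates heavy-dipeptide uptake followed by complete (or partial)
#' intracellular cleavage: per oocyte, the imported amount is
#' `rate * duration` with a per-oocyte biological coefficient of variation;
#' a `cleavage` fraction appears as the two product amino acids (equimolar)
#' and the remainder as intact dipeptide. Peak areas follow a linear response
#' with intercept (blank) and multiplicative noise; calibration standards are
#' emitted at known amounts spanning the sample range. A mock (zero-transport)
#' arm is included.
#'
#' @param config A [scenario_config()]; `config$tracer` sets rate, duration,
#'   cleavage and replication.
#' @param seed Optional override of `config$seed`.
#' @return List with `sample_areas`, `standards` (the inputs to
#'   [tracer_quantify()]), `duration_s` and `truth`.
#' @export
generate_tracer_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  tc <- config$tracer
  if (tc$cleavage < 0 || tc$cleavage > 1) stop("cleavage fraction in [0,1]")
  analytes <- c("Leu(d3)-Ala", "Leu(d3)", "Ala")
  slope <- c(120, 100, 90)     # counts per pmol, per analyte
  intercept <- c(500, 400, 600)
  names(slope) <- names(intercept) <- analytes
  total <- tc$rate_pmol_s * tc$duration_s
  std_amounts <- total * c(0.05, 0.15, 0.4, 0.8, 1.5, 2.5)
  with_seed(seed * 977 + 11, {
    standards <- do.call(rbind, lapply(analytes, function(a)
      data.frame(analyte = a, amount_pmol = std_amounts,
                 area = (intercept[[a]] + slope[[a]] * std_amounts) *
                   (1 + stats::rnorm(length(std_amounts), 0,
                                     config$noise$area_frac)),
                 stringsAsFactors = FALSE)))
    samples <- NULL
    for (arm in c("MFSD1-GLMP", "mock")) {
      for (i in seq_len(tc$n_oocytes)) {
        imported <- if (arm == "mock") 0 else
          total * (1 + stats::rnorm(1, 0, tc$bio_cv))
        amt <- c("Leu(d3)-Ala" = (1 - tc$cleavage) * imported,
                 "Leu(d3)" = tc$cleavage * imported,
                 "Ala" = tc$cleavage * imported)
        for (a in analytes) {
          samples <- rbind(samples, data.frame(
            analyte = a, sample_id = paste0(arm, "_", i), arm = arm,
            area = (intercept[[a]] + slope[[a]] * amt[[a]]) *
              (1 + stats::rnorm(1, 0, config$noise$area_frac)),
            stringsAsFactors = FALSE))
        }
      }
    }
  })
  list(sample_areas = samples, standards = standards,
       duration_s = tc$duration_s,
       truth = list(rate_pmol_s = tc$rate_pmol_s, cleavage = tc$cleavage,
                    product_ratio = if (tc$cleavage > 0) 1 else NA_real_))
}

#' Generate a melt-curve titration series
#'
#' Vectorizes [simulate_melt_curve()] over a ligand dilution series with
#' melting temperatures following the saturation model
#' `T_m(L) = T_m_apo + dT_m_max * L / (K_D + L)`.
#'
#' @param config A [scenario_config()]; `config$titration` sets the series.
#' @param seed Optional override of `config$seed`.
#' @param noise_sd Signal noise passed to [simulate_melt_curve()].
#' @return List with `curves` (list of `melt_curve`), `concentrations` and
#'   `truth`.
#' @export
generate_melt_titration <- function(config, seed = config$seed,
                                    noise_sd = 0.002) {
  stopifnot(inherits(config, "scenario_config"))
  ti <- config$titration
  concs <- ti$concentrations
  curves <- lapply(seq_along(concs), function(i) {
    L <- concs[i]
    tm <- ti$t_m_apo + ti$dT_m_max * L / (ti$K_D + L)
    simulate_melt_curve(tm, noise_sd = noise_sd, seed = seed * 1009 + i,
                        ligand = if (L == 0) "apo" else "ligand",
                        conc_M = L, replicate = i)
  })
  list(curves = curves, concentrations = concs,
       truth = list(K_D = ti$K_D, dT_m_max = ti$dT_m_max,
                    t_m_apo = ti$t_m_apo))
}

#' Generate a two-genotype dipeptide abundance table
#'
#' Log-normal dipeptide abundances for wild-type and knockout-like groups with
#' configured fold changes, an isotopically labelled internal-standard column
#' equal in expectation across genotypes, and a per-sample global scale factor
#' (extraction efficiency) applied to all analytes including the standard, so
#' internal-standard normalization removes it exactly.
#'
#' @param config A [scenario_config()]; `config$genotype` sets fold changes,
#'   group size and dispersions.
#' @param seed Optional override of `config$seed`.
#' @return List with `table` (long data frame: `genotype`, `sample_id`,
#'   `dipeptide`, `raw_abundance`, `internal_standard`, `normalized`) and
#'   `truth` (the fold changes).
#' @export
generate_genotype_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$genotype
  sdlog <- sqrt(log(1 + g$cv^2))
  sdlog_is <- sqrt(log(1 + g$is_cv^2))
  sdlog_sc <- sqrt(log(1 + g$scale_cv^2))
  with_seed(seed * 499 + 7, {
    rows <- NULL
    for (geno in c("WT", "KO")) {
      for (i in seq_len(g$n_per_group)) {
        scale_i <- stats::rlnorm(1, -sdlog_sc^2 / 2, sdlog_sc)
        is_i <- stats::rlnorm(1, -sdlog_is^2 / 2, sdlog_is) * scale_i
        for (dp in names(g$fold_changes)) {
          mu <- if (geno == "KO") g$fold_changes[[dp]] else 1
          raw <- stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog) * scale_i
          rows <- rbind(rows, data.frame(
            genotype = geno, sample_id = paste0(geno, "_", i),
            dipeptide = dp, raw_abundance = raw, internal_standard = is_i,
            stringsAsFactors = FALSE))
        }
      }
    }
  })
  rows$normalized <- rows$raw_abundance / rows$internal_standard
  list(table = rows, truth = list(fold_changes = g$fold_changes))
}
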