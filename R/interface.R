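# Versioned delimited-text I/O and the pipeline runner tying the stages
# together. All tables are comma-delimited with a header, numerics written at
# 15 significant digits (lossless for double precision round-trips).

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

write_table_versioned <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an assay trace in the long trace schema
#'
#' Three sidecar files share a prefix: `<prefix>_trace.csv` (columns
#' `time_s`, `channel`, `value`), `<prefix>_events.csv` (`label`, `start_s`,
#' `end_s`) and `<prefix>_meta.yaml` (metadata).
#'
#' @param trace An [assay_trace()].
#' @param prefix Path prefix (no extension).
#' @return `write_trace` returns the prefix invisibly; `read_trace` returns
#'   the reconstructed [assay_trace()].
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "assay_trace"))
  long <- do.call(rbind, lapply(names(trace$channels), function(ch)
    data.frame(time_s = trace$time, channel = ch,
               value = trace$channels[[ch]])))
  write_table_versioned(long, paste0(prefix, "_trace.csv"))
  if (!is.null(trace$events))
    write_table_versioned(trace$events, paste0(prefix, "_events.csv"))
  if (length(trace$metadata))
    yaml::write_yaml(trace$metadata, paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  long <- utils::read.csv(paste0(prefix, "_trace.csv"))
  if (!all(c("time_s", "channel", "value") %in% names(long)))
    stop("trace schema violation: need columns time_s, channel, value")
  chans <- split(long, long$channel)
  time <- chans[[1]]$time_s
  channels <- lapply(chans, function(d) {
    if (!isTRUE(all.equal(d$time_s, time)))
      stop("trace schema violation: channels disagree on the time grid")
    d$value
  })
  ev_path <- paste0(prefix, "_events.csv")
  events <- if (file.exists(ev_path)) utils::read.csv(ev_path) else NULL
  meta_path <- paste0(prefix, "_meta.yaml")
  metadata <- if (file.exists(meta_path)) yaml::read_yaml(meta_path)
    else list()
  assay_trace(time, channels, events, metadata)
}

#' Write / read a dose-response table
#'
#' Schema: columns `substrate`, `concentration_mM`, `response`, `unit`.
#'
#' @param data A [dose_response()] object.
#' @param path CSV path.
#' @return `read_dose_response` returns a [dose_response()].
#' @export
write_dose_response <- function(data, path) {
  stopifnot(inherits(data, "dose_response"))
  df <- data.frame(substrate = attr(data, "substrate"),
                   concentration_mM = data$concentration * 1e3,
                   response = data$response, unit = attr(data, "unit"))
  write_table_versioned(df, path)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path)
  need <- c("substrate", "concentration_mM", "response", "unit")
  if (!all(need %in% names(df)))
    stop("dose-response schema violation: need columns ",
         paste(need, collapse = ", "))
  dose_response(df$substrate[1], df$concentration_mM * 1e-3, df$response,
                unit = df$unit[1])
}

#' Write / read melt curves
#'
#' Schema: columns `temperature_C`, `ratio`, `ligand`, `conc_M`, `replicate`.
#'
#' @param curves List of `melt_curve` objects.
#' @param path CSV path.
#' @return `read_melt_curves` returns a list of `melt_curve` objects.
#' @export
write_melt_curves <- function(curves, path) {
  long <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperature_C, ratio = cv$ratio,
               ligand = attr(cv, "ligand"), conc_M = attr(cv, "conc_M"),
               replicate = attr(cv, "replicate"))))
  write_table_versioned(long, path)
  invisible(path)
}

#' @rdname write_melt_curves
#' @export
read_melt_curves <- function(path) {
  df <- utils::read.csv(path)
  need <- c("temperature_C", "ratio", "ligand", "conc_M", "replicate")
  if (!all(need %in% names(df)))
    stop("melt-curve schema violation: need columns ",
         paste(need, collapse = ", "))
  lapply(split(df, list(df$ligand, df$conc_M, df$replicate), drop = TRUE),
         function(d) structure(
           data.frame(temperature_C = d$temperature_C, ratio = d$ratio),
           class = c("melt_curve", "data.frame"),
           ligand = d$ligand[1], conc_M = d$conc_M[1],
           replicate = d$replicate[1]))
}

peptides_from_config <- function(cfg) {
  if (is.null(cfg$peptides)) stop("config is missing a 'peptides' section")
  out <- lapply(cfg$peptides, function(e)
    dipeptide(e$residues, name = e$name,
              pka_overrides = unlist(e$pka_overrides), labels = e$labels,
              include_termini = isTRUE(e$include_termini)))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Run a pipeline stage
#'
#' Thin, reproducible driver over the package's functions. Stage inputs come
#' from a YAML config; outputs are delimited tables under `out_dir`, and each
#' run writes a `manifest.json` (config digest, seed, package version, file
#' listing). All randomness is seeded from `seed` (default: the config's
#' `seed` entry).
#'
#' Commands: `speciate` (microstate tables for the configured peptides and pH
#' values), `stoichiometry` (per-species z/h/r tables), `thermo`
#' (equilibrium accumulation ratios), `simulate` (synthetic dual-recording
#' experiment), `analyze-tevc`, `analyze-pyranine`, `analyze-tracer`
#' (pipelines over trace/table inputs), `fit-mm`, `fit-kd` (model fits on
#' dose/titration tables), `report` (plain-text summary of a results
#' directory).
#'
#' @param command One of the stage names above.
#' @param config Path to the YAML config, or an already-parsed list.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding the config's.
#' @return Invisibly, the manifest list. Validation failures signal errors
#'   with distinct diagnostics (schema violation, missing channel/event,
#'   unknown command).
#' @export
run_pipeline <- function(command, config, out_dir, seed = NULL) {
  commands <- c("speciate", "stoichiometry", "thermo", "fit-mm", "fit-kd",
                "analyze-tevc", "analyze-pyranine", "analyze-tracer",
                "simulate", "report")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(seed)) seed <- config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table_versioned(df, path)
    files <<- c(files, path)
  }

  if (command == "speciate") {
    peps <- peptides_from_config(config)
    ph <- config$pH %||% 5.0
    rows <- NULL
    for (p in peps) for (x in ph) {
      d <- enumerate_species(p, x)
      rows <- rbind(rows, cbind(peptide = p$name, pH = x,
                                as.data.frame(d)[, c("label", "fraction",
                                                     "net_side_chain_charge",
                                                     "net_total_charge",
                                                     "dominant")]))
    }
    emit(rows, "species.csv")
  } else if (command == "stoichiometry") {
    peps <- peptides_from_config(config)
    rows <- NULL
    for (p in peps)
      rows <- rbind(rows, cbind(peptide = p$name, stoichiometry_table(
        p, pH_ref = config$pH_ref %||% 5.0, pH_cyt = config$pH_cyt %||% 7.2,
        mode = config$mode %||% "ideal")))
    emit(rows, "stoichiometry.csv")
  } else if (command == "thermo") {
    peps <- peptides_from_config(config)
    cond <- membrane_condition(config$condition$pH_lum %||% 5.0,
                               config$condition$pH_cyt %||% 7.2,
                               config$condition$delta_psi %||% 0,
                               config$condition$temperature %||% 293.15)
    rows <- NULL
    for (e in config$peptides) {
      p <- peps[[if (is.null(e$name))
        paste(AA3[substr(toupper(e$residues), 1, 1)],
              AA3[substr(toupper(e$residues), 2, 2)], sep = "-") else e$name]]
      ratio <- total_substrate_accumulation(p, e$transported_species, cond)
      rows <- rbind(rows, data.frame(peptide = p$name,
                                     accumulation_cyt_over_lum = ratio))
    }
    emit(rows, "accumulation.csv")
  } else if (command == "simulate") {
    sc <- scenario_config(seed = seed)
    exp <- generate_tevc_phin_experiment(sc)
    write_trace(exp$trace, file.path(out_dir, "tevc"))
    files <- c(files, file.path(out_dir, paste0("tevc", c("_trace.csv",
                                                          "_events.csv",
                                                          "_meta.yaml"))))
    emit(exp$truth, "tevc_truth.csv")
  } else if (command == "analyze-tevc") {
    prefix <- config$trace_prefix
    if (is.null(prefix)) stop("config is missing 'trace_prefix'")
    trace <- read_trace(prefix)
    if (is.null(trace$metadata$reference) && is.null(config$reference))
      stop("missing reference substrate (config 'reference' or trace metadata)")
    res <- analyze_tevc_experiment(trace,
                                   reference = config$reference %||% NULL)
    emit(res$cell_results, "tevc_cell_results.csv")
    emit(res$ratios, "tevc_ratios.csv")
  } else if (command == "analyze-pyranine") {
    prefix <- config$trace_prefix
    if (is.null(prefix)) stop("config is missing 'trace_prefix'")
    trace <- read_trace(prefix)
    fn <- pyranine_normalized_ratio(trace, config$peptide_event %||% "peptide")
    t_val <- event_window(trace, "valinomycin")[1]
    rate <- initial_rate(fn$time_s, fn$F_norm, c(t_val, t_val + 30))
    emit(fn, "pyranine_fnorm.csv")
    emit(data.frame(initial_rate_Fnorm_s = rate$slope, se = rate$se),
         "pyranine_rate.csv")
  } else if (command == "analyze-tracer") {
    for (f in c("sample_areas", "standards"))
      if (is.null(config[[f]])) stop("config is missing '", f, "'")
    res <- tracer_quantify(utils::read.csv(config$sample_areas),
                           utils::read.csv(config$standards),
                           duration_s = config$duration_s %||% 1200,
                           products = unlist(config$products))
    emit(res$amounts, "tracer_amounts.csv")
    if (!is.null(res$product_ratio))
      emit(data.frame(product_ratio = res$product_ratio),
           "tracer_product_ratio.csv")
  } else if (command == "fit-mm") {
    if (is.null(config$dose_response))
      stop("config is missing 'dose_response'")
    fit <- fit_michaelis_menten(read_dose_response(config$dose_response))
    emit(data.frame(substrate = fit$substrate, K_M = fit$K_M,
                    K_M_se = fit$K_M_se, v_max = fit$v_max,
                    v_max_se = fit$v_max_se, converged = fit$converged),
         "mm_fit.csv")
  } else if (command == "fit-kd") {
    if (is.null(config$titration)) stop("config is missing 'titration'")
    tt <- utils::read.csv(config$titration)
    if (!all(c("conc_M", "t_m") %in% names(tt)))
      stop("titration schema violation: need columns conc_M, t_m")
    fit <- fit_kd_from_shifts(tt$conc_M, tt$t_m)
    emit(data.frame(K_D = fit$K_D, K_D_se = fit$K_D_se,
                    dT_m_max = fit$dT_m_max, binder = fit$binder,
                    converged = fit$converged), "kd_fit.csv")
  } else if (command == "report") {
    found <- list.files(out_dir, pattern = "\\.csv$")
    lines <- c("uniportr run report", paste("generated files:", length(found)),
               paste(" -", found))
    writeLines(lines, file.path(out_dir, "report.txt"))
    files <- c(files, file.path(out_dir, "report.txt"))
  }

  manifest <- list(
    command = command,
    seed = seed,
    config_digest = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    package_version = as.character(utils::packageVersion("uniportr")),
    files = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
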