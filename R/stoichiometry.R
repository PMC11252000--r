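# Charge/proton stoichiometry of transported protonation species.
#
# A uniporter moves the dipeptide in a fixed protonation microstate; once the
# substrate faces the cytosol its titratable groups re-equilibrate at
# cytosolic pH, releasing (or consuming) protons. The statistic of interest is
# r = protons released per translocated elementary charge, the quantity read
# out by combined voltage-clamp / intracellular-pH recordings.

#' Protons released by a transported species at cytosolic pH
#'
#' In `"ideal"` mode a group that enters protonated releases its proton fully
#' when its pKa lies below the cytosolic pH (integer counts, the model behind
#' the printed predictions 0, 1, 2). In `"equilibrium"` mode each group
#' re-equilibrates by Henderson-Hasselbalch: a group entering protonated
#' releases `1 - fraction_protonated(pKa, pH_cyt)` protons, and a group
#' entering deprotonated consumes `fraction_protonated(pKa, pH_cyt)` protons
#' (negative release).
#'
#' @param species A [species_state()] of the peptide.
#' @param peptide The [dipeptide()] the species belongs to.
#' @param pH_cyt Cytosolic pH (default 7.2).
#' @param mode `"ideal"` (default) or `"equilibrium"`.
#' @return Protons released per transported molecule.
#' @examples
#' ka <- dipeptide("KA")
#' s <- species_state(enumerate_species(ka, 5.0), "Lys+-Ala")
#' protons_released(s, ka, 7.2)  # 0: the Lys side chain stays protonated
#' @export
protons_released <- function(species, peptide, pH_cyt = 7.2,
                             mode = c("ideal", "equilibrium")) {
  mode <- match.arg(mode)
  stopifnot(inherits(species, "species_state"), inherits(peptide, "dipeptide"))
  if (!is.finite(pH_cyt)) stop("pH_cyt must be finite")
  if (length(species$protonated) != length(peptide$groups))
    stop("species does not belong to the peptide's state space")
  h <- 0
  for (i in seq_along(peptide$groups)) {
    g <- peptide$groups[[i]]
    if (species$protonated[i]) {
      h <- h + if (mode == "ideal") as.numeric(g$pKa < pH_cyt)
        else 1 - fraction_protonated(g$pKa, pH_cyt)
    } else if (mode == "equilibrium") {
      h <- h - fraction_protonated(g$pKa, pH_cyt)
    }
  }
  h
}

#' Charge and proton stoichiometry of a transported species
#'
#' Computes the translocated charge z (net side-chain charge of the species),
#' the protons released h at cytosolic pH, and their ratio r = h/z. An
#' electroneutral species (z = 0) is a valid, flagged outcome for which r is
#' undefined.
#'
#' @inheritParams protons_released
#' @return An object of class `stoichiometry_result` with fields `species`
#'   (label), `charge_z`, `protons_released_h`, `protons_per_charge_r` (NA when
#'   electroneutral), `electroneutral`, `mode`.
#' @examples
#' he <- dipeptide("HE")
#' d <- enumerate_species(he, 5.0)
#' protons_per_charge(species_state(d, "His+-Glu0"), he)  # z=1, h=2, r=2
#' @export
protons_per_charge <- function(species, peptide, pH_cyt = 7.2,
                               mode = c("ideal", "equilibrium")) {
  mode <- match.arg(mode)
  h <- protons_released(species, peptide, pH_cyt, mode)
  z <- species$net_side_chain_charge
  structure(list(species = species$label, charge_z = z,
                 protons_released_h = h,
                 protons_per_charge_r = if (z != 0) h / z else NA_real_,
                 electroneutral = z == 0, mode = mode),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("%s (%s mode): z = %+d, h = %.4g", x$species, x$mode,
              x$charge_z, x$protons_released_h))
  if (x$electroneutral) cat(", electroneutral (r undefined)\n")
  else cat(sprintf(", r = %.4g protons per elementary charge\n",
                   x$protons_per_charge_r))
  invisible(x)
}

#' Acidification/current prediction for a transport-weighted ensemble
#'
#' Mixes species-level stoichiometries with transport weights: per mole of
#' transported substrate the current is the weighted mean charge and the
#' proton release the weighted mean h. Their ratio exceeds any single-species
#' r when electroneutral proton-carrying species contribute, as for mixed
#' uptake of cationic and zwitterionic His-Glu.
#'
#' @param weights Named numeric vector of transport weights (names are species
#'   labels of `peptide`'s state space at `pH_ref`); must sum to 1.
#' @param peptide A [dipeptide()].
#' @param pH_cyt Cytosolic pH.
#' @param mode `"ideal"` or `"equilibrium"`.
#' @param pH_ref pH at which the state space is enumerated for label lookup
#'   (default 5.0, the application medium).
#' @return An object of class `ensemble_prediction` with `current_per_mole`
#'   (elementary charges), `protons_per_mole`, `ratio` (NA and flagged when
#'   the ensemble carries no current), and the per-species table.
#' @export
predict_ensemble <- function(weights, peptide, pH_cyt = 7.2,
                             mode = c("ideal", "equilibrium"), pH_ref = 5.0) {
  mode <- match.arg(mode)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  dist <- enumerate_species(peptide, pH_ref)
  res <- lapply(names(weights), function(lb)
    protons_per_charge(species_state(dist, lb), peptide, pH_cyt, mode))
  z <- vapply(res, `[[`, numeric(1), "charge_z")
  h <- vapply(res, `[[`, numeric(1), "protons_released_h")
  current <- sum(weights * z)
  protons <- sum(weights * h)
  structure(list(
    weights = weights,
    current_per_mole = current,
    protons_per_mole = protons,
    ratio = if (current != 0) protons / current else NA_real_,
    zero_current = current == 0,
    species = data.frame(species = names(weights), weight = unname(weights),
                         charge_z = z, protons_released_h = h,
                         stringsAsFactors = FALSE),
    mode = mode), class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("Ensemble prediction (%s mode)\n", x$mode))
  print(x$species, row.names = FALSE)
  cat(sprintf("current %.4g e/mol, protons %.4g /mol", x$current_per_mole,
              x$protons_per_mole))
  if (x$zero_current) cat(", ratio undefined (zero current)\n")
  else cat(sprintf(", acidification/current ratio %.4g\n", x$ratio))
  invisible(x)
}

#' Tabulate stoichiometry over a peptide's state space
#'
#' One row per microstate with its fraction at the reference pH, charge,
#' proton release and r; the export consumed by the synthetic generators and
#' the assay pipelines.
#'
#' @param peptide A [dipeptide()].
#' @param pH_ref pH of the application/luminal medium.
#' @param pH_cyt Cytosolic pH.
#' @param mode `"ideal"` or `"equilibrium"`.
#' @return Data frame with columns `species`, `fraction_at_ref`, `charge_z`,
#'   `protons_released_h`, `protons_per_charge_r`, `electroneutral`, `mode`.
#' @export
stoichiometry_table <- function(peptide, pH_ref = 5.0, pH_cyt = 7.2,
                                mode = c("ideal", "equilibrium")) {
  mode <- match.arg(mode)
  dist <- enumerate_species(peptide, pH_ref)
  rows <- lapply(dist$label, function(lb) {
    r <- protons_per_charge(species_state(dist, lb), peptide, pH_cyt, mode)
    data.frame(species = lb,
               fraction_at_ref = dist$fraction[dist$label == lb],
               charge_z = r$charge_z, protons_released_h = r$protons_released_h,
               protons_per_charge_r = r$protons_per_charge_r,
               electroneutral = r$electroneutral, mode = mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
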