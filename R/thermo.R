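# Uniporter thermodynamics: Nernst-type equilibrium accumulation and driving
# forces under membrane potential and bilateral pH.
#
# Sign convention (used everywhere in this package): delta_psi = psi_cyt -
# psi_lum. A "positive-inside" organelle (lumen positive, psi_lum > psi_cyt)
# therefore has delta_psi < 0, and exported cations move down this gradient.

#' Physical constants
#'
#' Centralised values of the Faraday constant and the molar gas constant; no
#' other magic numbers appear in the thermodynamic code.
#'
#' @return Named list with `faraday` (96485.332 C/mol) and `gas_constant`
#'   (8.314462 J/mol/K).
#' @export
physical_constants <- function() {
  list(faraday = 96485.332, gas_constant = 8.314462)
}

#' Membrane condition
#'
#' @param pH_lum Luminal (or extracellular, in the whole-cell configuration)
#'   pH; 0--14.
#' @param pH_cyt Cytosolic pH; 0--14.
#' @param delta_psi Membrane potential in volts, defined as `psi_cyt -
#'   psi_lum`.
#' @param temperature Absolute temperature in kelvin; defaults to 293.15 K
#'   (room-temperature recordings).
#' @return An object of class `membrane_condition`.
#' @export
membrane_condition <- function(pH_lum = 5.0, pH_cyt = 7.2, delta_psi = 0,
                               temperature = 293.15) {
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  for (p in c(pH_lum, pH_cyt))
    if (!is.finite(p) || p < 0 || p > 14) stop("pH values must lie in 0-14")
  if (!is.finite(delta_psi)) stop("delta_psi must be finite")
  structure(list(pH_lum = pH_lum, pH_cyt = pH_cyt, delta_psi = delta_psi,
                 temperature = temperature), class = "membrane_condition")
}

#' Nernst equilibrium accumulation ratio
#'
#' Equilibrium cytosol/lumen concentration ratio of a species of charge z under
#' a membrane potential, `exp(-z F delta_psi / (R T))`. Equals 1 at
#' `delta_psi = 0` or `z = 0`; for a cation and a lumen-positive potential
#' (`delta_psi < 0` in this package's convention) the ratio exceeds 1,
#' i.e. the potential drives cation export.
#'
#' @param z Species charge in elementary charges.
#' @param condition A [membrane_condition()].
#' @return Equilibrium concentration ratio (cytosol/lumen).
#' @examples
#' nernst_accumulation(1, membrane_condition(delta_psi = -0.040))  # ~4.88
#' @export
nernst_accumulation <- function(z, condition) {
  stopifnot(inherits(condition, "membrane_condition"))
  if (!all(is.finite(z))) stop("z must be finite")
  k <- physical_constants()
  exp(-z * k$faraday * condition$delta_psi /
        (k$gas_constant * condition$temperature))
}

#' Electrochemical driving force on a transported species
#'
#' Free energy of moving one mole of the species from lumen to cytosol,
#' `dG = RT ln(c_cyt / c_lum) + z F delta_psi`. Negative dG means net export
#' (lumen to cytosol) is spontaneous.
#'
#' @param concentration_cyt,concentration_lum Species concentrations
#'   (activities) in mol/L; must be positive.
#' @param z Species charge in elementary charges.
#' @param condition A [membrane_condition()].
#' @return List with `delta_g` (J/mol) and `direction` (`"export"`,
#'   `"import"` or `"equilibrium"`).
#' @export
species_driving_force <- function(concentration_cyt, concentration_lum, z,
                                  condition) {
  stopifnot(inherits(condition, "membrane_condition"))
  if (concentration_cyt <= 0 || concentration_lum <= 0)
    stop("concentrations must be positive")
  k <- physical_constants()
  rt <- k$gas_constant * condition$temperature
  dg <- rt * log(concentration_cyt / concentration_lum) +
    z * k$faraday * condition$delta_psi
  direction <- if (abs(dg) < 1e-9) "equilibrium" else
    if (dg < 0) "export" else "import"
  list(delta_g = dg, direction = direction)
}

#' Total-substrate equilibrium accumulation with speciation
#'
#' The transporter only moves the listed protonation species; on each side of
#' the membrane the total substrate re-speciates at the local pH. At the
#' zero-net-flux steady state (equal per-species transporter rate constants,
#' each species tending to its own Nernst ratio rho_i) the total
#' cytosol/lumen ratio is
#' `sum_i rho_i f_i(pH_lum) / sum_i f_i(pH_cyt)` over the transported species
#' i, where f_i are the microstate fractions. With a single transported
#' species this is the exact per-species equilibrium
#' `rho f(pH_lum) / f(pH_cyt)`; it reduces to [nernst_accumulation()] when
#' the peptide has a single state. A proton carried by the substrate thus
#' couples accumulation to the pH gradient even though the transporter itself
#' moves no protons.
#'
#' @param peptide A [dipeptide()].
#' @param transported_species Character vector of microstate labels (as in
#'   [enumerate_species()]) that the transporter accepts; non-empty.
#' @param condition A [membrane_condition()].
#' @return Total-concentration equilibrium ratio (cytosol/lumen).
#' @examples
#' ha <- dipeptide("HA")
#' cond <- membrane_condition(pH_lum = 5.0, pH_cyt = 7.2, delta_psi = 0)
#' total_substrate_accumulation(ha, "His+-Ala", cond)  # ~15.3
#' @export
total_substrate_accumulation <- function(peptide, transported_species,
                                         condition) {
  stopifnot(inherits(peptide, "dipeptide"),
            inherits(condition, "membrane_condition"))
  if (length(transported_species) == 0)
    stop("transported_species must be a non-empty set of microstate labels")
  d_lum <- enumerate_species(peptide, condition$pH_lum)
  d_cyt <- enumerate_species(peptide, condition$pH_cyt)
  miss <- setdiff(transported_species, d_lum$label)
  if (length(miss))
    stop("unknown species label(s): ", paste(miss, collapse = ", "))
  i_lum <- match(transported_species, d_lum$label)
  i_cyt <- match(transported_species, d_cyt$label)
  rho <- nernst_accumulation(d_lum$net_total_charge[i_lum], condition)
  sum(rho * d_lum$fraction[i_lum]) / sum(d_cyt$fraction[i_cyt])
}
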