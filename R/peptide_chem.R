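# Dipeptide definitions, protonation microstates and monoisotopic masses.

#' Default side-chain and terminal pKa registry
#'
#' Side-chain pKa values for His (6.0), Glu (4.1) and Lys (10.5) follow the
#' values used throughout the transport experiments; the remaining side chains
#' and the termini come from a standard biochemical table and can be overridden
#' per peptide. Only side chains with a titratable group in the 0--14 range are
#' listed.
#'
#' @return Named list with elements `side_chain` (named numeric vector of pKa
#'   by one-letter residue code, with an attribute `kind` giving "acid" or
#'   "base" per entry), `n_terminus` and `c_terminus` (single pKa values).
#' @export
default_pka_registry <- function() {
  side <- c(D = 3.65, E = 4.1, H = 6.0, C = 8.18, Y = 10.46, K = 10.5, R = 12.48)
  kind <- c(D = "acid", E = "acid", H = "base", C = "acid", Y = "acid",
            K = "base", R = "base")
  attr(side, "kind") <- kind
  list(side_chain = side, n_terminus = 8.0, c_terminus = 3.1)
}

# Monoisotopic residue masses (Da) of the 20 canonical amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276

AA3 <- c(G = "Gly", A = "Ala", S = "Ser", P = "Pro", V = "Val", T = "Thr",
         C = "Cys", L = "Leu", I = "Ile", N = "Asn", D = "Asp", Q = "Gln",
         K = "Lys", E = "Glu", M = "Met", H = "His", F = "Phe", R = "Arg",
         Y = "Tyr", W = "Trp")

#' Construct an ionizable group
#'
#' An acid contributes charge 0 when protonated and -1 when deprotonated; a
#' base contributes +1 when protonated and 0 when deprotonated.
#'
#' @param label Short text label (e.g. `"His"`).
#' @param pKa Acid dissociation constant on the pH scale; must be finite and
#'   within 0--14.
#' @param kind `"acid"` or `"base"`.
#' @param location One of `"side_chain_1"`, `"side_chain_2"`, `"n_terminus"`,
#'   `"c_terminus"`.
#' @return An object of class `ionizable_group`.
#' @export
ionizable_group <- function(label, pKa, kind = c("acid", "base"),
                            location = c("side_chain_1", "side_chain_2",
                                         "n_terminus", "c_terminus")) {
  kind <- match.arg(kind)
  location <- match.arg(location)
  if (!is.finite(pKa) || pKa < 0 || pKa > 14)
    stop("pKa must be finite and within 0-14, got ", pKa)
  structure(list(label = label, pKa = pKa, kind = kind, location = location),
            class = "ionizable_group")
}

#' Charge contribution of an ionizable group
#'
#' @param group An [ionizable_group()].
#' @param protonated Logical; is the group protonated?
#' @return Integer charge in elementary charges.
#' @export
group_charge <- function(group, protonated) {
  if (group$kind == "base") as.integer(protonated) else as.integer(protonated) - 1L
}

#' Define a dipeptide with its titratable groups
#'
#' Builds a two-residue peptide specification from one-letter codes. Side-chain
#' groups are taken from the pKa registry; the zwitterionic termini are net
#' neutral across the pH range of interest and are excluded by default, but can
#' be switched on for full titration curves.
#'
#' @param residues Two-character string (e.g. `"HE"`) or character vector of
#'   two one-letter codes.
#' @param name Display name; defaults to e.g. `"His-Glu"`.
#' @param pka_overrides Named numeric vector overriding registry pKa values by
#'   location (`side_chain_1`, `side_chain_2`, `n_terminus`, `c_terminus`).
#' @param labels Optional list of heavy-isotope labels, each a list/vector with
#'   elements `residue` (1 or 2) and `shift` (mass shift in Da).
#' @param include_termini Logical; model the alpha-amino and alpha-carboxyl
#'   groups as titratable sites (default `FALSE`).
#' @param registry pKa registry, see [default_pka_registry()].
#' @return An object of class `dipeptide` with fields `residue_1`, `residue_2`,
#'   `groups`, `labels`, `name`.
#' @examples
#' his_glu <- dipeptide("HE")
#' length(his_glu$groups)  # two side-chain groups
#' @export
dipeptide <- function(residues, name = NULL, pka_overrides = NULL,
                      labels = NULL, include_termini = FALSE,
                      registry = default_pka_registry()) {
  if (length(residues) == 1L) residues <- strsplit(residues, "")[[1]]
  if (length(residues) != 2L)
    stop("a dipeptide has exactly two residues, got ", length(residues))
  residues <- toupper(residues)
  unknown <- setdiff(residues, names(RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))

  side <- registry$side_chain
  kinds <- attr(side, "kind")
  groups <- list()
  for (i in 1:2) {
    res <- residues[i]
    loc <- paste0("side_chain_", i)
    if (!res %in% names(side)) next  # no titratable side chain
    pka <- if (!is.null(pka_overrides) && loc %in% names(pka_overrides))
      pka_overrides[[loc]] else unname(side[res])
    groups[[length(groups) + 1L]] <-
      ionizable_group(AA3[[res]], pka, kinds[[res]], loc)
  }
  if (include_termini) {
    npka <- if (!is.null(pka_overrides) && "n_terminus" %in% names(pka_overrides))
      pka_overrides[["n_terminus"]] else registry$n_terminus
    cpka <- if (!is.null(pka_overrides) && "c_terminus" %in% names(pka_overrides))
      pka_overrides[["c_terminus"]] else registry$c_terminus
    groups[[length(groups) + 1L]] <-
      ionizable_group("N-term", npka, "base", "n_terminus")
    groups[[length(groups) + 1L]] <-
      ionizable_group("C-term", cpka, "acid", "c_terminus")
  }
  locs <- vapply(groups, `[[`, "", "location")
  if (anyDuplicated(locs)) stop("at most one ionizable group per location")

  if (!is.null(labels)) {
    for (lb in labels) {
      if (!all(c("residue", "shift") %in% names(lb)))
        stop("each label needs 'residue' and 'shift'")
      if (!is.finite(lb$shift)) stop("label mass shift must be finite")
      if (!lb$residue %in% 1:2) stop("label residue index must be 1 or 2")
    }
  }
  if (is.null(name))
    name <- paste(AA3[residues[1]], AA3[residues[2]], sep = "-")
  structure(list(residue_1 = residues[1], residue_2 = residues[2],
                 groups = groups, labels = labels, name = name),
            class = "dipeptide")
}

#' @export
print.dipeptide <- function(x, ...) {
  cat("Dipeptide:", x$name, sprintf("(%s-%s)\n", x$residue_1, x$residue_2))
  for (g in x$groups)
    cat(sprintf("  %-10s %-12s pKa %.2f (%s)\n", g$label, g$location, g$pKa,
                g$kind))
  if (!is.null(x$labels))
    for (lb in x$labels)
      cat(sprintf("  isotope label on residue %d: +%.4f Da\n",
                  lb$residue, lb$shift))
  invisible(x)
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Fraction of a single titratable group in the protonated state at a given pH.
#'
#' @param pKa Acid dissociation constant (pH units).
#' @param pH Solution pH.
#' @return `1 / (1 + 10^(pH - pKa))`, a fraction in \[0, 1\]; strictly
#'   decreasing in pH.
#' @examples
#' fraction_protonated(6.0, 6.0)   # 0.5 at the midpoint
#' fraction_protonated(10.5, 7.2)  # Lys side chain stays protonated
#' @export
fraction_protonated <- function(pKa, pH) {
  if (!all(is.finite(pKa)) || !all(is.finite(pH)))
    stop("pKa and pH must be finite")
  1 / (1 + 10^(pH - pKa))
}

species_label <- function(peptide, protonated) {
  locs <- vapply(peptide$groups, `[[`, "", "location")
  charge_sym <- function(loc) {
    idx <- which(locs == loc)
    if (!length(idx)) return(NA_character_)
    z <- group_charge(peptide$groups[[idx]], protonated[idx])
    c(`-1` = "-", `0` = "0", `1` = "+")[as.character(z)]
  }
  sym <- function(i) {
    res <- AA3[[if (i == 1) peptide$residue_1 else peptide$residue_2]]
    s <- charge_sym(paste0("side_chain_", i))
    if (is.na(s)) res else paste0(res, s)
  }
  lab <- paste0(sym(1), "-", sym(2))
  # termini, when modelled, are appended so every microstate label is unique
  nt <- charge_sym("n_terminus")
  ct <- charge_sym("c_terminus")
  if (!is.na(nt) || !is.na(ct))
    lab <- paste0(lab, "/N", if (is.na(nt)) "." else nt,
                  "C", if (is.na(ct)) "." else ct)
  lab
}

#' Enumerate protonation microstates of a dipeptide
#'
#' All 2^n assignments of protonated/deprotonated over the peptide's n
#' ionizable groups, with fractions given by the product of independent
#' per-group Henderson-Hasselbalch probabilities (no site-site coupling).
#'
#' @param peptide A [dipeptide()].
#' @param pH Solution pH.
#' @return An object of class `species_distribution`: a data frame with one
#'   row per microstate and columns `label`, `fraction`,
#'   `net_side_chain_charge`, `net_total_charge`, `dominant`, plus a logical
#'   column per group giving its protonation state. Fractions sum to 1.
#' @examples
#' enumerate_species(dipeptide("HE"), pH = 5.0)  # the four-state His-Glu model
#' @export
enumerate_species <- function(peptide, pH) {
  stopifnot(inherits(peptide, "dipeptide"))
  if (!is.finite(pH)) stop("pH must be finite")
  n <- length(peptide$groups)
  if (n == 0L) {
    out <- data.frame(label = paste0(AA3[[peptide$residue_1]], "-",
                                     AA3[[peptide$residue_2]]),
                      fraction = 1, net_side_chain_charge = 0L,
                      net_total_charge = 0L, dominant = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    fp <- vapply(peptide$groups, function(g) fraction_protonated(g$pKa, pH),
                 numeric(1))
    locs <- vapply(peptide$groups, `[[`, "", "location")
    frac <- apply(grid, 1, function(state)
      prod(ifelse(as.logical(state), fp, 1 - fp)))
    zs <- apply(grid, 1, function(state) {
      z <- mapply(function(g, p) group_charge(g, p), peptide$groups,
                  as.logical(state))
      c(side = sum(z[grepl("^side_chain", locs)]), total = sum(z))
    })
    labels <- apply(grid, 1, function(state)
      species_label(peptide, as.logical(state)))
    out <- data.frame(label = labels, fraction = frac,
                      net_side_chain_charge = as.integer(zs["side", ]),
                      net_total_charge = as.integer(zs["total", ]),
                      dominant = frac == max(frac), stringsAsFactors = FALSE)
    names(grid) <- vapply(peptide$groups, `[[`, "", "label")
    names(grid) <- make.unique(names(grid))
    out <- cbind(out, grid)
    out <- out[order(-out$fraction), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("species_distribution", "data.frame"),
            pH = pH, peptide = peptide$name)
}

#' @export
print.species_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Protonation microstates of %s at pH %.2f\n",
              attr(x, "peptide"), attr(x, "pH")))
  df <- as.data.frame(x)[, c("label", "fraction", "net_side_chain_charge",
                             "net_total_charge", "dominant")]
  df$fraction <- signif(df$fraction, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract one microstate from a species distribution
#'
#' @param dist A [enumerate_species()] result.
#' @param label Microstate label, e.g. `"His+-Glu0"`.
#' @return A one-row `species_state` list with the protonation assignment and
#'   net charges.
#' @export
species_state <- function(dist, label) {
  i <- match(label, dist$label)
  if (is.na(i)) stop("no microstate labelled '", label, "'; available: ",
                     paste(dist$label, collapse = ", "))
  ngrp <- ncol(dist) - 5L
  prot <- if (ngrp > 0) as.logical(dist[i, 5L + seq_len(ngrp)]) else logical(0)
  structure(list(label = label, protonated = prot,
                 net_side_chain_charge = dist$net_side_chain_charge[i],
                 net_total_charge = dist$net_total_charge[i]),
            class = "species_state")
}

#' Mean net charge of a dipeptide at one or more pH values
#'
#' @param peptide A [dipeptide()].
#' @param pH Numeric vector of pH values.
#' @return Numeric vector of ensemble-average net charges (all modelled
#'   groups); monotone non-increasing in pH.
#' @export
mean_net_charge <- function(peptide, pH) {
  vapply(pH, function(p) {
    d <- enumerate_species(peptide, p)
    sum(d$fraction * d$net_total_charge)
  }, numeric(1))
}

#' Monoisotopic m/z of a dipeptide
#'
#' Sum of monoisotopic residue masses plus one water, plus the adduct proton,
#' plus any heavy-isotope label shifts.
#'
#' @param peptide A [dipeptide()].
#' @param adduct Only `"M+H"` is supported.
#' @return m/z in Da, reported to 4 decimals.
#' @examples
#' monoisotopic_mz(dipeptide("RP"))  # 272.1717
#' @export
monoisotopic_mz <- function(peptide, adduct = "M+H") {
  stopifnot(inherits(peptide, "dipeptide"))
  adduct <- match.arg(adduct, "M+H")
  m <- RESIDUE_MASS[[peptide$residue_1]] + RESIDUE_MASS[[peptide$residue_2]] +
    MASS_WATER + MASS_PROTON
  if (!is.null(peptide$labels))
    m <- m + sum(vapply(peptide$labels, `[[`, numeric(1), "shift"))
  round(m, 4)
}

#' Read a peptide registry from a YAML config
#'
#' Each entry maps a key to `residues`, optional `name`, `pka_overrides`,
#' `labels` (list of `{residue, shift}`) and `include_termini`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [dipeptide()] objects.
#' @export
read_peptide_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(e) {
    dipeptide(e$residues, name = e$name,
              pka_overrides = unlist(e$pka_overrides),
              labels = e$labels,
              include_termini = isTRUE(e$include_termini))
  })
  names(out) <- names(cfg)
  out
}

#' Export an m/z table for SIM/MRM list building
#'
#' @param peptides Named list of [dipeptide()] objects.
#' @param path Optional output path; when given, a two-column tab-delimited
#'   table (name, mz) is written.
#' @return Data frame with columns `name` and `mz`.
#' @export
mz_table <- function(peptides, path = NULL) {
  df <- data.frame(
    name = vapply(peptides, `[[`, "", "name"),
    mz = vapply(peptides, monoisotopic_mz, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
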