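# Independent oracles used to cross-check the package's closed-form code
# paths. These deliberately use different algorithms (explicit microstate
# Boltzmann sums, iterative relaxation) from the implementation.

# Boltzmann enumeration over explicit microstates: each protonated group
# carries an unnormalized statistical weight 10^(pKa - pH); fractions come
# from the partition sum over all 2^n assignments.
boltzmann_fractions <- function(peptide, pH) {
  n <- length(peptide$groups)
  if (n == 0) return(stats::setNames(1, "state"))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  w <- apply(grid, 1, function(state) {
    lw <- 0
    for (j in seq_len(n))
      if (state[j]) lw <- lw + (peptide$groups[[j]]$pKa - pH) * log(10)
    exp(lw)
  })
  labs <- apply(grid, 1, function(state)
    paste(ifelse(as.logical(state), "H", "-"), collapse = ""))
  stats::setNames(w / sum(w), labs)
}

# protonation pattern key for a row of an enumerate_species() table
state_key <- function(dist, row) {
  ngrp <- ncol(dist) - 5L
  if (ngrp == 0) return("state")
  paste(ifelse(as.logical(dist[row, 5L + seq_len(ngrp)]), "H", "-"),
        collapse = "")
}

# Fixed-point relaxation oracle for total substrate accumulation: evolve the
# cytosolic total under per-species fluxes J_i = rho_i * c_lum_i - c_cyt_i
# until the net flux vanishes.
relaxation_accumulation <- function(peptide, transported, condition,
                                    tol = 1e-12, max_iter = 20000) {
  d_lum <- enumerate_species(peptide, condition$pH_lum)
  d_cyt <- enumerate_species(peptide, condition$pH_cyt)
  i_lum <- match(transported, d_lum$label)
  i_cyt <- match(transported, d_cyt$label)
  rho <- nernst_accumulation(d_lum$net_total_charge[i_lum], condition)
  c_lum <- 1
  c_cyt <- 1
  eta <- 0.2 / sum(d_cyt$fraction[i_cyt])
  f_cyt_total <- sum(d_cyt$fraction[i_cyt])
  for (k in seq_len(max_iter)) {
    flux <- sum(rho * d_lum$fraction[i_lum] * c_lum -
                  d_cyt$fraction[i_cyt] * c_cyt)
    if (abs(flux) < tol * f_cyt_total) break
    c_cyt <- c_cyt + eta * flux
  }
  c_cyt / c_lum
}

# random dipeptide with 0-4 ionizable groups at random pKa values
random_peptide <- function() {
  res <- sample(c("H", "E", "K", "A", "G", "S", "D", "R"), 2, replace = TRUE)
  overrides <- list()
  if (stats::runif(1) < 0.5)
    overrides$side_chain_1 <- stats::runif(1, 2, 12)
  if (stats::runif(1) < 0.5)
    overrides$side_chain_2 <- stats::runif(1, 2, 12)
  dipeptide(paste(res, collapse = ""),
            pka_overrides = unlist(overrides),
            include_termini = stats::runif(1) < 0.5)
}
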