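# Unit conversions are centralized here: coordinates are Angstrom throughout,
# concentrations mol/L, Kirkwood-Buff integrals L/mol, energies kJ/mol.

# 1 mol/L expressed in molecules/A^3 (Avogadro / 1e27)
.MOLAR_TO_PER_A3 <- 6.02214076e-4

# Boltzmann constant, kJ/(mol K)
.KB_KJ <- 8.31446261815324e-3

#' Convert a number density in molecules/Angstrom^3 to mol/L
#'
#' @param rho number density, molecules/A^3
#' @return concentration in mol/L
#' @export
per_a3_to_molar <- function(rho) rho / .MOLAR_TO_PER_A3

#' Convert a concentration in mol/L to molecules/Angstrom^3
#'
#' @param c concentration, mol/L
#' @return number density in molecules/A^3
#' @export
molar_to_per_a3 <- function(c) c * .MOLAR_TO_PER_A3

# A^3 per molecule -> L/mol (same constant: volumes transform like 1/density)
.a3_to_l_mol <- function(v) v * .MOLAR_TO_PER_A3

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package route
# through this so that seeded runs are bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}
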