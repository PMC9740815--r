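# Unit system: kcal/mol, Angstrom, ps, amu, elementary charge.
# 1 amu*A^2/ps^2 (the native MD energy unit, "mdu") = 10 J/mol = 1/418.4 kcal/mol.
.ht <- new.env(parent = emptyenv())
.ht$kB_eV <- 8.6173e-5                    # Boltzmann constant, eV/K
.ht$eV_per_kcal <- 0.0433641              # 1 kcal/mol in eV
.ht$kB_kcal <- .ht$kB_eV / .ht$eV_per_kcal
.ht$mdu_per_kcal <- 418.4
.ht$kB_mdu <- .ht$kB_kcal * .ht$mdu_per_kcal
.ht$coulomb_k <- 332.0637                 # kcal*A/(mol*e^2)
.ht$hbar_SI <- 1.0545718e-34              # J*s
.ht$kB_SI <- .ht$kB_eV * 1.602176634e-19  # J/K
.ht$masses <- c(Ca = 40.078, P = 30.973762, O = 15.999, H = 1.008)

#' Physical constants used by the package
#'
#' Returns the constants the package computes with: the Boltzmann constant
#' in eV/K and kcal/(mol K), the Coulomb prefactor in kcal A/(mol e^2), the
#' kcal/mol to eV conversion, and the reduced Planck constant in SI units.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' ht_constants()$kB_eV
ht_constants <- function() {
  list(kB_eV = .ht$kB_eV, kB_kcal = .ht$kB_kcal, kB_SI = .ht$kB_SI,
       eV_per_kcal = .ht$eV_per_kcal, coulomb_k = .ht$coulomb_k,
       hbar_SI = .ht$hbar_SI, mdu_per_kcal = .ht$mdu_per_kcal)
}

.species_element <- function(species) {
  # species labels are element symbols possibly followed by a role suffix,
  # e.g. "Op" (phosphate O), "Oh"/"Ho" (hydroxyl), "Ow"/"Hw" (water)
  el <- sub("^(Ca|Cl|Na|[A-Z])[a-z0-9]*$", "\\1", species)
  el
}

.species_mass <- function(species, strict = TRUE) {
  el <- .species_element(species)
  m <- .ht$masses[el]
  if (anyNA(m)) {
    if (strict)
      # unknown labels (toy species etc.) must carry explicit masses elsewhere
      stop("no tabulated mass for species: ",
           paste(unique(species[is.na(m)]), collapse = ", "))
    m[is.na(m)] <- 1
  }
  unname(m)
}
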