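# Particle classes: the database key is (species, energy), energies in MeV
# for electrons and protons and MeV per nucleon for heavier ions.

#' Species registry with database energy ranges
#'
#' A data frame with one row per supported particle species: electrons,
#' protons and fully stripped ions from He to Ar. `E_min`/`E_max` delimit the
#' energy range covered by a database for that species (MeV for electrons and
#' protons, MeV per nucleon for ions); `A` is the mass number of the stable
#' isotope used for the database entry.
#'
#' @return A data frame with columns `species`, `Z`, `A`, `E_min`, `E_max`,
#'   `unit`.
#' @export
#' @examples
#' id_species_table()
id_species_table <- function() {
  data.frame(
    species = c("e-", "p", "He", "Li", "Be", "B", "C", "N", "O", "F",
                "Ne", "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
    Z = c(-1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L,
          10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L),
    A = c(0L, 1L, 4L, 7L, 9L, 11L, 12L, 14L, 16L, 19L,
          20L, 23L, 24L, 27L, 28L, 31L, 32L, 35L, 40L),
    E_min = c(0.001, 0.1, rep(0.5, 17)),
    E_max = c(1, 230, 100, 255, 305, 355, 425, 470, 510, 530,
              600, 615, 675, 700, 760, 780, 840, 900, 950),
    unit = c("MeV", "MeV", rep("MeV/u", 17)),
    stringsAsFactors = FALSE
  )
}

.species_row <- function(species) {
  tab <- id_species_table()
  i <- match(species, tab$species)
  if (is.na(i)) {
    stop("unknown species '", species, "'; supported: ",
         paste(tab$species, collapse = ", "), call. = FALSE)
  }
  tab[i, , drop = FALSE]
}

#' Database energy range for a species
#'
#' @param species Species symbol, e.g. `"p"`, `"C"`, `"e-"`.
#' @return Named numeric vector `c(E_min, E_max)` in the species' energy unit.
#' @export
id_energy_range <- function(species) {
  row <- .species_row(species)
  c(E_min = row$E_min, E_max = row$E_max)
}

#' Construct a particle class (database key)
#'
#' A particle class is a (species, energy) pair. The energy must lie within
#' the database range for the species; energies are interpreted in MeV for
#' electrons and protons and MeV per nucleon for heavier ions.
#'
#' @param species Species symbol.
#' @param energy Kinetic energy in the species' energy unit.
#' @param check_range If `TRUE` (default), error when `energy` lies outside
#'   the database range for the species.
#' @return An object of class `particle_class` with fields `species`, `Z`,
#'   `A`, `energy`, `unit`.
#' @export
particle_class <- function(species, energy, check_range = TRUE) {
  row <- .species_row(species)
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy) ||
      energy <= 0) {
    stop("'energy' must be a single positive number", call. = FALSE)
  }
  if (check_range && (energy < row$E_min || energy > row$E_max)) {
    stop(sprintf("energy %g %s outside database range [%g, %g] for %s",
                 energy, row$unit, row$E_min, row$E_max, species),
         call. = FALSE)
  }
  structure(list(species = row$species, Z = row$Z, A = row$A,
                 energy = energy, unit = row$unit),
            class = "particle_class")
}

#' @export
print.particle_class <- function(x, ...) {
  cat(sprintf("<particle class> %s (Z=%d, A=%d) at %g %s\n",
              x$species, x$Z, x$A, x$energy, x$unit))
  invisible(x)
}

#' Map an isotope to its database particle class
#'
#' The database stores one entry per atomic number (the stable ion). Any
#' isotope (Z, A) is mapped to the stable-ion class for that Z; because the
#' energy key for ions is per nucleon, no energy rescaling is applied.
#'
#' @param Z Atomic number, 1 to 18.
#' @param A Mass number of the queried isotope (kept for bookkeeping only).
#' @return A list with `species`, `Z`, `A_database` (stable mass number) and
#'   `A_query`.
#' @export
#' @examples
#' resolve_isotope(6, 13)  # 13C -> carbon database class
#' resolve_isotope(8, 15)  # 15O -> oxygen database class
resolve_isotope <- function(Z, A) {
  if (!is.numeric(Z) || length(Z) != 1L || Z < 1 || Z > 18 || Z != round(Z)) {
    stop("Z must be an integer between 1 and 18", call. = FALSE)
  }
  tab <- id_species_table()
  row <- tab[tab$Z == Z, , drop = FALSE]
  list(species = row$species, Z = row$Z, A_database = row$A,
       A_query = as.integer(A))
}

#' Relative difference between isotope and stable-ion ionization parameters
#'
#' Signed percentage difference `100 * (F_iso - F_stable) / F_stable`.
#'
#' @param F_iso Ionization parameter of the isotope (nm^-1).
#' @param F_stable Ionization parameter of the stable ion (nm^-1); must be
#'   positive.
#' @return Signed percentage (vectorized).
#' @export
isotope_relative_difference <- function(F_iso, F_stable) {
  if (any(!is.finite(F_stable)) || any(F_stable <= 0)) {
    stop("F_stable must be positive; relative difference undefined",
         call. = FALSE)
  }
  100 * (F_iso - F_stable) / F_stable
}
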