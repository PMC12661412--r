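# Plain-text interchange: lattice and event tables.

#' Write a lattice to CSV with a YAML geometry sidecar
#'
#' The CSV holds the cylinder centres (`cx_nm,cy_nm,cz_nm`); the sidecar
#' `<path>.yaml` records the geometry parameters so the lattice can be
#' rebuilt exactly.
#'
#' @param lattice A `cylinder_lattice`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "cylinder_lattice"))
  tab <- data.frame(cx_nm = lattice$centers[, 1],
                    cy_nm = lattice$centers[, 2],
                    cz_nm = lattice$centers[, 3])
  utils::write.csv(tab, path, row.names = FALSE)
  side <- list(cube_side_nm = lattice$cube_side,
               cyl_diameter_nm = lattice$cyl_diameter,
               cyl_length_nm = lattice$cyl_length,
               row_shift_nm = lattice$row_shift,
               n_cylinders = lattice$n,
               fill_fraction = lattice$fill_fraction)
  writeLines(yaml::as.yaml(side), paste0(path, ".yaml"))
  invisible(path)
}

#' Read an ionization-event table
#'
#' Expects the columns `history_id,kind,species,energy_MeV,x_nm,y_nm,z_nm`.
#'
#' @param path CSV path.
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("history_id", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(ev))) {
    stop("event file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ev
}

#' Write an ionization-event table
#'
#' @param events Event data frame as produced by [generate_histories()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
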