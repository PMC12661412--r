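# Ionization-detail database: F_k operator, adaptive energy binning,
# interpolation with boundary clamping, and plain-text persistence.

#' Cumulative cluster frequency F_k
#'
#' `F_k = sum_{nu >= k} f(nu)`: the number of clusters of k or more
#' ionizations per unit primary track length (nm^-1). F_k is non-increasing
#' in k by construction.
#'
#' @param tally A `cluster_tally`, or a data frame / list with fields `nu`
#'   and `f`, or a bare numeric `f` vector (then `nu = seq_along(f)`).
#' @param k Cluster-size threshold(s), `k >= 1` (vectorized).
#' @return Numeric vector of F_k values (nm^-1), one per element of `k`.
#' @export
#' @examples
#' compute_Fk(list(nu = 1:6, f = c(5, 3, 2, 1, 0.5, 0.1)), k = 1:3)
compute_Fk <- function(tally, k) {
  if (is.numeric(tally)) tally <- list(nu = seq_along(tally), f = tally)
  stopifnot(all(k >= 1))
  vapply(k, function(kk) sum(tally$f[tally$nu >= kk]), numeric(1))
}

#' Build an adaptively spaced energy grid
#'
#' Marching up from `E_min`, the next grid energy is the largest energy at
#' which the relative change of the ionization parameters F_5 to F_7 (by
#' default) with respect to the previous grid point stays within
#' `max_rel_change` (default 5%); `E_max` is always appended. The boundary
#' energy is root-found by bisection to relative tolerance `rel_tol` and then
#' nudged, if needed, so the criterion holds with `<=` at every accepted
#' pair. The criterion is applied as the maximum over the checked k.
#'
#' @param ip_curve Function of a scalar energy returning the F_k vector
#'   (indexable at the positions in `k_check`); must be positive and
#'   continuous on the range.
#' @param E_min,E_max Energy range endpoints (MeV or MeV/u).
#' @param max_rel_change Maximum allowed adjacent relative change.
#' @param k_check Which F_k enter the criterion (default 5:7).
#' @param rel_tol Relative root-finding tolerance.
#' @return An object of class `energy_grid` with fields `energies`,
#'   `max_rel_change`, `k_check`.
#' @export
build_adaptive_grid <- function(ip_curve, E_min, E_max,
                                max_rel_change = 0.05, k_check = 5:7,
                                rel_tol = 1e-6) {
  stopifnot(is.function(ip_curve), E_min > 0, E_max > E_min,
            max_rel_change > 0)
  fk <- function(E) {
    v <- ip_curve(E)[k_check]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("ip_curve must be positive and finite over the range",
           call. = FALSE)
    }
    v
  }
  energies <- E_min
  E_prev <- E_min
  F_prev <- fk(E_min)
  relchange <- function(E) max(abs(fk(E) - F_prev) / F_prev)
  repeat {
    if (relchange(E_max) <= max_rel_change) {
      energies <- c(energies, E_max)
      break
    }
    ur <- stats::uniroot(function(E) relchange(E) - max_rel_change,
                         lower = E_prev, upper = E_max,
                         tol = rel_tol * E_prev)
    E_next <- ur$root
    # keep the accepted pair strictly within the criterion
    iter <- 0L
    while (relchange(E_next) > max_rel_change && iter < 60L) {
      E_next <- E_prev + (E_next - E_prev) * (1 - 2 * rel_tol)
      iter <- iter + 1L
    }
    energies <- c(energies, E_next)
    E_prev <- E_next
    F_prev <- fk(E_next)
  }
  structure(list(energies = energies, max_rel_change = max_rel_change,
                 k_check = k_check),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy grid> %d energies in [%g, %g], criterion %.3g on F%s\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$max_rel_change,
              paste(range(x$k_check), collapse = "-F")))
  invisible(x)
}

#' Build an ionization-detail database from parametric curves
#'
#' For each species, an adaptive grid is built over the species' database
#' energy range and the curve is evaluated at the grid energies. The stored
#' record holds the frequency distribution `f(nu) = F_nu - F_{nu+1}`
#' (with `F_{nu_max + 1} = 0`), from which F_k is recovered exactly.
#'
#' @param curves Named list of curve functions (one per species symbol); each
#'   takes a scalar energy and returns the vector `F_1 .. F_{nu_max}`
#'   (nm^-1). See [synthetic_ip_curves()].
#' @param nu_max Largest cluster size carried by the database.
#' @param max_rel_change,k_check,rel_tol Passed to [build_adaptive_grid()].
#' @return An object of class `id_database`.
#' @export
build_id_database <- function(curves, nu_max = 10, max_rel_change = 0.05,
                              k_check = 5:7, rel_tol = 1e-6) {
  stopifnot(is.list(curves), !is.null(names(curves)))
  tab <- id_species_table()
  records <- lapply(names(curves), function(sp) {
    row <- .species_row(sp)
    grid <- build_adaptive_grid(curves[[sp]], row$E_min, row$E_max,
                                max_rel_change, k_check, rel_tol)
    Fk <- t(vapply(grid$energies,
                   function(E) curves[[sp]](E)[seq_len(nu_max)],
                   numeric(nu_max)))
    if (any(diff(t(Fk)) > 1e-12 * t(Fk)[-nu_max, , drop = FALSE])) {
      stop("curve for ", sp, " is not non-increasing in k", call. = FALSE)
    }
    f <- Fk - cbind(Fk[, -1, drop = FALSE], 0)
    f[f < 0] <- 0
    list(species = row$species, Z = row$Z, A = row$A, unit = row$unit,
         energies = grid$energies, f = f,
         se = matrix(0, nrow(f), ncol(f)))
  })
  names(records) <- names(curves)
  structure(list(records = records, nu_max = nu_max,
                 meta = list(max_rel_change = max_rel_change,
                             k_check = k_check, version = "1")),
            class = "id_database")
}

#' @export
print.id_database <- function(x, ...) {
  cat(sprintf("<id database> %d species, nu_max %d\n",
              length(x$records), x$nu_max))
  for (r in x$records) {
    cat(sprintf("  %-3s %3d energies in [%g, %g] %s\n", r$species,
                length(r$energies), min(r$energies), max(r$energies), r$unit))
  }
  invisible(x)
}

.db_record <- function(db, species) {
  rec <- db$records[[species]]
  if (is.null(rec)) {
    stop("species '", species, "' not in database", call. = FALSE)
  }
  rec
}

.record_Fk <- function(rec) {
  nu_max <- ncol(rec$f)
  t(apply(rec$f, 1, function(fv) rev(cumsum(rev(fv)))))
}

#' Interpolate ionization parameters from the database
#'
#' Linear interpolation in energy between the bracketing grid records;
#' queries below the lowest or above the highest database energy return the
#' boundary record unchanged (clamping). Queries at a grid node return the
#' stored values exactly.
#'
#' @param db An `id_database`.
#' @param species Species symbol, or `NULL` when `Z` is given (isotopes are
#'   mapped to the stable-ion class via [resolve_isotope()]).
#' @param energy Energies to query (MeV or MeV/u per the species' unit;
#'   vectorized).
#' @param k Which F_k to return (default all up to `nu_max`).
#' @param Z,A Optional isotope specification instead of `species`.
#' @return Matrix `length(energy) x length(k)` of F_k values (nm^-1), with
#'   column names `F<k>`.
#' @export
interpolate_ip <- function(db, species = NULL, energy, k = NULL,
                           Z = NULL, A = NULL) {
  stopifnot(inherits(db, "id_database"))
  if (is.null(species)) {
    if (is.null(Z)) stop("give either 'species' or 'Z'", call. = FALSE)
    species <- resolve_isotope(Z, if (is.null(A)) Z else A)$species
  }
  rec <- .db_record(db, species)
  if (is.null(k)) k <- seq_len(db$nu_max)
  Fk <- .record_Fk(rec)[, k, drop = FALSE]
  E <- pmin(pmax(energy, min(rec$energies)), max(rec$energies))
  if (length(rec$energies) == 1L) {
    out <- Fk[rep(1L, length(E)), , drop = FALSE]
  } else {
    i <- findInterval(E, rec$energies, rightmost.closed = TRUE,
                      all.inside = TRUE)
    w <- (E - rec$energies[i]) / (rec$energies[i + 1L] - rec$energies[i])
    out <- (1 - w) * Fk[i, , drop = FALSE] + w * Fk[i + 1L, , drop = FALSE]
  }
  colnames(out) <- paste0("F", k)
  rownames(out) <- NULL
  out
}

#' Write / read an ionization-detail database as plain text
#'
#' The on-disk format is a UTF-8 CSV with columns
#' `species,Z,A,energy,unit,nu,f_per_nm,se_per_nm`, preceded by a `#`-prefixed
#' YAML header recording `version`, `nu_max` and any metadata supplied at
#' build time. Values round-trip at full double precision.
#'
#' @param db An `id_database`.
#' @param path File path.
#' @return `write_db` returns `path` invisibly; `read_db` returns the parsed
#'   `id_database` (after validating monotone energy grids and non-negative
#'   frequencies, naming the offending row on failure).
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "id_database"))
  hdr <- yaml::as.yaml(c(list(version = db$meta$version %||% "1",
                              nu_max = db$nu_max),
                         db$meta[setdiff(names(db$meta), "version")]))
  rows <- lapply(db$records, function(rec) {
    nE <- length(rec$energies)
    nu_max <- ncol(rec$f)
    data.frame(species = rec$species, Z = rec$Z, A = rec$A,
               energy = rep(rec$energies, each = nu_max),
               unit = rec$unit,
               nu = rep(seq_len(nu_max), nE),
               f_per_nm = as.vector(t(rec$f)),
               se_per_nm = as.vector(t(rec$se)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(hdr, "\n", fixed = TRUE)[[1]]), con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  lines <- do.call(paste, c(lapply(tab, function(col) {
    if (is.numeric(col)) format(col, digits = 17, scientific = TRUE,
                                trim = TRUE) else as.character(col)
  }), sep = ","))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_db
#' @export
read_db <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[is_hdr]),
                                collapse = "\n"))
  tab <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"),
                         stringsAsFactors = FALSE)
  need <- c("species", "Z", "A", "energy", "unit", "nu", "f_per_nm",
            "se_per_nm")
  if (!all(need %in% names(tab))) {
    stop("malformed database file: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tab$f_per_nm) | tab$f_per_nm < 0)
  if (length(bad)) {
    stop("negative or non-finite f_per_nm at data row ", bad[1],
         call. = FALSE)
  }
  nu_max <- meta$nu_max %||% max(tab$nu)
  records <- lapply(split(tab, tab$species), function(sp) {
    sp <- sp[order(match(sp$energy, unique(sp$energy)), sp$nu), ]
    energies <- unique(sp$energy)
    if (any(diff(energies) <= 0)) {
      off <- which(diff(energies) <= 0)[1]
      stop("non-monotone energy grid for species ", sp$species[1],
           " near energy ", energies[off + 1], call. = FALSE)
    }
    f <- matrix(sp$f_per_nm, nrow = length(energies), ncol = nu_max,
                byrow = TRUE)
    se <- matrix(sp$se_per_nm, nrow = length(energies), ncol = nu_max,
                 byrow = TRUE)
    list(species = sp$species[1], Z = sp$Z[1], A = sp$A[1], unit = sp$unit[1],
         energies = energies, f = f, se = se)
  })
  structure(list(records = records, nu_max = nu_max,
                 meta = meta),
            class = "id_database")
}
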