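# Nanoscale sampling-volume lattice and ionization-cluster scoring.
#
# The simulation volume is a cube of water (side ~100 nm) densely packed with
# Z-aligned cylinders of 2.3 nm diameter x 3.4 nm length, each resembling a
# 10-base-pair DNA segment. Ionization events from a primary history are
# grouped by containing cylinder; the event count per occupied cylinder is
# the ionization cluster size nu.

#' Build the cylindrical sampling-volume lattice
#'
#' Deterministic maximal packing of Z-aligned cylinders inside a cube centred
#' at the origin. Layers are stacked along Z at pitch `cyl_length`; within a
#' layer, rows run along X and are stacked along Y at pitch `cyl_diameter`;
#' every other row is offset by `row_shift` along X. The number of elements
#' per axis is `floor(cube_side / pitch)`, and the first cylinder centre sits
#' at `(-cube_side/2 + r, -cube_side/2 + r, -cube_side/2 + L/2)`.
#'
#' When the axial margin `cube_side - n*cyl_diameter` is smaller than
#' `row_shift`, cylinders in shifted rows protrude by the (sub-pitch)
#' difference beyond one cube face; the packing tolerates this so that the
#' column count is identical in shifted and unshifted rows.
#'
#' @param cube_side Side of the cubic simulation volume (nm).
#' @param cyl_diameter Cylinder diameter (nm).
#' @param cyl_length Cylinder length (nm).
#' @param row_shift Offset of alternate rows along X (nm); defaults to the
#'   cylinder radius.
#' @return An object of class `cylinder_lattice` with fields `centers`
#'   (n x 3 matrix, nm), `n`, `fill_fraction`, per-axis counts `nx`, `ny`,
#'   `nz`, the geometry parameters, and an internal spatial index.
#' @export
#' @examples
#' lat <- build_cylinder_lattice(20, 2.3, 3.4, 1.15)
#' lat$n
build_cylinder_lattice <- function(cube_side, cyl_diameter, cyl_length,
                                   row_shift = cyl_diameter / 2) {
  if (!all(is.finite(c(cube_side, cyl_diameter, cyl_length, row_shift))) ||
      cube_side <= 0 || cyl_diameter <= 0 || cyl_length <= 0 || row_shift < 0) {
    stop("invalid geometry: all dimensions must be positive", call. = FALSE)
  }
  # floor() with a small slack so that e.g. cube_side == cyl_length gives 1
  nxy <- as.integer(floor(cube_side / cyl_diameter + 1e-9))
  nz <- as.integer(floor(cube_side / cyl_length + 1e-9))
  h <- cube_side / 2
  r <- cyl_diameter / 2

  if (nxy < 1L || nz < 1L) {
    centers <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    ijk <- matrix(integer(0), ncol = 3)
  } else {
    xs <- -h + (seq_len(nxy) - 0.5) * cyl_diameter
    ys <- -h + (seq_len(nxy) - 0.5) * cyl_diameter
    zs <- -h + (seq_len(nz) - 0.5) * cyl_length
    i <- rep.int(seq_len(nxy), times = nxy * nz)
    j <- rep.int(rep(seq_len(nxy), each = nxy), times = nz)
    k <- rep(seq_len(nz), each = nxy * nxy)
    cx <- xs[i] + ifelse(j %% 2L == 0L, row_shift, 0)
    centers <- cbind(x = cx, y = ys[j], z = zs[k])
    ijk <- cbind(i, j, k)
  }
  n <- nrow(centers)
  lat <- structure(list(
    cube_side = cube_side, cyl_diameter = cyl_diameter,
    cyl_length = cyl_length, row_shift = row_shift,
    nx = nxy, ny = nxy, nz = nz,
    centers = centers, ijk = ijk, n = n,
    fill_fraction = n * pi * r^2 * cyl_length / cube_side^3
  ), class = "cylinder_lattice")
  lat$pos_index <- .lattice_pos_index(lat)
  lat
}

# integer array mapping (i, j, k) -> row in centers (0 = absent)
.lattice_pos_index <- function(lat) {
  if (lat$n == 0L) return(integer(0))
  idx <- integer(lat$nx * lat$ny * lat$nz)
  key <- (lat$ijk[, 3L] - 1L) * lat$nx * lat$ny +
    (lat$ijk[, 2L] - 1L) * lat$nx + lat$ijk[, 1L]
  idx[key] <- seq_len(lat$n)
  idx
}

#' @export
print.cylinder_lattice <- function(x, ...) {
  cat(sprintf(paste0(
    "<cylinder lattice> %d cylinders (%d x %d x %d grid)\n",
    "  cube %g nm, cylinders %g nm diameter x %g nm, row shift %g nm\n",
    "  fill fraction %.1f%%\n"),
    x$n, x$nx, x$ny, x$nz, x$cube_side, x$cyl_diameter, x$cyl_length,
    x$row_shift, 100 * x$fill_fraction))
  invisible(x)
}

#' Spherical source volume
#'
#' The vacuum sphere at the centre of the simulation volume inside which
#' primary particles start, by default 34 nm across (ten times the largest
#' sampling-volume dimension).
#'
#' @param diameter Sphere diameter (nm).
#' @param center Sphere centre (nm), default the origin.
#' @return An object of class `source_sphere`.
#' @export
source_sphere <- function(diameter = 34, center = c(0, 0, 0)) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter >= 0,
            is.numeric(center), length(center) == 3L)
  structure(list(center = as.numeric(center), diameter = diameter,
                 radius = diameter / 2), class = "source_sphere")
}

#' Remove sampling volumes overlapping the source sphere
#'
#' Drops every cylinder whose solid intersects the sphere (distance from the
#' sphere centre to the cylinder solid strictly less than the sphere radius).
#' The lattice index is rebuilt so spatial queries remain exact.
#'
#' @param lattice A `cylinder_lattice`.
#' @param source A `source_sphere`.
#' @return The reduced lattice; the number of removed cylinders is stored in
#'   the `n_removed` field.
#' @export
exclude_source_overlap <- function(lattice, source = source_sphere()) {
  stopifnot(inherits(lattice, "cylinder_lattice"),
            inherits(source, "source_sphere"))
  if (source$radius == 0 || lattice$n == 0L) {
    lattice$n_removed <- 0L
    return(lattice)
  }
  r <- lattice$cyl_diameter / 2
  L2 <- lattice$cyl_length / 2
  dx <- source$center[1] - lattice$centers[, 1]
  dy <- source$center[2] - lattice$centers[, 2]
  dz <- source$center[3] - lattice$centers[, 3]
  rad_gap <- pmax(sqrt(dx^2 + dy^2) - r, 0)
  ax_gap <- pmax(abs(dz) - L2, 0)
  dist <- sqrt(rad_gap^2 + ax_gap^2)
  keep <- dist >= source$radius
  removed <- sum(!keep)
  lattice$centers <- lattice$centers[keep, , drop = FALSE]
  lattice$ijk <- lattice$ijk[keep, , drop = FALSE]
  lattice$n <- nrow(lattice$centers)
  lattice$n_removed <- removed
  lattice$pos_index <- .lattice_pos_index(lattice)
  lattice
}

#' Locate ionization events in the lattice
#'
#' Returns, for each point, the row index of the cylinder containing it, or
#' `NA` if the point falls in an inter-cylinder gap. Containment is closed:
#' radial distance from the axis `<= r` and axial offset `<= L/2`. The lookup
#' uses the regular-grid structure of the packing (constant time per point)
#' and is exact: it returns the lowest-index containing cylinder, the same
#' convention as a linear scan over the centre list.
#'
#' @param points Numeric vector of length 3 or an n x 3 matrix (nm).
#' @param lattice A `cylinder_lattice`.
#' @return Integer vector of cylinder indices (`NA` where outside all
#'   cylinders).
#' @export
locate_event <- function(points, lattice) {
  stopifnot(inherits(lattice, "cylinder_lattice"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  n <- nrow(p)
  if (lattice$n == 0L) return(rep(NA_integer_, n))
  h <- lattice$cube_side / 2
  d <- lattice$cyl_diameter
  L <- lattice$cyl_length
  r2 <- (d / 2)^2
  L2 <- L / 2
  nx <- lattice$nx; ny <- lattice$ny; nz <- lattice$nz
  cen <- lattice$centers
  pos <- lattice$pos_index

  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  j0 <- floor((y + h) / d) + 1
  k0 <- floor((z + h) / L) + 1
  best <- rep(NA_integer_, n)
  # candidate cells: the cell the point maps to and its immediate neighbours
  # (row shift and closed boundaries make +-1 sufficient)
  for (dk in -1:1) {
    kc <- k0 + dk
    ok_k <- kc >= 1 & kc <= nz
    for (dj in -1:1) {
      jc <- j0 + dj
      ok_j <- ok_k & jc >= 1 & jc <= ny
      if (!any(ok_j)) next
      shift <- ifelse(jc %% 2 == 0, lattice$row_shift, 0)
      i_base <- floor((x - shift + h) / d) + 1
      for (di in -1:1) {
        ic <- i_base + di
        ok <- ok_j & ic >= 1 & ic <= nx
        if (!any(ok)) next
        key <- (kc[ok] - 1) * nx * ny + (jc[ok] - 1) * nx + ic[ok]
        row <- pos[key]
        hit <- row > 0L
        if (!any(hit)) next
        sel <- which(ok)[hit]
        row <- row[hit]
        inside <- (x[sel] - cen[row, 1])^2 + (y[sel] - cen[row, 2])^2 <= r2 &
          abs(z[sel] - cen[row, 3]) <= L2
        sel <- sel[inside]; row <- row[inside]
        if (!length(sel)) next
        take <- is.na(best[sel]) | row < best[sel]
        best[sel[take]] <- row[take]
      }
    }
  }
  best
}

#' Energy-loss budget for primary-particle termination
#'
#' A primary is tracked only until its cumulative energy loss in the
#' simulation volume exceeds a small fraction (default 1%) of the gap between
#' its initial energy and the next lower database energy, keeping each
#' database entry nearly monoenergetic and preventing double counting of
#' clusters between adjacent entries.
#'
#' @param E0 Initial primary energy (MeV or MeV/u).
#' @param E_next_lower Next lower database energy (same unit).
#' @param fraction Allowed fraction of the gap, default 0.01.
#' @return Maximum allowed cumulative energy loss (same unit as `E0`).
#' @export
#' @examples
#' primary_termination_budget(15, 10)  # 0.05
primary_termination_budget <- function(E0, E_next_lower, fraction = 0.01) {
  if (any(E_next_lower < 0) || any(E0 <= E_next_lower)) {
    stop("require E0 > E_next_lower >= 0", call. = FALSE)
  }
  if (any(fraction <= 0) || any(fraction >= 1)) {
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  }
  fraction * (E0 - E_next_lower)
}

#' Transport rules for secondary particles and boundaries
#'
#' Production cutoffs mirror the defaults of condensed-history transport in
#' water: 0.054 MeV for electrons and 1.56 MeV for protons. Secondaries below
#' the cutoff are transported and scored at nanoscale (they would be deposited
#' locally at macroscale); secondaries at or above it carry their own database
#' class and are terminated here so their clusters are not counted twice.
#'
#' @param electron_cutoff Electron/positron production threshold (MeV).
#' @param proton_cutoff Proton production threshold (MeV).
#' @param primary_loss_fraction Fraction for
#'   [primary_termination_budget()].
#' @param pbc_enabled Whether periodic boundary re-entry of secondaries is
#'   active (off by default).
#' @return An object of class `transport_rules`.
#' @export
transport_rules <- function(electron_cutoff = 0.054, proton_cutoff = 1.56,
                            primary_loss_fraction = 0.01,
                            pbc_enabled = FALSE) {
  stopifnot(electron_cutoff > 0, proton_cutoff > 0,
            primary_loss_fraction > 0, primary_loss_fraction < 1)
  structure(list(electron_cutoff = electron_cutoff,
                 proton_cutoff = proton_cutoff,
                 primary_loss_fraction = primary_loss_fraction,
                 pbc_enabled = isTRUE(pbc_enabled)),
            class = "transport_rules")
}

#' Decide whether a secondary particle is transported or terminated
#'
#' @param species Species symbol (`"e-"`, `"e+"`, `"p"`, or a heavier ion
#'   symbol from [id_species_table()]).
#' @param energy Kinetic energy at creation (MeV; MeV/u for ions).
#' @param rules A [transport_rules()] object.
#' @return `"transport"` (score its ionizations here) or `"terminate"` (its
#'   ionizations belong to its own database class).
#' @export
secondary_transport_decision <- function(species, energy,
                                         rules = transport_rules()) {
  stopifnot(is.numeric(energy), length(energy) == 1L, energy >= 0)
  if (species %in% c("e-", "e+")) {
    if (energy < rules$electron_cutoff) "transport" else "terminate"
  } else if (species == "p") {
    if (energy < rules$proton_cutoff) "transport" else "terminate"
  } else if (species %in% id_species_table()$species) {
    "terminate"  # heavier than protons: always terminated at nanoscale
  } else {
    stop("unknown species '", species, "'", call. = FALSE)
  }
}

#' Periodic boundary re-entry
#'
#' When enabled, a secondary particle reaching the cube boundary is
#' reintroduced at the diametrically opposite boundary point (the exit point
#' reflected through the cube centre) with unchanged direction and energy.
#'
#' @param exit_point Point on the cube boundary (nm).
#' @param direction Unit direction vector.
#' @param energy Kinetic energy (MeV).
#' @param cube_side Cube side (nm).
#' @param tol Boundary tolerance (nm).
#' @return List with `position`, `direction`, `energy`.
#' @export
apply_pbc <- function(exit_point, direction, energy, cube_side, tol = 1e-9) {
  h <- cube_side / 2
  on_face <- any(abs(abs(exit_point) - h) <= tol)
  if (!on_face || max(abs(exit_point)) > h + tol) {
    stop("exit point is not on the cube boundary", call. = FALSE)
  }
  list(position = -exit_point, direction = direction, energy = energy)
}

#' Score one primary history into ionization clusters
#'
#' Groups the history's ionization events (primary plus transported
#' descendants) by containing cylinder; the cluster size nu is the event
#' count per occupied cylinder. Empty cylinders contribute nothing.
#'
#' @param events Data frame (or matrix) with columns/cols `x_nm`, `y_nm`,
#'   `z_nm` (a bare matrix is taken as x, y, z).
#' @param lattice A `cylinder_lattice`.
#' @param track_length Primary track length inside the simulation volume,
#'   excluding the source sphere (nm).
#' @return Integer vector of cluster sizes (one entry per occupied cylinder),
#'   with the track length attached as attribute `track_length`.
#' @export
score_history <- function(events, lattice, track_length) {
  pts <- .event_coords(events)
  if (nrow(pts) > 0 && track_length <= 0) {
    stop("zero track length with nonzero events", call. = FALSE)
  }
  idx <- locate_event(pts, lattice)
  sizes <- as.integer(table(idx[!is.na(idx)]))
  attr(sizes, "track_length") <- track_length
  sizes
}

.event_coords <- function(events) {
  if (is.matrix(events)) {
    m <- events[, 1:3, drop = FALSE]
  } else if (is.data.frame(events)) {
    cols <- if (all(c("x_nm", "y_nm", "z_nm") %in% names(events)))
      c("x_nm", "y_nm", "z_nm") else c("x", "y", "z")
    m <- as.matrix(events[, cols])
  } else {
    m <- matrix(as.numeric(events), ncol = 3)
  }
  storage.mode(m) <- "double"
  m
}

#' Score many histories at once
#'
#' Batched equivalent of [score_history()]: one spatial query over all events
#' followed by a split on history id.
#'
#' @param events Data frame with columns `history_id`, `x_nm`, `y_nm`, `z_nm`.
#' @param lattice A `cylinder_lattice`.
#' @param track_lengths Numeric vector of per-history track lengths (nm), one
#'   entry per history in `history_ids` order. Histories without events
#'   contribute their track length to the normalization with no clusters.
#' @param history_ids Ids covered by `track_lengths`; defaults to
#'   `seq_along(track_lengths)`, matching [generate_histories()] output.
#' @return List of histories, each `list(clusters =, track_length =)`,
#'   suitable for [accumulate_ficsd()].
#' @export
score_events <- function(events, lattice, track_lengths,
                         history_ids = seq_along(track_lengths)) {
  stopifnot(length(track_lengths) == length(history_ids))
  if (!all(events$history_id %in% history_ids)) {
    stop("events reference history ids without a track length", call. = FALSE)
  }
  idx <- locate_event(.event_coords(events), lattice)
  keep <- !is.na(idx)
  per_hist <- split(idx[keep],
                    factor(events$history_id[keep], levels = history_ids))
  lapply(seq_along(history_ids), function(i) {
    list(clusters = as.integer(table(per_hist[[i]])),
         track_length = as.numeric(track_lengths[[i]]))
  })
}

#' Accumulate histories into a frequency ionization cluster size distribution
#'
#' `f(nu)` is the absolute number of clusters of size nu divided by the
#' summed primary track length inside the simulation volume (nm^-1), an
#' intensive quantity independent of fluence. The statistical uncertainty is
#' the standard error across `n_batches` independent sub-simulations
#' (default 10): histories are assigned to batches round-robin and the
#' standard error of the per-batch estimates is reported.
#'
#' @param histories List of histories: each `list(clusters = integer vector,
#'   track_length = nm)` as returned by [score_events()], or the output of
#'   [score_history()] (cluster vector with a `track_length` attribute).
#' @param n_batches Number of batches for the uncertainty estimate.
#' @param nu_max Optional cap on reported cluster size (frequencies beyond it
#'   are retained in the tail bin count but `f` is reported up to `nu_max`).
#' @return An object of class `cluster_tally`: data-frame-like fields `nu`,
#'   `f`, `se` plus `n_histories`, `total_track_length`, per-batch matrices.
#' @export
accumulate_ficsd <- function(histories, n_batches = 10, nu_max = NULL) {
  if (length(histories) < 1L) stop("need at least one history", call. = FALSE)
  histories <- lapply(histories, function(hst) {
    if (is.list(hst)) hst
    else list(clusters = as.integer(hst),
              track_length = attr(hst, "track_length"))
  })
  sizes <- lapply(histories, `[[`, "clusters")
  lens <- vapply(histories, `[[`, numeric(1), "track_length")
  max_nu <- max(1L, unlist(lapply(sizes, function(s) if (length(s)) max(s) else 0L)))
  if (!is.null(nu_max)) max_nu <- max(max_nu, nu_max)
  nb <- min(n_batches, length(histories))
  batch <- (seq_along(histories) - 1L) %% nb + 1L

  counts <- matrix(0, nrow = max_nu, ncol = nb)
  for (hh in seq_along(sizes)) {
    s <- sizes[[hh]]
    if (length(s)) {
      tb <- tabulate(s, nbins = max_nu)
      counts[, batch[hh]] <- counts[, batch[hh]] + tb
    }
  }
  blen <- as.numeric(tapply(lens, batch, sum))
  total_len <- sum(lens)
  f <- rowSums(counts) / total_len
  fb <- sweep(counts, 2, blen, "/")
  se <- if (nb > 1) apply(fb, 1, stats::sd) / sqrt(nb) else rep(NA_real_, max_nu)

  structure(list(nu = seq_len(max_nu), f = f, se = se,
                 n_histories = length(histories),
                 total_track_length = total_len,
                 batch_counts = counts, batch_track_lengths = blen,
                 n_batches = nb),
            class = "cluster_tally")
}

#' @export
print.cluster_tally <- function(x, ...) {
  cat(sprintf(paste0("<cluster tally> %d histories, %.4g nm primary track ",
                     "length, nu up to %d\n"),
              x$n_histories, x$total_track_length, max(x$nu)))
  print(utils::head(data.frame(nu = x$nu, f_per_nm = x$f, se_per_nm = x$se), 10))
  invisible(x)
}

#' Relative standard error of F_k and the history stop criterion
#'
#' Computes `se(F_k) / F_k` from the per-batch tallies; simulations are run
#' until this falls at or below `rel_se` for each k of interest (default 5:7
#' at 1%).
#'
#' @param tally A `cluster_tally`.
#' @param k Cluster-size thresholds to check.
#' @param rel_se Target relative standard error.
#' @return List with `rel_se` (named vector over k) and logical `converged`.
#' @export
ficsd_converged <- function(tally, k = 5:7, rel_se = 0.01) {
  stopifnot(inherits(tally, "cluster_tally"))
  nb <- tally$n_batches
  out <- vapply(k, function(kk) {
    rows <- tally$nu >= kk
    Fk <- sum(tally$f[rows])
    Fb <- colSums(tally$batch_counts[rows, , drop = FALSE]) /
      tally$batch_track_lengths
    se <- if (nb > 1) stats::sd(Fb) / sqrt(nb) else NA_real_
    if (Fk > 0) se / Fk else NA_real_
  }, numeric(1))
  names(out) <- paste0("F", k)
  list(rel_se = out, converged = all(is.finite(out)) && all(out <= rel_se))
}

#' Mean path length from the source sphere interior to its surface
#'
#' Mean distance from a uniformly distributed interior point along an
#' isotropic direction to the sphere surface; the closed form is `3 R / 4`
#' (12.75 nm for the default 34 nm source sphere). With `n_samples > 0` a
#' Monte Carlo estimate is returned instead, with its standard error attached
#' as attribute `se`.
#'
#' @param radius Sphere radius (nm), default 17.
#' @param n_samples Number of point-direction samples; 0 (default) gives the
#'   closed form.
#' @return Mean path length (nm).
#' @export
#' @examples
#' mean_source_path(17)  # 12.75
mean_source_path <- function(radius = 17, n_samples = 0) {
  stopifnot(radius > 0, n_samples >= 0)
  if (n_samples == 0) return(3 * radius / 4)
  n <- as.integer(n_samples)
  # uniform point in the ball
  u <- stats::runif(n)^(1 / 3) * radius
  p <- .isotropic_dirs(n) * u
  d <- .isotropic_dirs(n)
  pd <- rowSums(p * d)
  t_exit <- -pd + sqrt(pd^2 + radius^2 - rowSums(p^2))
  est <- mean(t_exit)
  attr(est, "se") <- stats::sd(t_exit) / sqrt(n)
  est
}

# n isotropic unit vectors (uniform on the sphere)
.isotropic_dirs <- function(n) {
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - cz^2)
  cbind(s * cos(phi), s * sin(phi), cz)
}
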