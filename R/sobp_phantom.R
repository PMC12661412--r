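# One-dimensional water-phantom fixture.
#
# A deliberately minimal depth-transport toy: ranges follow a power law
# (Bragg-Kleeman form, range = alpha * (A/Z^2) * E^p), each history marches
# along depth with steps capped by a maximum step size and by voxel
# boundaries, and the poststep energy follows from the range-energy relation.
# No straggling, scattering or nuclear interactions: the fixture's only job
# is to produce step logs with realistic end-of-range structure so the
# macroscale scorer can be exercised end to end.

#' Power-law stopping model
#'
#' `range_mm = alpha * (A / Z^2) * E^p` with E in MeV for protons and MeV per
#' nucleon for ions; the default `alpha = 0.022` mm, `p = 1.77` approximates
#' proton ranges in water (e.g. ~157 mm at 150 MeV).
#'
#' @param alpha Range coefficient for protons (mm MeV^-p).
#' @param p Range exponent (> 1).
#' @param max_step_mm Maximum step length (mm).
#' @param energy_cut Transport cutoff (MeV or MeV/u); the residual energy is
#'   deposited in place when the particle falls below it.
#' @return An object of class `stopping_model`.
#' @export
stopping_model <- function(alpha = 0.022, p = 1.77, max_step_mm = 1,
                           energy_cut = 0.5) {
  stopifnot(alpha > 0, p > 1, max_step_mm > 0, energy_cut > 0)
  structure(list(alpha = alpha, p = p, max_step_mm = max_step_mm,
                 energy_cut = energy_cut), class = "stopping_model")
}

.range_scale <- function(species) {
  row <- .species_row(species)
  if (row$Z <= 0) stop("stopping model supports protons and ions only",
                       call. = FALSE)
  row$A / row$Z^2
}

#' Particle range and its inverse under the power-law stopping model
#'
#' @param model A [stopping_model()].
#' @param species Species symbol.
#' @param energy Kinetic energy (MeV for protons, MeV/u for ions).
#' @return `range_energy`: residual range (mm); `energy_from_range`: energy
#'   for a given residual range.
#' @export
range_energy <- function(model, species, energy) {
  model$alpha * .range_scale(species) * energy^model$p
}

#' @rdname range_energy
#' @param range_mm Residual range (mm).
#' @export
energy_from_range <- function(model, species, range_mm) {
  (pmax(range_mm, 0) / (model$alpha * .range_scale(species)))^(1 / model$p)
}

#' Beam specification for the phantom
#'
#' @param species Species symbol.
#' @param energies Initial energies (MeV or MeV/u); a single value gives a
#'   pristine peak, several with `weights` an SOBP.
#' @param weights Non-negative spectral weights (normalized internally).
#' @param n_histories Number of primary histories.
#' @param seed RNG seed (used only with multinomial history allocation).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(species, energies, weights = 1,
                      n_histories = 200, seed = 1L) {
  weights <- rep_len(weights, length(energies))
  stopifnot(all(weights >= 0), sum(weights) > 0, all(energies > 0),
            n_histories >= 1)
  rng <- id_energy_range(species)
  if (any(energies < rng[1] | energies > rng[2])) {
    stop("beam energies outside the database range for ", species,
         call. = FALSE)
  }
  structure(list(species = species, energies = energies,
                 weights = weights / sum(weights),
                 n_histories = as.integer(n_histories), seed = seed),
            class = "beam_spec")
}

#' Transport a beam through a 1D voxelized water phantom
#'
#' Each history marches in depth from z = 0; steps are capped at the model's
#' maximum step size, at voxel boundaries, and at the residual range. The
#' poststep energy follows the power-law range-energy relation; the history
#' terminates when the energy falls below the transport cutoff (residual
#' energy deposited in place). Deterministic given the seed; with
#' `allocation = "proportional"` (default) histories are split across beam
#' energies by largest-remainder rounding and no RNG is consumed.
#'
#' @param beam A [beam_spec()].
#' @param model A [stopping_model()].
#' @param n_voxels Number of depth voxels.
#' @param voxel_mm Voxel size along depth (mm).
#' @param density_g_cm3 Phantom density (uniform; g cm^-3).
#' @param allocation `"proportional"` or `"multinomial"` sampling of
#'   histories across the beam energies.
#' @return Step log data frame with columns `history_id`, `species`, `Z`,
#'   `A`, `E_pre`, `E_post`, `unit`, `step_length_mm`, `edep_MeV` (per
#'   nucleon for ions), `voxel_ix`, `voxel_iy`, `voxel_iz`, `density_g_cm3`.
#' @export
transport_1d <- function(beam, model = stopping_model(), n_voxels = 300,
                         voxel_mm = 1, density_g_cm3 = 1,
                         allocation = c("proportional", "multinomial")) {
  stopifnot(inherits(beam, "beam_spec"), inherits(model, "stopping_model"))
  allocation <- match.arg(allocation)
  row <- .species_row(beam$species)
  .range_scale(beam$species)  # errors for species the stopping model lacks
  if (allocation == "multinomial") {
    set.seed(beam$seed)
    counts <- as.integer(stats::rmultinom(1, beam$n_histories, beam$weights))
  } else {
    exact <- beam$weights * beam$n_histories
    counts <- floor(exact)
    rem <- beam$n_histories - sum(counts)
    if (rem > 0) {
      extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    counts <- as.integer(counts)
  }
  depth_max <- n_voxels * voxel_mm
  # simulate one track per distinct energy, then replicate per history
  tracks <- lapply(seq_along(beam$energies), function(ei) {
    if (counts[ei] == 0L) return(NULL)
    E <- beam$energies[ei]
    z <- 0
    rows <- list()
    while (E > model$energy_cut && z < depth_max - 1e-12) {
      res <- range_energy(model, beam$species, E)
      to_boundary <- (floor(z / voxel_mm + 1e-12) + 1) * voxel_mm - z
      step <- min(model$max_step_mm, to_boundary, res)
      if (step <= 0) break
      E_post <- if (step >= res) 0 else
        energy_from_range(model, beam$species, res - step)
      vox <- floor((z + step / 2) / voxel_mm)
      rows[[length(rows) + 1L]] <- c(E, max(E_post, 0), step, vox)
      z <- z + step
      E <- E_post
      if (E <= model$energy_cut) break  # residual deposited in place
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    cbind(m, ei)
  })
  tracks <- do.call(rbind, tracks[!vapply(tracks, is.null, logical(1))])
  if (is.null(tracks)) {
    stop("no transportable steps: beam energies at or below the energy cut",
         call. = FALSE)
  }
  reps <- counts[tracks[, 5]]
  # one row per history per step: replicate each distinct-energy track
  n_steps <- nrow(tracks)
  idx <- rep(seq_len(n_steps), times = reps)
  hist_offset <- c(0, cumsum(counts))[tracks[, 5]]
  # per-step within-energy history number
  per_hist <- sequence(reps)
  out <- data.frame(
    history_id = hist_offset[idx] + per_hist,
    species = row$species, Z = row$Z, A = row$A,
    E_pre = tracks[idx, 1], E_post = tracks[idx, 2],
    unit = row$unit,
    step_length_mm = tracks[idx, 3],
    edep_MeV = tracks[idx, 1] - tracks[idx, 2],
    voxel_ix = 0L, voxel_iy = 0L,
    voxel_iz = as.integer(tracks[idx, 4]),
    density_g_cm3 = density_g_cm3,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Energy-deposition depth profile of a step log
#'
#' Sums `edep` per voxel (per history if `per_history`), the fixture's proxy
#' for absorbed dose.
#'
#' @param steps Step log from [transport_1d()].
#' @param n_voxels Number of depth voxels in the profile.
#' @return Numeric vector of length `n_voxels` (MeV or MeV/u per voxel).
#' @export
edep_profile <- function(steps, n_voxels) {
  prof <- numeric(n_voxels)
  agg <- rowsum(steps$edep_MeV, steps$voxel_iz)
  iz <- as.integer(rownames(agg)) + 1L
  ok <- iz >= 1 & iz <= n_voxels
  prof[iz[ok]] <- agg[ok]
  prof
}

#' Spectral weights for a flat spread-out Bragg peak
#'
#' Computes non-negative weights for a set of pristine-peak energies so that
#' the fixture's energy-deposition profile is flat across a stated plateau,
#' by non-negative least squares on the per-energy depth profiles.
#'
#' @param species Species symbol.
#' @param energies Candidate pristine-peak energies (decreasing ranges give
#'   the classic SOBP ripple structure).
#' @param model A [stopping_model()].
#' @param plateau_mm Depth window `c(z1, z2)` (mm) over which the profile is
#'   flattened.
#' @param n_voxels,voxel_mm Phantom discretization.
#' @return Normalized weight vector aligned with `energies`.
#' @export
sobp_weights <- function(species, energies, model = stopping_model(),
                         plateau_mm, n_voxels = 300, voxel_mm = 1) {
  profs <- vapply(energies, function(E) {
    bm <- beam_spec(species, E, 1, n_histories = 1)
    edep_profile(transport_1d(bm, model, n_voxels, voxel_mm), n_voxels)
  }, numeric(n_voxels))
  depth <- (seq_len(n_voxels) - 0.5) * voxel_mm
  sel <- depth >= plateau_mm[1] & depth <= plateau_mm[2]
  if (!any(sel)) stop("plateau window contains no voxels", call. = FALSE)
  w <- pracma::lsqnonneg(profs[sel, , drop = FALSE], rep(1, sum(sel)))$x
  if (sum(w) <= 0) stop("could not construct a flat plateau", call. = FALSE)
  w / sum(w)
}

#' Smooth synthetic ionization-parameter curves
#'
#' Parametric stand-in for database F_k(E) curves (the real quantities come
#' from track-structure simulation): per species,
#' `F_k(E) = N(E) * q(E)^(k-1)` with cluster density
#' `N(E) = c0 * |Z|^1.6 * E^-0.85` and tail parameter
#' `q(E) = q_min + q_span * x / (x + x0)`, `x = Z^2 / E`. The curves are
#' positive, smooth, decreasing in energy, increasing with atomic number and
#' non-increasing in k -- the qualitative structure of ionization-cluster
#' frequencies, with a higher frequency of large clusters for slower and
#' heavier (higher-LET) particles.
#'
#' @param species Character vector of species symbols.
#' @param c0 Density scale (nm^-1).
#' @param q_min,q_span,x0 Tail-parameter shape constants.
#' @param nu_max Length of the returned F_k vector.
#' @return Named list of functions `f(E) -> c(F_1, ..., F_{nu_max})`.
#' @export
synthetic_ip_curves <- function(species = c("p", "C", "O"), c0 = 0.02,
                                q_min = 0.15, q_span = 0.75, x0 = 5,
                                nu_max = 10) {
  out <- lapply(species, function(sp) {
    Z <- .species_row(sp)$Z
    force(Z)
    function(E) {
      x <- Z^2 / E
      N <- c0 * abs(Z)^1.6 * E^-0.85
      q <- q_min + q_span * x / (x + x0)
      N * q^(seq_len(nu_max) - 1)
    }
  })
  names(out) <- species
  out
}
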