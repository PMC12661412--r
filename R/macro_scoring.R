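# Macroscale scoring: condensed-history step logs -> voxel-averaged
# ionization parameters and cluster dose.
#
# Each step is divided into substeps at the midpoints between adjacent
# database energies lying inside (E_post, E_pre) -- including midpoints
# formed with the database neighbours just outside the step when those
# midpoints fall inside it. Interior substeps look the parameter up at the
# single database energy they enclose (no interpolation); the first and last
# substeps interpolate at their own midpoint energies. Track lengths follow
# from the assumption of constant energy loss per unit track length.

#' Decompose a condensed-history step into database-aligned substeps
#'
#' @param E_pre,E_post Prestep and poststep energies (MeV or MeV/u);
#'   `E_pre >= E_post`.
#' @param grid_energies Sorted database energies for the particle's species.
#' @param step_length Geometric step length T (mm).
#' @return Data frame with one row per substep: `energy` (lookup energy),
#'   `interpolated` (FALSE when the lookup is at a database energy), `t`
#'   (track length, mm). `sum(t)` equals `step_length` exactly (the last
#'   entry is set by subtraction).
#' @export
#' @examples
#' substep_decompose(28, 12, c(10, 20, 30), 16)
substep_decompose <- function(E_pre, E_post, grid_energies, step_length) {
  if (!length(grid_energies)) stop("empty energy grid", call. = FALSE)
  if (E_pre < E_post) stop("require E_pre >= E_post", call. = FALSE)
  if (step_length <= 0) stop("require step_length > 0", call. = FALSE)
  if (E_pre == E_post) {
    return(data.frame(energy = E_pre, interpolated = TRUE, t = step_length))
  }
  g <- sort(grid_energies)
  mids <- (g[-1] + g[-length(g)]) / 2
  mids <- mids[mids > E_post & mids < E_pre]
  if (!length(mids)) {
    return(data.frame(energy = (E_pre + E_post) / 2, interpolated = TRUE,
                      t = step_length))
  }
  bounds <- c(E_pre, sort(mids, decreasing = TRUE), E_post)
  N <- length(bounds) - 1L
  upper <- bounds[-length(bounds)]
  lower <- bounds[-1]
  energy <- numeric(N)
  interpolated <- logical(N)
  for (s in seq_len(N)) {
    if (s == 1L || s == N) {
      energy[s] <- (upper[s] + lower[s]) / 2
      interpolated[s] <- TRUE
    } else {
      inside <- g[g > lower[s] & g < upper[s]]
      # interior intervals enclose exactly one database energy by construction
      energy[s] <- inside[1]
      interpolated[s] <- FALSE
    }
  }
  t <- (upper - lower) / (E_pre - E_post) * step_length
  t[N] <- step_length - sum(t[-N])
  data.frame(energy = energy, interpolated = interpolated, t = t)
}

#' Score a condensed-history step log into a voxel tally
#'
#' In `substep` mode each step contributes `sum over substeps of t * I_p`
#' with lookups placed by [substep_decompose()]; in `prestep` mode (the
#' legacy method, retained for differencing) the whole step contributes
#' `T * I_p(E_pre)`. Track lengths are scaled by `density / rho0` to account
#' for the linear density dependence of the nanoscopic quantities. Energies
#' outside the database range use the clamped boundary values.
#'
#' @param steps Data frame with columns `species` (or `Z` and `A`), `E_pre`,
#'   `E_post`, `step_length_mm`, `voxel_ix`, `voxel_iy`, `voxel_iz`, and
#'   optionally `density_g_cm3` (default 1).
#' @param db An `id_database`.
#' @param mode `"substep"` or `"prestep"`.
#' @param k Which F_k definitions to score (default all up to `nu_max`).
#' @param voxel_volume_mm3 Voxel volume (mm^3).
#' @param rho0 Reference density of the database medium (g cm^-3).
#' @return An object of class `voxel_tally`: data frame with per-voxel
#'   `sum_t_mm` and one `sum_tIp_F<k>` column per k (mm * nm^-1), plus
#'   attributes `voxel_volume_mm3`, `rho0`, `k`.
#' @export
score_steps <- function(steps, db, mode = c("substep", "prestep"),
                        k = NULL, voxel_volume_mm3 = 1, rho0 = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "id_database"))
  if (is.null(k)) k <- seq_len(db$nu_max)
  if (is.null(steps$density_g_cm3)) steps$density_g_cm3 <- 1
  if (is.null(steps$species)) {
    steps$species <- vapply(steps$Z, function(z) resolve_isotope(z, z)$species,
                            character(1))
  } else {
    # isotopes map to the stable-ion database class
    known <- steps$species %in% names(db$records)
    if (!all(known) && !is.null(steps$Z)) {
      steps$species[!known] <- vapply(steps$Z[!known],
                                      function(z) resolve_isotope(z, z)$species,
                                      character(1))
    }
  }

  n <- nrow(steps)
  scale <- steps$density_g_cm3 / rho0
  if (mode == "prestep") {
    lookup_E <- steps$E_pre
    lookup_t <- steps$step_length_mm * scale
    lookup_sp <- steps$species
    lookup_step <- seq_len(n)
  } else {
    plans <- vector("list", n)
    for (s in seq_len(n)) {
      rec <- .db_record(db, steps$species[s])
      plans[[s]] <- substep_decompose(steps$E_pre[s], steps$E_post[s],
                                      rec$energies, steps$step_length_mm[s])
    }
    reps <- vapply(plans, nrow, integer(1))
    lookup_E <- unlist(lapply(plans, `[[`, "energy"))
    lookup_t <- unlist(lapply(plans, `[[`, "t")) * rep.int(scale, reps)
    lookup_sp <- rep.int(steps$species, reps)
    lookup_step <- rep.int(seq_len(n), reps)
  }

  Ip <- matrix(NA_real_, length(lookup_E), length(k))
  for (sp in unique(lookup_sp)) {
    rows <- lookup_sp == sp
    Ip[rows, ] <- interpolate_ip(db, sp, lookup_E[rows], k = k)
  }
  vox_key <- paste(steps$voxel_ix[lookup_step], steps$voxel_iy[lookup_step],
                   steps$voxel_iz[lookup_step], sep = ",")
  sum_t <- rowsum(lookup_t, vox_key)
  sum_tIp <- rowsum(Ip * lookup_t, vox_key)
  keys <- do.call(rbind, strsplit(rownames(sum_t), ",", fixed = TRUE))
  out <- data.frame(voxel_ix = as.integer(keys[, 1]),
                    voxel_iy = as.integer(keys[, 2]),
                    voxel_iz = as.integer(keys[, 3]),
                    sum_t_mm = as.numeric(sum_t))
  colnames(sum_tIp) <- paste0("sum_tIp_F", k)
  out <- cbind(out, as.data.frame(sum_tIp, row.names = FALSE))
  out <- out[order(out$voxel_iz, out$voxel_iy, out$voxel_ix), ]
  rownames(out) <- NULL
  structure(out, class = c("voxel_tally", "data.frame"),
            voxel_volume_mm3 = voxel_volume_mm3, rho0 = rho0, k = k)
}

#' Voxel-averaged ionization parameter
#'
#' `I_p = sum(t * I_p) / sum(t)` per voxel; voxels with zero summed track
#' length would be reported as `NA` (empty), never zero.
#'
#' @param tally A `voxel_tally` from [score_steps()].
#' @return Data frame with the voxel indices, `sum_t_mm`, fluence
#'   `phi_per_mm2` (track-length estimator: `sum_t / voxel volume`), and one
#'   `ip_F<k>` column per scored k (nm^-1).
#' @export
voxel_average <- function(tally) {
  k <- attr(tally, "k")
  vol <- attr(tally, "voxel_volume_mm3")
  out <- tally[, c("voxel_ix", "voxel_iy", "voxel_iz", "sum_t_mm")]
  out$phi_per_mm2 <- tally$sum_t_mm / vol
  for (kk in k) {
    s <- tally[[paste0("sum_tIp_F", kk)]]
    out[[paste0("ip_F", kk)]] <- ifelse(tally$sum_t_mm > 0,
                                        s / tally$sum_t_mm, NA_real_)
  }
  out
}

# clusters = t[mm] * Ip[nm^-1] = t * Ip * 1e6;
# voxel mass = V[mm^3] * rho0[g cm^-3] * 1e-3 cm^3/mm^3 * 1e12 pg/g
# => g[pg^-1] = t * Ip / (V * rho0) * 1e-3
.CLUSTER_DOSE_PG <- 1e-3

#' Cluster dose per voxel
#'
#' `g = phi * I_p / rho0` in pg^-1: the number of ionization clusters (of k
#' or more ionizations, for the F_k family) produced per unit mass in the
#' voxel. With the track-length fluence estimator this equals
#' `sum(t * I_p) / (V * rho0)` up to unit conversion; it scales linearly
#' with fluence while the voxel-averaged I_p does not.
#'
#' @param tally A `voxel_tally`.
#' @param rho0 Reference density (g cm^-3); defaults to the tally's.
#' @return Data frame with voxel indices, `phi_per_mm2` and one `g_F<k>`
#'   column per scored k (pg^-1).
#' @export
cluster_dose <- function(tally, rho0 = NULL) {
  k <- attr(tally, "k")
  vol <- attr(tally, "voxel_volume_mm3")
  if (is.null(rho0)) rho0 <- attr(tally, "rho0")
  out <- tally[, c("voxel_ix", "voxel_iy", "voxel_iz")]
  out$phi_per_mm2 <- tally$sum_t_mm / vol
  for (kk in k) {
    s <- tally[[paste0("sum_tIp_F", kk)]]
    out[[paste0("g_F", kk)]] <- s / (vol * rho0) * .CLUSTER_DOSE_PG
  }
  out
}

#' Histogram of database energy intervals spanned per step
#'
#' Diagnostic: for each step, the number of database energies strictly inside
#' `(E_post, E_pre)`. Large counts flag steps whose single-prestep lookup
#' would miss substantial parameter variation.
#'
#' @param steps Step log as in [score_steps()].
#' @param db An `id_database` (or a numeric vector of grid energies applied
#'   to all steps).
#' @return Data frame `n_spanned`, `steps` (counts of steps).
#' @export
steps_spanned_histogram <- function(steps, db) {
  counts <- vapply(seq_len(nrow(steps)), function(s) {
    g <- if (is.numeric(db)) db else .db_record(db, steps$species[s])$energies
    sum(g > steps$E_post[s] & g < steps$E_pre[s])
  }, numeric(1))
  tb <- table(factor(counts, levels = 0:max(counts)))
  data.frame(n_spanned = as.integer(names(tb)), steps = as.integer(tb))
}

#' Depth profile of a voxel map
#'
#' Extracts a 1D profile along a voxel axis, averaging over the transverse
#' indices, optionally normalized to 1 at a stated depth.
#'
#' @param map Data frame from [voxel_average()] or [cluster_dose()].
#' @param quantity Column to profile, e.g. `"g_F5"`.
#' @param voxel_size_mm Voxel size along the profiled axis (mm).
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param normalization_depth Optional depth (mm) at which the profile is
#'   normalized to 1 (the nearest voxel centre is used; an empty or zero
#'   value there is an error).
#' @return Data frame `depth_mm`, `value`.
#' @export
depth_profile <- function(map, quantity, voxel_size_mm = 1, axis = "z",
                          normalization_depth = NULL) {
  icol <- paste0("voxel_i", axis)
  stopifnot(icol %in% names(map), quantity %in% names(map))
  agg <- tapply(map[[quantity]], map[[icol]], mean, na.rm = TRUE)
  prof <- data.frame(depth_mm = (as.numeric(names(agg)) + 0.5) * voxel_size_mm,
                     value = as.numeric(agg))
  prof <- prof[order(prof$depth_mm), ]
  if (!is.null(normalization_depth)) {
    at <- which.min(abs(prof$depth_mm - normalization_depth))
    ref <- prof$value[at]
    if (!is.finite(ref) || ref == 0) {
      stop("normalization voxel is empty", call. = FALSE)
    }
    prof$value <- prof$value / ref
  }
  rownames(prof) <- NULL
  prof
}
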