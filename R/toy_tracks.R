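# Synthetic ionization-event histories.
#
# This generator is deliberately NOT a physics model. Its single job is to
# produce histories with known, analytically tractable structure so that the
# nanoscale scoring chain can be validated without a track-structure engine:
# primary ionizations are a Poisson process along a straight ray, secondaries
# branch at Poisson points and deposit a geometric number of ionizations
# within an exponential range. The 1/E default rate mimics the LET trend
# (slower particles ionize more densely); nothing more is claimed.

#' Toy track model
#'
#' @param primary_rate Primary ionization density lambda_p (nm^-1), either a
#'   single number or a function of energy (MeV); see [toy_rate()].
#' @param secondary_yield Expected secondary branchings per nm of primary
#'   track.
#' @param secondary_range Exponential scale of secondary ionization distances
#'   from the branch point (nm).
#' @param secondary_ionizations Expected ionizations per secondary (>= 1,
#'   shifted-geometric).
#' @param jitter_sigma Isotropic Gaussian jitter applied to every event
#'   position (nm).
#' @return An object of class `toy_track_model`.
#' @export
toy_track_model <- function(primary_rate, secondary_yield = 0,
                            secondary_range = 1,
                            secondary_ionizations = 1,
                            jitter_sigma = 0) {
  stopifnot(secondary_yield >= 0, secondary_range > 0,
            secondary_ionizations >= 1 || secondary_yield == 0,
            jitter_sigma >= 0)
  if (!is.function(primary_rate)) {
    stopifnot(is.numeric(primary_rate), primary_rate >= 0)
  }
  structure(list(primary_rate = primary_rate,
                 secondary_yield = secondary_yield,
                 secondary_range = secondary_range,
                 secondary_ionizations = secondary_ionizations,
                 jitter_sigma = jitter_sigma),
            class = "toy_track_model")
}

#' Default energy dependence of the toy primary ionization density
#'
#' `lambda_p(E) = scale / E`: ionization density falls with energy, mimicking
#' the LET trend of real charged particles.
#'
#' @param scale Rate at 1 MeV (nm^-1 MeV).
#' @return A function of energy (MeV) returning a rate (nm^-1).
#' @export
toy_rate <- function(scale) {
  force(scale)
  function(E) scale / E
}

.model_rate <- function(model, energy) {
  if (is.function(model$primary_rate)) {
    if (is.null(energy)) stop("model rate needs an energy", call. = FALSE)
    model$primary_rate(energy)
  } else model$primary_rate
}

# distance along ray from p (inside the cube) with direction u to the cube
# surface
.cube_exit <- function(p, u, h) {
  tt <- Inf
  for (ax in 1:3) {
    if (u[ax] != 0) {
      tt <- min(tt, (sign(u[ax]) * h - p[ax]) / u[ax])
    }
  }
  tt
}

#' Generate one synthetic primary history
#'
#' The primary starts at a uniform point inside the source sphere with an
#' isotropic direction and travels in a straight line to the cube surface.
#' Primary ionizations are Poisson along the ray segment outside the (vacuum)
#' source sphere; the returned track length is the length of that segment.
#' Secondaries branch at Poisson points on the same segment; each deposits a
#' shifted-geometric number of ionizations at exponential distances along an
#' isotropic direction (events leaving the cube are dropped). All event
#' positions are jittered by an isotropic Gaussian of scale `jitter_sigma`.
#'
#' Uses the current RNG state; see [generate_histories()] for a seeded batch.
#'
#' @param model A [toy_track_model()].
#' @param source A [source_sphere()].
#' @param cube_side Simulation-cube side (nm).
#' @param energy Primary energy (MeV), only needed when the model rate is a
#'   function.
#' @param history_id Identifier stored in the event table.
#' @return List with `events` (data frame `history_id`, `kind`, `species`,
#'   `energy_MeV`, `x_nm`, `y_nm`, `z_nm`) and `track_length` (nm, excluding
#'   the source sphere).
#' @export
generate_history <- function(model, source = source_sphere(),
                             cube_side = 100, energy = NULL,
                             history_id = 1L) {
  stopifnot(inherits(model, "toy_track_model"))
  h <- cube_side / 2
  R <- source$radius
  lambda <- .model_rate(model, energy)

  p0 <- as.numeric(.isotropic_dirs(1)) * stats::runif(1)^(1 / 3) * R +
    source$center
  u <- as.numeric(.isotropic_dirs(1))
  t_cube <- .cube_exit(p0, u, h)
  # exit parameter of the source sphere along the ray (start is inside it)
  pc <- p0 - source$center
  pd <- sum(pc * u)
  t_sph <- -pd + sqrt(pd^2 + R^2 - sum(pc^2))
  t_sph <- min(t_sph, t_cube)
  track_length <- t_cube - t_sph

  ev_pos <- matrix(numeric(0), ncol = 3)
  kind <- character(0)

  if (track_length > 0) {
    n_p <- stats::rpois(1, lambda * track_length)
    if (n_p > 0) {
      tp <- stats::runif(n_p, t_sph, t_cube)
      ev_pos <- rbind(ev_pos, rep(p0, each = n_p) + outer(tp, u))
      kind <- c(kind, rep("primary", n_p))
    }
    n_s <- stats::rpois(1, model$secondary_yield * track_length)
    if (n_s > 0) {
      ts <- stats::runif(n_s, t_sph, t_cube)
      for (s in seq_len(n_s)) {
        b <- p0 + ts[s] * u
        us <- as.numeric(.isotropic_dirs(1))
        m <- model$secondary_ionizations
        n_i <- 1L + stats::rgeom(1, prob = 1 / m)
        dist <- stats::rexp(n_i, rate = 1 / model$secondary_range)
        pos <- rep(b, each = n_i) + outer(dist, us)
        # drop events outside the cube or inside the vacuum source sphere
        keep <- apply(abs(pos) <= h, 1, all) &
          sqrt(rowSums(sweep(pos, 2, source$center)^2)) >= R
        if (any(keep)) {
          ev_pos <- rbind(ev_pos, pos[keep, , drop = FALSE])
          kind <- c(kind, rep("secondary", sum(keep)))
        }
      }
    }
  }
  if (model$jitter_sigma > 0 && nrow(ev_pos) > 0) {
    ev_pos <- ev_pos + matrix(stats::rnorm(length(ev_pos),
                                           sd = model$jitter_sigma),
                              ncol = 3)
  }
  events <- data.frame(
    history_id = rep(as.integer(history_id), nrow(ev_pos)),
    kind = kind,
    species = rep("toy", nrow(ev_pos)),
    energy_MeV = rep(if (is.null(energy)) NA_real_ else energy, nrow(ev_pos)),
    x_nm = ev_pos[, 1], y_nm = ev_pos[, 2], z_nm = ev_pos[, 3],
    stringsAsFactors = FALSE
  )
  list(events = events, track_length = track_length)
}

#' Generate a seeded batch of synthetic histories
#'
#' @inheritParams generate_history
#' @param n Number of histories.
#' @param seed RNG seed; the batch is bit-reproducible for a given seed.
#' @return List with `events` (one stacked data frame) and `track_lengths`
#'   (numeric vector, one entry per history).
#' @export
generate_histories <- function(model, n, source = source_sphere(),
                               cube_side = 100, energy = NULL, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  lens <- numeric(n)
  for (i in seq_len(n)) {
    hst <- generate_history(model, source, cube_side, energy, history_id = i)
    out[[i]] <- hst$events
    lens[i] <- hst$track_length
  }
  list(events = do.call(rbind, out), track_lengths = lens)
}

#' Closed-form expected F_1 per unit track length for an axial toy track
#'
#' For a primary constrained to a cylinder axis with constant ionization rate
#' lambda and no secondaries, the number of ionizations in each traversed
#' cylinder of length L is Poisson(lambda L), so the expected number of
#' non-empty cylinders (clusters of one or more ionizations) per unit track
#' length is `(1 - exp(-lambda L)) / L`. Used as the independent oracle for
#' the scoring chain.
#'
#' @param primary_rate Constant ionization rate lambda (nm^-1).
#' @param cyl_length Cylinder length L (nm).
#' @return Expected clusters (nu >= 1) per nm.
#' @export
closed_form_f1 <- function(primary_rate, cyl_length) {
  if (!is.numeric(primary_rate) || any(primary_rate < 0)) {
    stop("unsupported configuration: need a constant rate >= 0", call. = FALSE)
  }
  stopifnot(cyl_length > 0)
  (1 - exp(-primary_rate * cyl_length)) / cyl_length
}
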