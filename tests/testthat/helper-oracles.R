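# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized/indexed code paths.

# Exhaustive placement: march positions axis by axis with explicit pitch-fit
# tests; returns the centre list. Shifted rows keep the column count of the
# packing rule (sub-pitch protrusion along the row axis is tolerated, see
# build_cylinder_lattice docs).
oracle_lattice_centers <- function(cube, d, L, shift) {
  h <- cube / 2
  centers <- NULL
  k <- 1L
  while (k * L <= cube + 1e-9) {
    z <- -h + (k - 0.5) * L
    j <- 1L
    while (j * d <= cube + 1e-9) {
      y <- -h + (j - 0.5) * d
      off <- if (j %% 2L == 0L) shift else 0
      i <- 1L
      while (i * d <= cube + 1e-9) {
        centers <- rbind(centers, c(-h + (i - 0.5) * d + off, y, z))
        i <- i + 1L
      }
      j <- j + 1L
    }
    k <- k + 1L
  }
  if (is.null(centers)) matrix(numeric(0), ncol = 3) else centers
}

# Linear scan point-in-cylinder lookup: first (lowest-index) containing
# cylinder, closed boundaries.
oracle_locate_scan <- function(p, centers, d, L) {
  r2 <- (d / 2)^2
  for (row in seq_len(nrow(centers))) {
    if ((p[1] - centers[row, 1])^2 + (p[2] - centers[row, 2])^2 <= r2 &&
        abs(p[3] - centers[row, 3]) <= L / 2) {
      return(row)
    }
  }
  NA_integer_
}

# Sphere-cylinder intersection by dense surface/solid point sampling of the
# cylinder: intersects iff any sampled cylinder point lies inside the sphere.
oracle_cyl_sphere_intersects <- function(center, d, L, s_center, s_radius,
                                         n_grid = 25) {
  r <- d / 2
  g <- expand.grid(rr = seq(0, r, length.out = n_grid),
                   ph = seq(0, 2 * pi, length.out = 3 * n_grid),
                   zz = seq(-L / 2, L / 2, length.out = n_grid))
  px <- center[1] + g$rr * cos(g$ph)
  py <- center[2] + g$rr * sin(g$ph)
  pz <- center[3] + g$zz
  any((px - s_center[1])^2 + (py - s_center[2])^2 +
        (pz - s_center[3])^2 < s_radius^2)
}

# Fine-sampling reference for substep scoring: under constant energy loss per
# unit track length the track-averaged parameter is the plain mean of the
# (clamped, linearly interpolated) parameter over energies uniform in
# [E_post, E_pre].
oracle_step_mean_ip <- function(db, species, E_pre, E_post, k, n = 1e4) {
  E <- seq(E_post, E_pre, length.out = n)
  mean(interpolate_ip(db, species, E, k = k))
}

# Shared small fixtures -----------------------------------------------------

tiny_lattice <- function(cube = 20) {
  build_cylinder_lattice(cube, 2.3, 3.4, 1.15)
}

fixture_curves <- function() synthetic_ip_curves(c("p", "C", "O"))

# cached database: building takes ~0.2 s, reused by several files
fixture_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_id_database(fixture_curves())
    cache
  }
})
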