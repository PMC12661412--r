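test_that("packing handles the degenerate single- and zero-cylinder cubes", {
  expect_equal(build_cylinder_lattice(3.4, 2.3, 3.4, 1.15)$n, 1L)
  expect_equal(build_cylinder_lattice(2.0, 2.3, 3.4, 1.15)$n, 0L)
  expect_error(build_cylinder_lattice(-1, 2.3, 3.4), "invalid geometry")
})

test_that("packing is deterministic and matches the exhaustive placement oracle", {
  for (cube in c(10, 17.5)) {
    lat <- build_cylinder_lattice(cube, 2.3, 3.4, 1.15)
    lat2 <- build_cylinder_lattice(cube, 2.3, 3.4, 1.15)
    expect_identical(lat$centers, lat2$centers)
    oc <- oracle_lattice_centers(cube, 2.3, 3.4, 1.15)
    expect_equal(lat$n, nrow(oc))
    expect_equal(lat$centers[order(lat$centers[, 3], lat$centers[, 2],
                                   lat$centers[, 1]), , drop = FALSE],
                 oc[order(oc[, 3], oc[, 2], oc[, 1]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("no two cylinders overlap (pairwise circle test per layer)", {
  lat <- tiny_lattice()
  d <- lat$cyl_diameter
  for (z in unique(lat$centers[, 3])) {
    layer <- lat$centers[lat$centers[, 3] == z, , drop = FALSE]
    dd <- as.matrix(dist(layer[, 1:2]))
    diag(dd) <- Inf
    expect_gte(min(dd), d - 1e-12)
  }
})

test_that("source-sphere exclusion removes intersecting cylinders only", {
  lat <- tiny_lattice()
  expect_equal(exclude_source_overlap(lat, source_sphere(0))$n, lat$n)
  expect_equal(exclude_source_overlap(lat, source_sphere(1000))$n, 0L)

  src <- source_sphere(7)
  ex <- exclude_source_overlap(lat, src)
  # the analytic distance test agrees with dense point-sampling of each
  # cylinder solid
  removed_oracle <- vapply(seq_len(lat$n), function(i) {
    oracle_cyl_sphere_intersects(lat$centers[i, ], lat$cyl_diameter,
                                 lat$cyl_length, src$center, src$radius)
  }, logical(1))
  expect_equal(ex$n_removed, sum(removed_oracle))
  expect_lt(ex$n, lat$n)
})

test_that("spatial-index lookup equals the linear-scan oracle", {
  lat <- tiny_lattice()
  # cylinder centres map to themselves; gap points map to nothing
  expect_equal(locate_event(lat$centers[c(1, 17, lat$n), ], lat),
               c(1L, 17L, lat$n))
  corner <- c(-lat$cube_side / 2 + 0.01, -lat$cube_side / 2 + 2.29, 0)
  expect_true(is.na(locate_event(corner, lat)))

  set.seed(42)
  pts <- matrix(runif(3 * 2000, -lat$cube_side / 2, lat$cube_side / 2),
                ncol = 3)
  fast <- locate_event(pts, lat)
  slow <- vapply(seq_len(nrow(pts)), function(i) {
    oracle_locate_scan(pts[i, ], lat$centers, lat$cyl_diameter,
                       lat$cyl_length)
  }, integer(1))
  expect_identical(fast, slow)

  # still exact after source exclusion renumbers the cylinders
  ex <- exclude_source_overlap(lat, source_sphere(7))
  fast2 <- locate_event(pts, ex)
  slow2 <- vapply(seq_len(nrow(pts)), function(i) {
    oracle_locate_scan(pts[i, ], ex$centers, ex$cyl_diameter, ex$cyl_length)
  }, integer(1))
  expect_identical(fast2, slow2)
})

test_that("primary termination budget follows the 1% gap rule", {
  expect_equal(primary_termination_budget(15, 10, 0.01), 0.05)
  expect_equal(primary_termination_budget(1.0, 0.9, 0.01), 0.001)
  expect_error(primary_termination_budget(10, 10), "E0 > E_next_lower")
  expect_error(primary_termination_budget(5, 10), "E0 > E_next_lower")
  # threshold semantics: the budget is a bound on cumulative loss
  budget <- primary_termination_budget(15, 10)
  expect_true(0.049 <= budget)   # continues
  expect_false(0.051 <= budget)  # killed
})

test_that("secondary transport decisions respect the production cutoffs", {
  rules <- transport_rules()
  expect_equal(secondary_transport_decision("e-", 0.04, rules), "transport")
  expect_equal(secondary_transport_decision("e-", 0.054, rules), "terminate")
  expect_equal(secondary_transport_decision("p", 1.0, rules), "transport")
  expect_equal(secondary_transport_decision("p", 2.0, rules), "terminate")
  expect_equal(secondary_transport_decision("He", 0.1, rules), "terminate")
  expect_equal(secondary_transport_decision("Ar", 500, rules), "terminate")
  expect_error(secondary_transport_decision("mystery", 1, rules),
               "unknown species")
})

test_that("periodic boundary re-entry reflects through the cube centre", {
  re <- apply_pbc(c(50, 3, 7), c(1, 0, 0), 2.5, cube_side = 100)
  expect_equal(re$position, c(-50, -3, -7))
  expect_equal(re$direction, c(1, 0, 0))
  expect_equal(re$energy, 2.5)
  expect_error(apply_pbc(c(10, 3, 7), c(1, 0, 0), 2.5, 100), "boundary")
})

test_that("history scoring groups events into clusters by cylinder", {
  lat <- tiny_lattice()
  c1 <- lat$centers[5, ]
  c2 <- lat$centers[11, ]
  one <- score_history(matrix(c1, ncol = 3), lat, track_length = 10)
  expect_equal(as.integer(one), 1L)
  ev <- rbind(matrix(rep(c1, 4), ncol = 3, byrow = TRUE),
              matrix(rep(c2, 2), ncol = 3, byrow = TRUE))
  cl <- score_history(ev, lat, track_length = 10)
  expect_equal(sort(as.integer(cl)), c(2L, 4L))
  expect_error(score_history(matrix(c1, ncol = 3), lat, track_length = 0),
               "zero track length")
  # conservation: sum(nu * n(nu)) equals the number of in-cylinder events
  set.seed(7)
  pts <- matrix(runif(300, -10, 10), ncol = 3)
  cl <- score_history(pts, lat, track_length = 50)
  expect_equal(sum(cl), sum(!is.na(locate_event(pts, lat))))
})

test_that("fICSD accumulation is intensive and its batch SE behaves", {
  hist1 <- list(clusters = c(1L, 1L, 2L), track_length = 10)
  histories <- rep(list(hist1), 20)
  tal <- accumulate_ficsd(histories)
  expect_equal(tal$f, c(2 * 20, 20) / 200)
  expect_equal(tal$se, c(0, 0))  # identical batches
  # doubling history count leaves f unchanged
  tal2 <- accumulate_ficsd(rep(list(hist1), 40))
  expect_equal(tal2$f, tal$f)
  conv <- ficsd_converged(tal, k = 1:2, rel_se = 0.01)
  expect_true(conv$converged)
})

test_that("axial Poisson tracks reproduce the closed-form F_1 oracle", {
  lat <- tiny_lattice()
  L <- lat$cyl_length
  lambda <- 0.35
  col_sel <- lat$ijk[, 1] == 3 & lat$ijk[, 2] == 3
  zs <- range(lat$centers[col_sel, 3])
  z0 <- zs[1] - L / 2
  z1 <- zs[2] + L / 2
  track_len <- z1 - z0
  axis_xy <- lat$centers[which(col_sel)[1], 1:2]

  set.seed(11)
  n_hist <- 20000
  histories <- lapply(seq_len(n_hist), function(i) {
    n <- rpois(1, lambda * track_len)
    z <- runif(n, z0, z1)
    ev <- cbind(rep(axis_xy[1], n), rep(axis_xy[2], n), z)
    list(clusters = as.integer(score_history(ev, lat, track_len)),
         track_length = track_len)
  })
  tal <- accumulate_ficsd(histories)
  f1 <- sum(tal$f)
  se <- ficsd_converged(tal, k = 1)$rel_se * f1
  expect_lt(abs(f1 - closed_form_f1(lambda, L)), 3 * se + 1e-12)
})

test_that("Monte Carlo mean source path converges to 3R/4", {
  expect_equal(mean_source_path(17), 12.75)
  expect_equal(mean_source_path(4), 3.0)
  set.seed(3)
  est <- mean_source_path(17, n_samples = 1e5)
  expect_lt(abs(est - 12.75), 3 * attr(est, "se"))
})
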