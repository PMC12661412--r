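test_that("substep decomposition reproduces the worked midpoint example", {
  plan <- substep_decompose(28, 12, c(10, 20, 30), 16)
  expect_equal(plan$energy, c(26.5, 20, 13.5))
  expect_equal(plan$interpolated, c(TRUE, FALSE, TRUE))
  expect_equal(plan$t, c(3, 10, 3))
})

test_that("substep decomposition handles degenerate steps", {
  # zero-loss step: one substep at the (pre = post) energy
  plan <- substep_decompose(15, 15, c(10, 20), 2)
  expect_equal(nrow(plan), 1L)
  expect_equal(plan$t, 2)
  expect_equal(plan$energy, 15)
  # no database midpoint inside: single substep at the step midpoint
  plan <- substep_decompose(14, 12, c(10, 20, 30), 5)
  expect_equal(nrow(plan), 1L)
  expect_equal(plan$energy, 13)
  expect_true(plan$interpolated)
  expect_error(substep_decompose(5, 10, c(1, 2), 1), "E_pre >= E_post")
  expect_error(substep_decompose(10, 5, numeric(0), 1), "empty")
})

test_that("exterior midpoints are used only when they fall inside the step", {
  g <- c(10, 20, 30, 40, 50)
  # three database energies inside, both exterior midpoints inside: 5 substeps
  wide <- substep_decompose(46, 14, g, 10)
  expect_equal(nrow(wide), 5L)
  expect_equal(wide$energy[2:4], c(40, 30, 20))
  expect_false(any(wide$interpolated[2:4]))
  # three database energies inside, exterior midpoints outside: 3 substeps
  narrow <- substep_decompose(42, 18, g, 10)
  expect_equal(nrow(narrow), 3L)
  expect_equal(narrow$energy[2], 30)
  # first/last substeps interpolate at their own midpoints even though their
  # intervals contain the database energies 40 and 20
  expect_equal(narrow$energy[c(1, 3)], c((42 + 35) / 2, (25 + 18) / 2))
  expect_true(all(narrow$interpolated[c(1, 3)]))
})

test_that("substep track lengths always sum exactly to the step length", {
  set.seed(9)
  g <- sort(runif(30, 0.5, 400))
  for (rep in 1:500) {
    E_post <- runif(1, 0.1, 300)
    E_pre <- E_post + rexp(1, 1 / 30)
    T <- rexp(1, 1)
    plan <- substep_decompose(E_pre, E_post, g, T)
    expect_equal(sum(plan$t), T, tolerance = 1e-13)
    expect_true(all(plan$t >= 0))
    expect_true(all(plan$energy >= E_post - 1e-12 &
                      plan$energy <= E_pre + 1e-12))
  }
})

test_that("substep and prestep modes agree for a constant parameter", {
  flat_db <- local({
    crv <- function(E) rep(0.4, 10) * 0.5^(seq_len(10) - 1)
    # constant in E: adaptive grid collapses to the endpoints
    build_id_database(list(p = crv))
  })
  steps <- data.frame(species = "p", E_pre = c(200, 90), E_post = c(150, 10),
                      step_length_mm = c(2, 3), voxel_ix = 0, voxel_iy = 0,
                      voxel_iz = c(0, 1))
  sub <- score_steps(steps, flat_db, "substep")
  pre <- score_steps(steps, flat_db, "prestep")
  expect_equal(sub$sum_tIp_F1, pre$sum_tIp_F1)
  expect_equal(sub$sum_tIp_F5, pre$sum_tIp_F5)
})

test_that("substep mode beats prestep when the parameter grows toward low energy", {
  db <- fixture_db()
  # one long step spanning many database energies
  steps <- data.frame(species = "p", E_pre = 10, E_post = 0.2,
                      step_length_mm = 1, voxel_ix = 0, voxel_iy = 0,
                      voxel_iz = 0)
  sub <- score_steps(steps, db, "substep")
  pre <- score_steps(steps, db, "prestep")
  expect_gt(sub$sum_tIp_F5, pre$sum_tIp_F5)
})

test_that("substep scoring matches a fine-sampling track integrator", {
  db <- fixture_db()
  set.seed(21)
  for (sp in c("p", "C")) {
    rng <- id_energy_range(sp)
    for (rep in 1:20) {
      E_post <- runif(1, rng[1], rng[2] * 0.8)
      E_pre <- min(E_post * runif(1, 1.02, 1.6), rng[2])
      steps <- data.frame(species = sp, E_pre = E_pre, E_post = E_post,
                          step_length_mm = 1, voxel_ix = 0, voxel_iy = 0,
                          voxel_iz = 0)
      sub <- score_steps(steps, db, "substep", k = 5)
      ref <- oracle_step_mean_ip(db, sp, E_pre, E_post, k = 5)
      # agreement within the 1% interpolation error bound of the 5% grid
      expect_equal(sub$sum_tIp_F5, ref, tolerance = 0.01)
    }
  }
})

test_that("voxel averaging is the track-weighted mean with empty flagged NA", {
  db <- fixture_db()
  rec_E <- db$records$p$energies
  steps <- data.frame(species = "p",
                      E_pre = rec_E[c(10, 20)], E_post = rec_E[c(10, 20)],
                      step_length_mm = c(1, 3), voxel_ix = 0, voxel_iy = 0,
                      voxel_iz = 0)
  tal <- score_steps(steps, db, "substep", k = 5)
  av <- voxel_average(tal)
  ip <- sapply(rec_E[c(10, 20)],
               function(E) interpolate_ip(db, "p", E, k = 5))
  expect_equal(av$ip_F5, (1 * ip[1] + 3 * ip[2]) / 4)
  # weighted arithmetic identity: t = (1, 3), Ip = (4, 8) -> 7
  expect_equal((1 * 4 + 3 * 8) / 4, 7)
})

test_that("cluster dose scales with fluence while voxel-averaged Ip does not", {
  db <- fixture_db()
  set.seed(33)
  n <- 40
  E_post <- runif(n, 0.2, 100)
  steps <- data.frame(species = "p", E_pre = pmin(E_post * 1.3, 230),
                      E_post = E_post, step_length_mm = runif(n, 0.1, 1),
                      voxel_ix = 0, voxel_iy = 0,
                      voxel_iz = sample(0:3, n, replace = TRUE))
  one <- score_steps(steps, db, "substep")
  two <- score_steps(rbind(steps, steps), db, "substep")
  expect_equal(voxel_average(two)$ip_F5, voxel_average(one)$ip_F5)
  expect_equal(cluster_dose(two)$g_F5, 2 * cluster_dose(one)$g_F5)
  # bounding: the voxel average lies within the contributing lookups
  av <- voxel_average(one)
  rngF5 <- range(interpolate_ip(db, "p", c(0.1, 230), k = 5))
  expect_true(all(av$ip_F5 >= min(rngF5) & av$ip_F5 <= max(rngF5)))
})

test_that("cluster dose follows the hand-computed unit conversion", {
  # three hand-authored contributions in one 1 mm^3 voxel of unit density:
  # g [pg^-1] = sum(t [mm] * Ip [nm^-1]) * 1e6 clusters / (1e9 pg)
  db <- read_db(test_path("fixtures", "mini_db.csv"))
  steps <- data.frame(species = "p", E_pre = c(1, 10, 100),
                      E_post = c(1, 10, 100),
                      step_length_mm = c(0.5, 1, 2),
                      voxel_ix = 0, voxel_iy = 0, voxel_iz = 0)
  tal <- score_steps(steps, db, "prestep", k = 1)
  g <- cluster_dose(tal)
  ip <- c(0.9, 0.45, 0.21)  # F_1 of the fixture records
  expect_equal(g$g_F1, sum(c(0.5, 1, 2) * ip) * 1e-3)
  # empty beam: zero fluence means zero cluster dose
  expect_equal(cluster_dose(tal)$g_F1[tal$sum_t_mm == 0], numeric(0))
})

test_that("track lengths scale with material density", {
  db <- read_db(test_path("fixtures", "mini_db.csv"))
  base <- data.frame(species = "p", E_pre = 10, E_post = 10,
                     step_length_mm = 1, voxel_ix = 0, voxel_iy = 0,
                     voxel_iz = 0, density_g_cm3 = 1)
  dense <- transform(base, density_g_cm3 = 1.5)
  t1 <- score_steps(base, db, "prestep", k = 1)
  t2 <- score_steps(dense, db, "prestep", k = 1)
  expect_equal(t2$sum_t_mm, 1.5 * t1$sum_t_mm)
  expect_equal(t2$sum_tIp_F1, 1.5 * t1$sum_tIp_F1)
})

test_that("spanned-interval histogram counts database energies inside steps", {
  g <- c(1, 2, 4, 8, 16)
  steps <- data.frame(species = "p",
                      E_pre = c(10, 10, 3, 5), E_post = c(10, 0.5, 2.5, 3),
                      step_length_mm = 1, voxel_ix = 0, voxel_iy = 0,
                      voxel_iz = 0)
  h <- steps_spanned_histogram(steps, g)
  counts <- rep(h$n_spanned, h$steps)
  expect_equal(sort(counts), c(0, 0, 1, 4))
})

test_that("depth profiles normalize at the requested depth", {
  map <- data.frame(voxel_ix = 0, voxel_iy = 0, voxel_iz = 0:9,
                    g_F5 = c(rep(2, 5), 4, 6, 8, 3, 1))
  prof <- depth_profile(map, "g_F5", voxel_size_mm = 1,
                        normalization_depth = 6.5)
  expect_equal(prof$value[prof$depth_mm == 6.5], 1)
  flat <- depth_profile(data.frame(voxel_ix = 0, voxel_iy = 0,
                                   voxel_iz = 0:4, g_F5 = 3),
                        "g_F5", normalization_depth = 2)
  expect_equal(flat$value, rep(1, 5))
  empty <- data.frame(voxel_ix = 0, voxel_iy = 0, voxel_iz = 0:2,
                      g_F5 = c(1, 0, 2))
  expect_error(depth_profile(empty, "g_F5", normalization_depth = 1.5),
               "empty")
})
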