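test_that("point acceleration reduces to known closed forms", {
  # constant steady spin about Z: a_p = -w^2 r along the offset (centripetal)
  T <- 5L
  hist <- list(
    quat = matrix(rep(c(1, 0, 0, 0), T), 4),
    a_world = matrix(0, 3, T),
    alpha_body = matrix(0, 3, T),
    omega_body = matrix(rep(c(0, 0, 10), T), 3)
  )
  ap <- point_acceleration(hist, c(0.1, 0, 0))
  expect_equal(ap, matrix(rep(c(-10, 0, 0), T), 3))
  # r = 0 returns the CoG acceleration expressed in the body frame
  hist$a_world <- matrix(rnorm(3 * T), 3)
  expect_equal(point_acceleration(hist, c(0, 0, 0)), hist$a_world)
})

test_that("point acceleration matches a finite-difference oracle", {
  # smooth prescribed trajectory: x(t) sinusoidal, rotation about a fixed
  # axis with sinusoidal angle; compare against double-differenced position
  dt <- 1e-4
  tt <- seq(0, 0.05, by = dt)
  T <- length(tt)
  ax <- c(0, 0, 1)
  ang <- 0.8 * sin(2 * pi * 30 * tt)
  angd <- 0.8 * 2 * pi * 30 * cos(2 * pi * 30 * tt)
  angdd <- -0.8 * (2 * pi * 30)^2 * sin(2 * pi * 30 * tt)
  xc <- rbind(0.02 * sin(2 * pi * 25 * tt), 0, 0)
  acc <- rbind(-0.02 * (2 * pi * 25)^2 * sin(2 * pi * 25 * tt), 0, 0)
  hist <- list(
    quat = rbind(cos(ang / 2), 0, 0, sin(ang / 2)),
    a_world = acc,
    alpha_body = rbind(0, 0, angdd),
    omega_body = rbind(0, 0, angd)
  )
  r <- c(0.05, 0.02, 0)
  ap_body <- point_acceleration(hist, r)
  # world position of the point, double-differenced
  pos <- vapply(seq_len(T), function(i) {
    R <- matrix(c(cos(ang[i]), sin(ang[i]), 0,
                  -sin(ang[i]), cos(ang[i]), 0, 0, 0, 1), 3)
    xc[, i] + R %*% r
  }, numeric(3))
  num <- (pos[, 3:T] - 2 * pos[, 2:(T - 1)] + pos[, 1:(T - 2)]) / dt^2
  # rotate analytic body-frame result to world for comparison
  ap_world <- vapply(seq_len(T), function(i) {
    R <- matrix(c(cos(ang[i]), sin(ang[i]), 0,
                  -sin(ang[i]), cos(ang[i]), 0, 0, 0, 1), 3)
    R %*% ap_body[, i]
  }, numeric(3))
  expect_equal(ap_world[, 2:(T - 1)], num, tolerance = 1e-3)
})

test_that("channel projection is tangential and orthonormal", {
  layout <- sensor_layout()
  T <- 4L
  # purely radial acceleration at every location reads zero on both axes
  pa_radial <- lapply(seq_len(6L), function(j)
    matrix(rep(100 * layout$locations[, j], T), 3))
  ch <- project_channels(pa_radial, layout)
  expect_equal(max(abs(ch)), 0)
  # acceleration along axis-1 of a location reads on that channel only
  pa <- lapply(seq_len(6L), function(j) matrix(0, 3, T))
  pa[[3]] <- matrix(rep(100 * layout$axis1[, 3], T), 3)
  ch <- project_channels(pa, layout)
  expect_equal(ch[5, ], rep(100, T))   # location 3, axis 1 => channel 5
  expect_equal(ch[6, ], rep(0, T))
  # Pythagoras: the two tangential channels never exceed the vector norm
  v <- rnorm(3)
  pa_v <- lapply(seq_len(6L), function(j) matrix(v, 3, T))
  ch <- project_channels(pa_v, layout)
  for (j in seq_len(6L)) {
    expect_lte(max(ch[2 * j - 1, ]^2 + ch[2 * j, ]^2), sum(v^2) + 1e-12)
  }
})

test_that("a body displaced away from the ground produces zero channels", {
  rec <- simulate_impact(one_scenario(vn = 2, vt = 3), contact = test_contact(),
                         duration = 0.02, dt = 1e-5, initial_gap = 1)
  expect_equal(max(abs(rec$helmet)), 0)
  expect_equal(max(abs(rec$head_lin)), 0)
  expect_equal(max(abs(rec$head_rot)), 0)
})

test_that("frictionless central normal impact produces no head rotation", {
  cp <- contact_params(liner_friction_mu = 0, ground_friction_mu = 0,
                       n_liner_patches = 32L)
  sc <- one_scenario(beta = 0, gamma = 0, vn = 6, vt = 3, theta = 0)
  # pure normal approach: zero the tangential speed at simulation level
  sc$vt_ms <- 1e-9
  rec <- simulate_impact(sc, contact = cp, duration = 0.02, dt = 5e-6)
  rot_peak <- max(resultant(rec$head_rot))
  lin_peak <- max(resultant(rec$head_lin))
  expect_lt(rot_peak, 1e-6 * lin_peak)
})

test_that("solver conserves momentum and dissipates energy", {
  for (sc in list(one_scenario(beta = 30, gamma = -40, vn = 8, vt = 12,
                               theta = 200),
                  one_scenario(beta = -80, gamma = 10, vn = 4, vt = 16,
                               theta = 45))) {
    rec <- quick_record(sc)
    d <- rec$meta$diagnostics
    # impulse of external forces equals total momentum change within 1%
    err <- sqrt(sum((d$impulse - d$momentum_change)^2)) /
      sqrt(sum(d$momentum_change^2))
    expect_lt(err, 0.01)
    # liner internal forces cancel to machine precision
    expect_lt(d$newton_residual, 1e-9)
    # couplings only dissipate
    expect_lte(d$ke_end, d$ke_start)
  }
})

test_that("helmet and head angular velocities decouple", {
  r2 <- simulate_impact(one_scenario(beta = 20, gamma = 30, vn = 7, vt = 14,
                                     theta = 90), contact = test_contact(),
                        duration = 0.02, dt = 2e-6)
  expect_false(isTRUE(all.equal(r2$history$head$omega_body,
                                r2$history$helmet$omega_body)))
})

test_that("simulation is deterministic", {
  sc <- one_scenario(beta = 15, gamma = -25, vn = 6, vt = 9, theta = 310)
  a <- quick_record(sc)
  b <- quick_record(sc)
  expect_identical(a$helmet, b$helmet)
  expect_identical(a$head_rot, b$head_rot)
})

test_that("dataset generation collects records, failures and a manifest", {
  sc <- lhs_scenarios(3, seed = 21)
  ds <- generate_dataset(sc, contact = test_contact(), dt = 5e-6,
                         duration = 0.02, seed = 21)
  expect_s3_class(ds, "impact_dataset")
  expect_equal(nrow(ds$manifest), 3L)
  expect_equal(length(ds$records), 3L)
  expect_true(all(ds$manifest$status == "ok"))
  expect_true(all(c("scenario_id", "param_hash", "seed") %in%
                  names(ds$manifest)))
  # an unphysical parameter set is recorded as failed, not dropped
  bad <- contact_params(liner_stiffness = 0, liner_damping = 0,
                        liner_hardening = 0, strap_stiffness = 0)
  ds_bad <- generate_dataset(one_scenario(vn = 12, vt = 18),
                             contact = bad, dt = 5e-6, duration = 0.02)
  expect_equal(nrow(ds_bad$manifest), 1L)
  expect_equal(ds_bad$manifest$status, "failed")
  expect_match(ds_bad$manifest$message, "interpenetration")
})

test_that("datasets round-trip through the on-disk format", {
  sc <- lhs_scenarios(2, seed = 33)
  ds <- generate_dataset(sc, contact = test_contact(), dt = 5e-6,
                         duration = 0.02, seed = 33)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back$records), 2L)
  r0 <- ds$records[["1"]]
  r1 <- back$records[["1"]]
  expect_equal(r1$helmet, r0$helmet, tolerance = 1e-12)
  expect_equal(r1$head_rot, r0$head_rot, tolerance = 1e-12)
  expect_equal(r1$dt, r0$dt)
  expect_equal(r1$scenario$beta_deg, r0$scenario$beta_deg)
})

test_that("attenuation diagnostics are present and positive", {
  rec <- quick_record(one_scenario())
  expect_gt(attenuation_ratio(rec), 1)
})
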