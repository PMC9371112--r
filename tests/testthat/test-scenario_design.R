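strata_counts <- function(values, range, n_bins, shape = NULL) {
  u <- (values - range[1]) / (range[2] - range[1])
  p <- if (!is.null(shape) && shape$kind == "u_shaped") {
    helmetkin:::p_ushaped(u, shape$tail_to_center_ratio)
  } else {
    u
  }
  tabulate(pmin(floor(p * n_bins) + 1L, n_bins), n_bins)
}

test_that("each parameter gets exactly one sample per equal-probability stratum", {
  ranges <- param_ranges()
  shapes <- default_shapes()
  for (n in c(1L, 10L, 100L)) {
    sc <- lhs_scenarios(n, ranges, shapes, seed = 5)
    expect_equal(nrow(sc), n)
    validate_scenarios(sc, ranges)
    for (nm in names(unclass(ranges))) {
      counts <- strata_counts(sc[[nm]], ranges[[nm]], n, shapes[[nm]])
      expect_equal(counts, rep(1L, n), info = sprintf("%s, n=%d", nm, n))
    }
  }
})

test_that("uniform marginals give exact equal-width bin counts", {
  sc <- lhs_scenarios(100, shapes = default_shapes(u_angles = FALSE),
                      seed = 3)
  counts <- strata_counts(sc$beta_deg, c(-100, 100), 10)
  expect_equal(counts, rep(10L, 10))
})

test_that("u-shaped marginals stay in range and thin the center", {
  sc <- lhs_scenarios(2000, seed = 17)
  expect_true(all(sc$beta_deg >= -100 & sc$beta_deg <= 100))
  expect_true(all(sc$gamma_deg >= -125 & sc$gamma_deg <= 115))
  # per-width frequency near the center below that near the range ends
  center <- mean(sc$beta_deg >= -20 & sc$beta_deg <= 20) / 40
  tail_hi <- mean(sc$beta_deg >= 60 & sc$beta_deg <= 100) / 40
  expect_lt(center, tail_hi)
})

test_that("sampling is deterministic under seed and varies across seeds", {
  a <- lhs_scenarios(50, seed = 123)
  b <- lhs_scenarios(50, seed = 123)
  c <- lhs_scenarios(50, seed = 124)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$beta_deg, c$beta_deg)))
})

test_that("u-shaped quantile function inverts its CDF", {
  p <- seq(0.001, 0.999, length.out = 201)
  for (r in c(1.5, 3, 10)) {
    q <- helmetkin:::q_ushaped(p, r)
    expect_equal(helmetkin:::p_ushaped(q, r), p, tolerance = 1e-10)
    expect_true(all(q >= 0 & q <= 1))
  }
  expect_error(marginal_shape("u_shaped", 1), "must be > 1")
  expect_error(lhs_scenarios(0), "positive integer")
})

test_that("speed_vector has the stated components and magnitude", {
  v <- speed_vector(one_scenario(vn = 2, vt = 3, theta = 0))
  expect_equal(v, c(3, 0, -2))
  expect_equal(sqrt(sum(v^2)), 3.606, tolerance = 1e-3)
  v2 <- speed_vector(one_scenario(vn = 12, vt = 18, theta = 137))
  expect_equal(sqrt(sum(v2^2)), 21.63, tolerance = 1e-3)  # ~ 77.9 km/h
  expect_equal(-v2[3], 12)                                # normal component
  expect_equal(sqrt(sum(v2[1:2]^2)), 18)                  # tangential
  expect_error(speed_vector(one_scenario(vn = 5, vt = 0)), "vt > 0")
})

test_that("ground orientation is sequential X-then-Y and non-commutative", {
  expect_equal(ground_orientation(one_scenario(beta = 0, gamma = 0)),
               diag(3))
  # beta = 90 deg maps the ground normal onto the head's lateral axis
  R <- ground_orientation(one_scenario(beta = 90, gamma = 0))
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(0, -1, 0), tolerance = 1e-12)
  R1 <- ground_orientation(one_scenario(beta = 45, gamma = 45))
  R2 <- helmetkin:::rot_y(pi / 4) %*% helmetkin:::rot_x(pi / 4)
  expect_false(isTRUE(all.equal(R1, R2)))
})

test_that("scenario tables round-trip through CSV", {
  sc <- lhs_scenarios(8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenarios(sc, path)
  back <- read_scenarios(path)
  expect_equal(as.data.frame(back), as.data.frame(sc), tolerance = 1e-12)
})
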