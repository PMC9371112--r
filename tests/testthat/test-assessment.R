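test_that("r_squared is the squared Pearson correlation", {
  t <- c(1, 2, 3, 4)
  expect_equal(r_squared(t, t), 1.0)
  expect_equal(r_squared(t, 2 * t + 5), 1.0)
  e <- c(1, 2, 3, 8)
  expect_equal(r_squared(t, e), stats::cor(t, e)^2)
  # hand computation for the same pair
  expect_equal(r_squared(t, e), 121 / 145, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:2, 1:2), ">= 3")
})

test_that("exclusion rule keeps records at or below the target threshold", {
  m <- tibble::tibble(scenario_id = 1:4,
                      peak_rot = c(30, 45, 39, 41) * 1000)
  kept <- apply_exclusion(m, 40000)
  expect_equal(kept$peak_rot, c(30000, 39000))
  expect_equal(attr(kept, "n_excluded"), 2L)
  all_kept <- apply_exclusion(m, Inf)
  expect_equal(nrow(all_kept), 4L)
  expect_equal(attr(all_kept, "n_excluded"), 0L)
  expect_warning(apply_exclusion(m, 0), "every record")
})

test_that("per-quantity tables give R^2 = 1 for a verbatim estimator", {
  set.seed(31)
  tm <- tibble::tibble(
    scenario_id = 1:20,
    peak_ax = rnorm(20), peak_ay = rnorm(20), peak_az = rnorm(20),
    peak_lin = abs(rnorm(20)) + 1,
    peak_rx = rnorm(20), peak_ry = rnorm(20), peak_rz = rnorm(20),
    peak_rot = abs(rnorm(20)) * 1e4 + 1e3,
    hic = abs(rnorm(20)) * 100, ric = abs(rnorm(20)) * 1e5
  )
  tab <- helmetkin:::assessment_table(tm, tm)
  expect_equal(tab$r_squared, rep(1, 10))
  expect_equal(tab$slope, rep(1, 10))
  expect_equal(tab$intercept, rep(0, 10), tolerance = 1e-10)
  expect_equal(tab$network, rep(c("A", "B"), each = 5))
  # shuffled estimates decorrelate
  em <- tm[sample(20), ]
  em$scenario_id <- tm$scenario_id
  tab2 <- helmetkin:::assessment_table(tm, em)
  expect_lt(max(tab2$r_squared), 0.5)
})

test_that("assessment refuses records that appear in a training manifest", {
  stub <- function(target, ids) {
    structure(list(target = target, train_ids = ids),
              class = c("trained_estimator", "dann_estimator"))
  }
  recs <- list(
    helmetkin:::new_impact_record(
      time = (0:19) * 1e-3, helmet = matrix(rnorm(240), 12),
      head_lin = matrix(rnorm(60), 3), head_rot = matrix(rnorm(60), 3),
      scenario = tibble::tibble(scenario_id = 7L), dt = 1e-3)
  )
  expect_error(
    assess(recs, stub("linear", c(5, 7)), stub("rotational", c(5, 6))),
    "overlaps the training manifest")
  expect_error(
    assess(recs, stub("rotational", 1), stub("rotational", 2)),
    "linear network")
})

test_that("assessment end-to-end on learnable synthetic records", {
  train <- make_synth_records(24, seed = 301)
  val <- make_synth_records(6, seed = 302)
  test <- make_synth_records(12, seed = 303, id0 = 2000L)
  cfg <- tiny_config(lr_init = 0.02, max_epochs = 200, patience = 200,
                     seed = 304)
  pair <- fit_pair(train, val, config = cfg)
  rep <- assess(test, pair$A, pair$B, exclusion_threshold = Inf)
  expect_s3_class(rep, "assessment_report")
  expect_equal(rep$n_records, 12L)
  expect_equal(rep$n_excluded, 0L)
  expect_true(all(rep$full$r_squared >= 0 & rep$full$r_squared <= 1))
  # the component mixtures are learnable: windowed severity metrics, which
  # integrate the whole history, correlate near-perfectly; peaks of
  # near-noise fixtures have little across-record variance, so only a loose
  # bound is meaningful there
  expect_gt(rep$full$r_squared[rep$full$quantity == "hic"], 0.95)
  expect_gt(rep$full$r_squared[rep$full$quantity == "ric"], 0.95)
  lin_r2 <- rep$full$r_squared[rep$full$quantity == "peak_lin"]
  expect_gt(lin_r2, 0.5)
  # tidy/glance carry the headline values
  td <- tidy(rep)
  expect_equal(nrow(td), 20L)
  gl <- glance(rep)
  expect_equal(gl$r2_peak_lin, lin_r2)
  # report round trip
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$summary$r2_peak_lin, gl$r2_peak_lin, tolerance = 1e-12)
  expect_equal(nrow(back$r_squared), 20L)
})
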