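test_that("BPTT gradients agree with central finite differences", {
  set.seed(5)
  cfg <- estimator_config(
    layers = list(list(type = "blstm", units = 3L),
                  list(type = "lstm", units = 4L),
                  list(type = "fc", units = 5L),
                  list(type = "fc", units = 3L)),
    dropout_p = 0, seed = 3)
  est <- build_estimator(cfg, n_inputs = 2L)
  X <- array(rnorm(2 * 3 * 6), c(2, 3, 6))
  Y <- array(rnorm(3 * 3 * 6), c(3, 3, 6))
  g <- helmetkin:::cpp_dann_grad(est$params, est$types, X, Y, 0, 1)
  eps <- 1e-5
  for (li in seq_along(est$params)) {
    for (nm in names(est$params[[li]])) {
      P <- est$params
      w <- P[[li]][[nm]]
      for (k in sample(length(w), min(5, length(w)))) {
        P[[li]][[nm]][k] <- w[k] + eps
        lp <- helmetkin:::cpp_dann_grad(P, est$types, X, Y, 0, 1)$loss
        P[[li]][[nm]][k] <- w[k] - eps
        lm <- helmetkin:::cpp_dann_grad(P, est$types, X, Y, 0, 1)$loss
        P[[li]][[nm]][k] <- w[k]
        fd <- (lp - lm) / (2 * eps)
        an <- g$grads[[li]][[nm]][k]
        expect_lt(abs(fd - an) / max(1e-5, abs(fd), abs(an)), 1e-4)
      }
    }
  }
})

test_that("configs validate their layer lists and express deep variants", {
  expect_error(estimator_config(layers = list(list(type = "fc", units = 7L))),
               "3 units")
  expect_error(estimator_config(layers = list(list(type = "conv", units = 4),
                                              list(type = "fc", units = 3L))),
               "malformed")
  # the standard stack and the 4-LSTM + 2-FC variant are both expressible
  std <- dann_architecture(200)
  expect_equal(vapply(std, `[[`, "", "type"),
               c("blstm", "lstm", "lstm", "fc", "fc"))
  deep <- dann_architecture(200, n_blstm = 0, n_lstm = 4)
  expect_equal(vapply(deep, `[[`, "", "type"),
               c(rep("lstm", 4), "fc", "fc"))
  est <- build_estimator(estimator_config(layers = deep, seed = 1))
  expect_gt(est$n_params, 0)
})

test_that("building is deterministic under seed, and inference has no noise", {
  cfg <- tiny_config(seed = 7)
  a <- build_estimator(cfg)
  b <- build_estimator(cfg)
  expect_identical(a$params, b$params)
  X <- array(rnorm(12 * 2 * 15), c(12, 2, 15))
  expect_identical(helmetkin:::cpp_dann_forward(a$params, a$types, X),
                   helmetkin:::cpp_dann_forward(b$params, b$types, X))
})

test_that("a tiny network overfits a single record", {
  recs <- make_synth_records(1, T = 30L)
  cfg <- tiny_config(lr_init = 0.005, max_epochs = 200, patience = 200,
                     seed = 11)
  fit <- train_estimator(cfg, recs, recs, target = "linear")
  log <- tidy(fit)
  expect_lt(log$train_loss[nrow(log)], 0.01 * log$train_loss[1])
})

test_that("an identity mapping is learned almost perfectly on held-out data", {
  train <- make_synth_records(24, seed = 1)
  val <- make_synth_records(6, seed = 2)
  test <- make_synth_records(6, seed = 3)
  cfg <- tiny_config(lr_init = 0.01, max_epochs = 120, patience = 120,
                     seed = 4)
  fit <- train_estimator(cfg, train, val, target = "linear")
  pred <- predict(fit, test)
  y <- unlist(lapply(test, function(r) r$head_lin))
  yhat <- unlist(pred)
  expect_gt(stats::cor(y, yhat)^2, 0.99)
})

test_that("the bidirectional layer exploits future context a causal stack cannot", {
  # target at t is the input at t + 1: the backward pass sees it, a causal
  # stack can at best exploit the input autocorrelation
  train <- make_synth_records(32, shift = 1L, seed = 5)
  val <- make_synth_records(8, shift = 1L, seed = 6)
  blstm_cfg <- estimator_config(
    layers = list(list(type = "blstm", units = 16L),
                  list(type = "fc", units = 3L)),
    dropout_p = 0, batch_size = 8, lr_init = 0.02, lr_drop_every = 100,
    max_epochs = 250, patience = 250, seed = 8)
  causal_cfg <- estimator_config(
    layers = list(list(type = "lstm", units = 16L),
                  list(type = "fc", units = 3L)),
    dropout_p = 0, batch_size = 8, lr_init = 0.02, lr_drop_every = 100,
    max_epochs = 250, patience = 250, seed = 8)
  fit_b <- train_estimator(blstm_cfg, train, val, target = "linear")
  fit_c <- train_estimator(causal_cfg, train, val, target = "linear")
  expect_gt(fit_c$best_val_rmse / fit_b$best_val_rmse, 2)
})

test_that("learning-rate schedule halves every 45 epochs from the start value", {
  expect_equal(lr_schedule(1), 0.001)
  expect_equal(lr_schedule(45), 0.001)
  expect_equal(lr_schedule(46), 0.001 / 2)
  expect_equal(lr_schedule(90), 0.001 / 2)
  expect_equal(lr_schedule(91), 0.001 / 4)
  expect_equal(lr_schedule(10, lr_init = 0.1, factor = 10, every = 3), 1e-4)
})

test_that("early stopping fires after exactly `patience` non-improving epochs", {
  # constructed sequence: improves until epoch 4, then flat
  v <- c(1, 0.8, 0.6, 0.5, rep(0.55, 50))
  expect_equal(stopping_epoch(v, patience = 30), 34)
  expect_equal(stopping_epoch(v, patience = 0), 5)
  expect_equal(stopping_epoch(v, patience = 3), 7)
  expect_equal(stopping_epoch(c(3, 2, 1), patience = 5), 3)
  # the trainer stops exactly where the rule applied to its own validation
  # trace says it should; an aggressive learning rate makes the validation
  # error bounce so the rule fires well before max_epochs
  recs <- make_synth_records(10, seed = 12, noise = 2)
  cfg <- tiny_config(lr_init = 0.05, max_epochs = 80, patience = 2, seed = 2)
  fit <- train_estimator(cfg, recs[1:8], recs[9:10], target = "linear")
  log <- tidy(fit)
  expect_equal(nrow(log), stopping_epoch(log$val_rmse, 2))
  expect_lt(nrow(log), 80)
  # the restored weights are the best-validation ones
  expect_equal(fit$best_val_rmse, min(log$val_rmse))
})

test_that("training is reproducible under the configuration seed", {
  recs <- make_synth_records(10, seed = 20)
  cfg <- tiny_config(lr_init = 0.005, max_epochs = 5, patience = 5, seed = 31)
  a <- train_estimator(cfg, recs[1:8], recs[9:10], target = "linear")
  b <- train_estimator(cfg, recs[1:8], recs[9:10], target = "linear")
  expect_equal(tidy(a)$train_loss, tidy(b)$train_loss, tolerance = 1e-6)
  expect_equal(tidy(a)$val_rmse, tidy(b)$val_rmse, tolerance = 1e-6)
})

test_that("normalization round-trips and shapes/units are respected", {
  recs <- make_synth_records(6, seed = 40)
  X <- as_sequence_array(recs, "helmet")
  Y <- as_sequence_array(recs, "head_lin")
  norm <- helmetkin:::normalization_stats(X, Y)
  Xn <- helmetkin:::normalize_inputs(X, norm)
  back <- Xn * array(norm$x_sd, dim(X)) + array(norm$x_mean, dim(X))
  expect_equal(back, X, tolerance = 1e-12)
  cfg <- tiny_config(max_epochs = 2, patience = 2, seed = 3)
  fit <- train_estimator(cfg, recs[1:4], recs[5:6], target = "linear")
  p <- predict(fit, recs[[1]])
  expect_equal(dim(p), c(3L, 40L))
  expect_error(predict(fit, matrix(0, 5, 40)), "channels")
})

test_that("fit_pair trains two identical architectures on the two targets", {
  recs <- make_synth_records(8, seed = 50)
  pair <- fit_pair(recs[1:6], recs[7:8],
                   config = tiny_config(max_epochs = 3, patience = 3,
                                        seed = 13))
  expect_equal(pair$A$target, "linear")
  expect_equal(pair$B$target, "rotational")
  expect_equal(pair$A$types, pair$B$types)
  expect_equal(pair$A$n_params, pair$B$n_params)
  # rotational targets are 0.5 x linear in the fixture: scales differ
  expect_equal(pair$B$norm$y_scale, 0.5 * pair$A$norm$y_scale,
               tolerance = 1e-10)
})

test_that("checkpoints round-trip through the JSON archive", {
  recs <- make_synth_records(6, seed = 60)
  cfg <- tiny_config(max_epochs = 2, patience = 2, seed = 17)
  fit <- train_estimator(cfg, recs[1:4], recs[5:6], target = "rotational")
  path <- withr::local_tempfile(fileext = ".json")
  save_estimator(fit, path)
  back <- load_estimator(path)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(back$norm, fit$norm, tolerance = 1e-12)
  expect_equal(back$target, fit$target)
  expect_equal(back$train_ids, fit$train_ids)
  p1 <- predict(fit, recs[[1]])
  p2 <- predict(back, recs[[1]])
  expect_equal(p2, p1, tolerance = 1e-10)
})
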