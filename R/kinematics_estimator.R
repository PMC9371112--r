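#' Estimator architecture and training configuration
#'
#' Describes the sequence-to-sequence network mapping the 12 helmet channels
#' to 3 head acceleration components, and its training protocol: RMSprop
#' over mini-batches, validation-RMSE early stopping, and a stepwise
#' learning-rate drop schedule.
#'
#' @param layers List of layers, each `list(type =, units =)` with type in
#'   `"blstm"`, `"lstm"`, `"fc"`. The last layer must be `fc` with 3 units.
#'   See [dann_architecture()] for the default stack.
#' @param dropout_p Dropout probability on non-recurrent connections
#'   (between layers), in `[0, 1)`.
#' @param lr_init Initial learning rate.
#' @param lr_drop_factor Learning rate divided by this factor every
#'   `lr_drop_every` epochs (default: halved every 45).
#' @param lr_drop_every Epoch period of the learning-rate drop.
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Maximum training epochs (default 1000).
#' @param patience Consecutive non-improving validation epochs before
#'   stopping (default 30).
#' @param rho,epsilon RMSprop squared-gradient smoothing constant and
#'   stabilizer.
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout.
#' @return List of class `estimator_config`.
#' @export
estimator_config <- function(layers = dann_architecture(),
                             dropout_p = 0.5,
                             lr_init = 0.001,
                             lr_drop_factor = 2,
                             lr_drop_every = 45,
                             batch_size = 16,
                             max_epochs = 1000,
                             patience = 30,
                             rho = 0.99,
                             epsilon = 1e-8,
                             seed = 1L) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            dropout_p >= 0, dropout_p < 1,
            lr_init > 0, lr_drop_factor > 0, lr_drop_every >= 1,
            batch_size >= 1, max_epochs >= 1, patience >= 0,
            rho > 0, rho < 1, epsilon > 0)
  for (l in layers) {
    if (!is.list(l) || !l$type %in% c("blstm", "lstm", "fc") || l$units < 1) {
      rlang::abort("malformed layer list")
    }
  }
  last <- layers[[length(layers)]]
  if (last$type != "fc" || last$units != 3L) {
    rlang::abort("last layer must be fully-connected with 3 units")
  }
  structure(
    list(layers = layers, dropout_p = dropout_p, lr_init = lr_init,
         lr_drop_factor = lr_drop_factor, lr_drop_every = lr_drop_every,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), rho = rho, epsilon = epsilon,
         seed = as.integer(seed), loss = "mse"),
    class = "estimator_config"
  )
}

#' Standard deep architecture
#'
#' One bidirectional LSTM layer, `n_lstm` unidirectional LSTM layers and two
#' fully connected layers; recurrent layers and the first FC layer share the
#' same unit count (200 by default), the last FC layer has 3 units (one per
#' acceleration component).
#'
#' @param hidden Units per recurrent / first FC layer.
#' @param n_blstm,n_lstm Number of bidirectional and unidirectional LSTM
#'   layers.
#' @return Layer list for [estimator_config()].
#' @export
dann_architecture <- function(hidden = 200, n_blstm = 1, n_lstm = 2) {
  c(
    replicate(n_blstm, list(type = "blstm", units = hidden), simplify = FALSE),
    replicate(n_lstm, list(type = "lstm", units = hidden), simplify = FALSE),
    list(list(type = "fc", units = hidden), list(type = "fc", units = 3L))
  )
}

# layer output widths given input width (blstm concatenates both passes)
layer_dims <- function(layers, n_inputs) {
  dims <- integer(length(layers))
  cur <- n_inputs
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    dims[i] <- switch(l$type, blstm = 2L * l$units, lstm = l$units,
                      fc = l$units)
    cur <- dims[i]
  }
  dims
}

init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nc)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_lstm <- function(units, n_in) {
  W <- init_mat(4L * units, n_in + units)
  b <- rep(0, 4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget-gate bias at 1
  list(W = W, b = b)
}

#' Build an untrained estimator
#'
#' Initializes the weight set for a configuration, deterministically under
#' the configuration seed.
#'
#' @param config An [estimator_config()].
#' @param n_inputs Number of input channels (12 helmet channels).
#' @return List of class `dann_estimator` with `config`, `params`, `types`
#'   and `n_params`.
#' @export
build_estimator <- function(config, n_inputs = 12L) {
  stopifnot(inherits(config, "estimator_config"))
  set.seed(config$seed)
  layers <- config$layers
  dims <- layer_dims(layers, n_inputs)
  n_in <- n_inputs
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    params[[i]] <- switch(
      l$type,
      lstm = init_lstm(l$units, n_in),
      blstm = {
        f <- init_lstm(l$units, n_in)
        b <- init_lstm(l$units, n_in)
        list(Wf = f$W, bf = f$b, Wb = b$W, bb = b$b)
      },
      fc = list(W = init_mat(l$units, n_in), b = rep(0, l$units))
    )
    n_in <- dims[i]
  }
  structure(
    list(config = config, params = params,
         types = vapply(layers, `[[`, "", "type"),
         n_inputs = as.integer(n_inputs),
         n_params = sum(vapply(params, function(p)
           sum(vapply(p, length, 1L)), 1L))),
    class = "dann_estimator"
  )
}

#' Stack impact records into a sequence array
#'
#' @param records `impact_dataset` or list of records (equal length, equal
#'   channel layout).
#' @param what `"helmet"`, `"head_lin"` or `"head_rot"`.
#' @return Numeric array `channels x n_records x T`.
#' @export
as_sequence_array <- function(records, what = c("helmet", "head_lin",
                                                "head_rot")) {
  what <- match.arg(what)
  recs <- as_record_list(records)
  Ts <- unique(purrr::map_int(recs, ~ length(.x$time)))
  if (length(Ts) != 1L) rlang::abort("records must share the same length")
  mats <- purrr::map(recs, what)
  nch <- nrow(mats[[1L]])
  arr <- array(0, dim = c(nch, length(recs), Ts))
  for (i in seq_along(mats)) arr[, i, ] <- mats[[i]]
  arr
}

# z-score inputs per channel; scale outputs per component by training sd
normalization_stats <- function(X, Y) {
  x_mean <- apply(X, 1L, mean)
  x_sd <- apply(X, 1L, stats::sd)
  y_scale <- apply(Y, 1L, stats::sd)
  if (any(x_sd <= 0) || any(y_scale <= 0)) {
    rlang::abort("degenerate (constant) channel in training data")
  }
  list(x_mean = x_mean, x_sd = x_sd, y_scale = y_scale)
}

normalize_inputs <- function(X, norm) {
  (X - array(norm$x_mean, dim(X))) / array(norm$x_sd, dim(X))
}

#' Learning-rate schedule
#'
#' Stepwise drop: the initial rate is divided by `factor` every `every`
#' epochs, so with the defaults epochs 1-45 use `lr_init`, epochs 46-90 use
#' `lr_init / 2`, epochs 91-135 use `lr_init / 4`, and so on.
#'
#' @param epoch Epoch number (1-based); vectorized.
#' @param lr_init Initial learning rate.
#' @param factor Drop factor.
#' @param every Epoch period.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, lr_init = 0.001, factor = 2, every = 45) {
  lr_init / factor^((epoch - 1) %/% every)
}

#' Early-stopping epoch for a validation-error sequence
#'
#' Training stops at the first epoch ending a run of `patience` consecutive
#' epochs without strict improvement over the best validation RMSE so far
#' (with `patience = 0`, at the first non-improving epoch).
#'
#' @param val_rmse Per-epoch validation RMSE sequence.
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @return The stopping epoch, or `length(val_rmse)` if the rule never
#'   fires.
#' @export
stopping_epoch <- function(val_rmse, patience) {
  best <- Inf
  streak <- 0L
  limit <- max(patience, 1L)
  for (e in seq_along(val_rmse)) {
    if (val_rmse[e] < best) {
      best <- val_rmse[e]
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= limit) return(e)
    }
  }
  length(val_rmse)
}

rmsprop_update <- function(params, grads, cache, lr, rho, eps) {
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      cache[[i]][[nm]] <- rho * cache[[i]][[nm]] + (1 - rho) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * g / (sqrt(cache[[i]][[nm]]) + eps)
    }
  }
  list(params = params, cache = cache)
}

#' Train a sequence-to-sequence estimator
#'
#' Optimizes the network weights by back-propagation through time with
#' RMSprop over mini-batches, monitoring validation RMSE after each epoch.
#' Training stops at `max_epochs` or when validation RMSE has not improved
#' for `patience` consecutive epochs; the best-validation weights are
#' restored. The learning rate follows [lr_schedule()].
#'
#' @param estimator A [build_estimator()] result (or an
#'   [estimator_config()], which is built first).
#' @param train,val Training and validation `impact_dataset`s (or record
#'   lists).
#' @param target `"linear"` (head CoG linear acceleration, m/s^2) or
#'   `"rotational"` (head rotational acceleration, rad/s^2).
#' @param verbose Print per-epoch progress.
#' @return List of class `trained_estimator`: the estimator plus `norm`
#'   (normalization statistics), `training_log` tibble (epoch, train_loss,
#'   val_rmse, lr), `target`, `train_ids`.
#' @export
train_estimator <- function(estimator, train, val,
                            target = c("linear", "rotational"),
                            verbose = FALSE) {
  target <- match.arg(target)
  if (inherits(estimator, "estimator_config")) {
    estimator <- build_estimator(estimator)
  }
  stopifnot(inherits(estimator, "dann_estimator"))
  cfg <- estimator$config
  what <- if (target == "linear") "head_lin" else "head_rot"
  Xtr <- as_sequence_array(train, "helmet")
  Ytr <- as_sequence_array(train, what)
  Xva <- as_sequence_array(val, "helmet")
  Yva <- as_sequence_array(val, what)
  if (dim(Xtr)[1] != estimator$n_inputs) {
    rlang::abort("channel count does not match the estimator inputs")
  }
  norm <- normalization_stats(Xtr, Ytr)
  Xtr <- normalize_inputs(Xtr, norm)
  Xva <- normalize_inputs(Xva, norm)
  Ytr <- Ytr / array(norm$y_scale, dim(Ytr))
  Yva <- Yva / array(norm$y_scale, dim(Yva))

  n <- dim(Xtr)[2]
  params <- estimator$params
  cache <- purrr::map(params, ~ purrr::map(.x, ~ .x * 0))
  set.seed(cfg$seed)
  log_rows <- vector("list", cfg$max_epochs)
  best_rmse <- Inf
  best_params <- params
  best_epoch <- 0L
  streak <- 0L
  limit <- max(cfg$patience, 1L)

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch, cfg$lr_init, cfg$lr_drop_factor,
                      cfg$lr_drop_every)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      gb <- cpp_dann_grad(params, estimator$types,
                          Xtr[, idx, , drop = FALSE],
                          Ytr[, idx, , drop = FALSE],
                          cfg$dropout_p,
                          stats::runif(1) * 2^31)
      losses[bi] <- gb$loss
      upd <- rmsprop_update(params, gb$grads, cache, lr, cfg$rho,
                            cfg$epsilon)
      params <- upd$params
      cache <- upd$cache
    }
    pred_va <- cpp_dann_forward(params, estimator$types, Xva)
    val_rmse <- sqrt(mean((pred_va - Yva)^2))
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_rmse = val_rmse, lr = lr)
    if (verbose) {
      message(sprintf("epoch %4d  loss %.5f  val RMSE %.5f  lr %.2e",
                      epoch, mean(losses), val_rmse, lr))
    }
    if (val_rmse < best_rmse) {
      best_rmse <- val_rmse
      best_params <- params
      best_epoch <- epoch
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= limit) break
    }
  }

  structure(
    list(config = cfg, params = best_params, types = estimator$types,
         n_inputs = estimator$n_inputs, n_params = estimator$n_params,
         norm = norm, target = target,
         training_log = dplyr::bind_rows(purrr::compact(log_rows)),
         best_epoch = best_epoch, best_val_rmse = best_rmse,
         train_ids = record_ids(train)),
    class = c("trained_estimator", "dann_estimator")
  )
}

record_ids <- function(records) {
  purrr::map_dbl(as_record_list(records), ~ .x$scenario$scenario_id)
}

#' Predict head acceleration time histories
#'
#' @param object A `trained_estimator`.
#' @param newdata An `impact_record`, a 12 x T channel matrix, or an
#'   `impact_dataset` / record list.
#' @param ... Unused.
#' @return For a single record or matrix, a 3 x T matrix in physical units
#'   (m/s^2 or rad/s^2 according to the training target); for several
#'   records, a list of such matrices.
#' @export
predict.trained_estimator <- function(object, newdata, ...) {
  single <- inherits(newdata, "impact_record") ||
    (is.matrix(newdata) && !is.list(newdata))
  X <- if (is.matrix(newdata)) {
    array(newdata, dim = c(nrow(newdata), 1L, ncol(newdata)))
  } else {
    as_sequence_array(newdata, "helmet")
  }
  if (dim(X)[1] != object$n_inputs) {
    rlang::abort(sprintf("expected %d input channels, got %d",
                         object$n_inputs, dim(X)[1]))
  }
  X <- normalize_inputs(X, object$norm)
  Yn <- cpp_dann_forward(object$params, object$types, X)
  Y <- Yn * array(object$norm$y_scale, dim(Yn))
  if (single) {
    matrix(Y[, 1L, ], nrow = 3L)
  } else {
    purrr::map(seq_len(dim(Y)[2]), ~ matrix(Y[, .x, ], nrow = 3L))
  }
}

#' Train the linear / rotational estimator pair
#'
#' Two separate but identically configured networks: A is trained on the
#' head linear acceleration targets, B on the rotational ones.
#'
#' @param train,val Training and validation datasets carrying both target
#'   blocks.
#' @param config Shared [estimator_config()].
#' @param verbose Passed to [train_estimator()].
#' @return List with elements `A` and `B` (`trained_estimator`s).
#' @export
fit_pair <- function(train, val, config = estimator_config(),
                     verbose = FALSE) {
  list(
    A = train_estimator(config, train, val, target = "linear",
                        verbose = verbose),
    B = train_estimator(config, train, val, target = "rotational",
                        verbose = verbose)
  )
}

#' @export
print.dann_estimator <- function(x, ...) {
  arch <- paste(vapply(x$config$layers, function(l)
    sprintf("%s(%d)", l$type, l$units), ""), collapse = " - ")
  cat("<dann_estimator>", arch, "\n")
  cat("  parameters:", x$n_params, "\n")
  if (inherits(x, "trained_estimator")) {
    cat(sprintf("  target: %s; best val RMSE %.5f at epoch %d/%d\n",
                x$target, x$best_val_rmse, x$best_epoch,
                nrow(x$training_log)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fitted estimator
#'
#' @param x A `trained_estimator`.
#' @param ... Unused.
#' @return Tibble with columns epoch, train_loss, val_rmse, lr.
#' @export
tidy.trained_estimator <- function(x, ...) x$training_log

#' One-row summary of a fitted estimator
#'
#' @param x A `trained_estimator`.
#' @param ... Unused.
#' @return One-row tibble: target, n_params, epochs, best_epoch,
#'   best_val_rmse.
#' @export
glance.trained_estimator <- function(x, ...) {
  tibble::tibble(target = x$target, n_params = x$n_params,
                 epochs = nrow(x$training_log), best_epoch = x$best_epoch,
                 best_val_rmse = x$best_val_rmse)
}

#' Save / load a trained estimator as a self-describing archive
#'
#' Plain-text checkpoint: a JSON file holding the configuration, layer
#' types, normalization statistics and all weight matrices.
#'
#' @param object A `trained_estimator`.
#' @param path File path (`.json`).
#' @return `save_estimator()` returns `path` invisibly; `load_estimator()`
#'   the restored estimator.
#' @export
save_estimator <- function(object, path) {
  stopifnot(inherits(object, "trained_estimator"))
  payload <- list(
    config = unclass(object$config), types = object$types,
    n_inputs = object$n_inputs, n_params = object$n_params,
    norm = object$norm, target = object$target,
    training_log = object$training_log, best_epoch = object$best_epoch,
    best_val_rmse = object$best_val_rmse, train_ids = object$train_ids,
    params = stats::setNames(object$params,
                             paste0("layer", seq_along(object$params)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  cfg <- p$config
  ldf <- cfg$layers   # simplified to a data frame by jsonlite
  cfg$layers <- purrr::map(seq_len(nrow(ldf)), function(i) {
    list(type = ldf$type[i], units = as.integer(ldf$units[i]))
  })
  config <- do.call(estimator_config, cfg[setdiff(names(cfg), "loss")])
  params <- purrr::map(unname(p$params), function(pl) {
    purrr::map(pl, function(m) {
      # column-major matrices come back transposed under row-major reading
      if (is.matrix(m)) t(m) else as.numeric(m)
    })
  })
  structure(
    list(config = config, params = params, types = p$types,
         n_inputs = p$n_inputs, n_params = p$n_params,
         norm = purrr::map(p$norm, as.numeric), target = p$target,
         training_log = tibble::as_tibble(p$training_log),
         best_epoch = p$best_epoch, best_val_rmse = p$best_val_rmse,
         train_ids = as.numeric(p$train_ids)),
    class = c("trained_estimator", "dann_estimator")
  )
}
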