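# Shared fixtures: small, fast simulator settings for unit tests.
# Coarser integration step and patch count than the package defaults;
# still stable, and an order of magnitude faster.

test_contact <- function(...) {
  contact_params(n_liner_patches = 32L, ...)
}

quick_record <- function(scenario, dt = 2e-6, duration = 0.02,
                         dt_out = 5e-5, ...) {
  simulate_impact(scenario, contact = test_contact(),
                  duration = duration, dt = dt, dt_out = dt_out, ...)
}

one_scenario <- function(beta = 0, gamma = 0, vn = 5, vt = 6, theta = 0,
                         id = 1L) {
  tibble::tibble(scenario_id = id, beta_deg = beta, gamma_deg = gamma,
                 vn_ms = vn, vt_ms = vt, theta_deg = theta, seed = 0L)
}

# Exhaustive O(T^2) windowed-severity search used as the independent oracle
# for HIC/RIC: enumerates every sample-aligned window, trapezoid integral
# computed directly per window start.
brute_force_severity <- function(a, time, max_window = Inf) {
  n <- length(a)
  dt <- time[2] - time[1]
  best <- -Inf
  best_t <- c(NA, NA)
  for (i in 1:(n - 1)) {
    # fresh trapezoid integrals from window start i
    ints <- cumsum((a[(i + 1):n] + a[i:(n - 1)]) / 2 * dt)
    for (j in (i + 1):n) {
      width <- time[j] - time[i]
      if (width > max_window + 1e-12) break
      val <- width * max(ints[j - i] / width, 0)^2.5
      if (val > best) {
        best <- val
        best_t <- c(time[i], time[j])
      }
    }
  }
  list(value = best, t1 = best_t[1], t2 = best_t[2])
}

# Synthetic sequence fixtures: 12 smooth channels; targets are fixed
# mixtures of the channels (optionally time-shifted), which a
# sequence-to-sequence network must be able to recover.
make_synth_records <- function(n, T = 40L, shift = 0L, noise = 0,
                               seed = 99L, id0 = 1000L) {
  set.seed(seed)
  target_mix <- matrix(0, 3, 12)
  target_mix[1, 1] <- 1
  target_mix[2, 4] <- 1
  target_mix[3, 7] <- 1
  off <- 10L
  lapply(seq_len(n), function(i) {
    raw <- matrix(rnorm(12 * (T + 2L * off)), 12)
    ch <- t(apply(raw, 1, function(x)
      as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2,
                               circular = TRUE))))
    helmet <- ch[, (off + 1):(off + T), drop = FALSE] * 10
    tgt_src <- ch[, (off + 1 + shift):(off + T + shift), drop = FALSE] * 10
    target <- target_mix %*% tgt_src + noise * matrix(rnorm(3 * T), 3)
    helmetkin:::new_impact_record(
      time = (seq_len(T) - 1) * 1e-3, helmet = helmet,
      head_lin = target, head_rot = 0.5 * target,
      scenario = tibble::tibble(scenario_id = i + id0), dt = 1e-3)
  })
}

tiny_config <- function(..., hidden = 8L) {
  estimator_config(
    layers = list(list(type = "blstm", units = hidden),
                  list(type = "fc", units = 3L)),
    dropout_p = 0, batch_size = 8, ...)
}

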