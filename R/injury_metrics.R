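#' Resultant (Euclidean norm) of a three-component signal
#'
#' Combines the three components of an acceleration time history into the
#' resultant magnitude, sample by sample.
#'
#' @param components Numeric matrix with 3 rows (x, y, z component) and one
#'   column per time sample.
#' @return Numeric vector of length `ncol(components)`.
#' @examples
#' resultant(rbind(3, 4, 0))
#' @export
resultant <- function(components) {
  stopifnot(is.matrix(components), nrow(components) == 3L)
  if (!all(is.finite(components))) {
    rlang::abort("`components` must be finite")
  }
  sqrt(colSums(components^2))
}

#' Peak value of a signal
#'
#' For resultant (non-negative) signals the peak is the maximum; for signed
#' components the peak is the sample of maximum absolute value, reported with
#' its original sign. Ties are broken by the earliest sample.
#'
#' @param signal Numeric vector.
#' @param time Optional time base (same length); if given, the peak time is
#'   reported.
#' @param signed If `TRUE` (components) use the signed abs-max convention;
#'   if `FALSE` (resultants) use the plain maximum.
#' @return A list of class `metric_result` with elements `value` and `t_peak`.
#' @export
peak <- function(signal, time = NULL, signed = TRUE) {
  if (length(signal) == 0L) rlang::abort("`signal` must be non-empty")
  idx <- if (signed) which.max(abs(signal)) else which.max(signal)
  t_peak <- if (is.null(time)) idx else time[idx]
  structure(
    list(value = signal[idx], t_peak = t_peak, index = idx),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat("<metric_result> value =", format(x$value), "\n")
  if (!is.null(x$t1)) {
    cat("  window: [", format(x$t1), ",", format(x$t2), "] s\n")
  } else if (!is.null(x$t_peak)) {
    cat("  at t =", format(x$t_peak), "\n")
  }
  invisible(x)
}

# Shared windowed power-mean maximization behind HIC and RIC.
# value(t1, t2) = (t2 - t1) * (mean of a over [t1, t2])^2.5, mean via
# trapezoidal integration on the uniform grid; maximized over all
# sample-aligned windows with width <= max_window. Negative window means are
# clamped to zero (they cannot maximize a non-negative functional).
# Ties: earliest t1, then shortest window.
windowed_severity <- function(a, time = NULL, dt = NULL, max_window = Inf) {
  n <- length(a)
  if (n < 2L) rlang::abort("signal must have at least 2 samples")
  if (!all(is.finite(a))) rlang::abort("signal must be finite")
  if (is.null(time)) {
    if (is.null(dt) || dt <= 0) rlang::abort("provide `time` or a positive `dt`")
    time <- (seq_len(n) - 1L) * dt
  } else {
    stopifnot(length(time) == n)
    dts <- diff(time)
    dt <- dts[1L]
    if (any(abs(dts - dt) > 1e-9 * max(dt, 1e-12))) {
      rlang::abort("time base must be uniform")
    }
  }
  # cumulative trapezoid: ctrap[k] = integral from time[1] to time[k]
  ctrap <- c(0, cumsum((a[-1L] + a[-n]) / 2) * dt)
  lmax <- min(n - 1L, floor(max_window / dt + 1e-9))
  if (lmax < 1L) rlang::abort("`max_window` shorter than one sample interval")

  best <- -Inf
  best_i <- 1L
  best_l <- 1L
  for (l in seq_len(lmax)) {
    ints <- ctrap[(1L + l):n] - ctrap[1L:(n - l)]
    width <- l * dt
    vals <- width * pmax(ints / width, 0)^2.5
    m <- max(vals)
    if (m > best) {
      best <- m
      best_i <- which.max(vals)
      best_l <- l
    } else if (m == best) {
      i <- which.max(vals)
      if (i < best_i) {
        best_i <- i
        best_l <- l
      }
    }
  }
  structure(
    list(
      value = best,
      t1 = time[best_i],
      t2 = time[best_i + best_l],
      i1 = best_i,
      i2 = best_i + best_l
    ),
    class = "metric_result"
  )
}

#' Head Injury Criterion (HIC)
#'
#' Maximizes \eqn{(t_2 - t_1)\,[\frac{1}{t_2-t_1}\int_{t_1}^{t_2} a(t)\,dt]^{2.5}}
#' over all sample-aligned windows of the resultant linear acceleration, with
#' an optional bound on the window width (`max_window = 0.015` gives HIC15).
#'
#' @param lin_resultant Resultant linear acceleration in g, on a uniform time
#'   base.
#' @param time Time vector in seconds (uniform), or `NULL` if `dt` is given.
#' @param dt Sample interval in seconds (used when `time` is `NULL`).
#' @param max_window Maximum window width \eqn{t_2 - t_1} in seconds
#'   (default unbounded).
#' @return `metric_result` with `value` (dimensionless) and the maximizing
#'   window `t1`, `t2`.
#' @examples
#' # constant 50 g for 10 ms: HIC = 50^2.5 * 0.010
#' hic(rep(50, 101), dt = 1e-4)$value
#' @export
hic <- function(lin_resultant, time = NULL, dt = NULL, max_window = Inf) {
  windowed_severity(lin_resultant, time = time, dt = dt, max_window = max_window)
}

#' Rotational Injury Criterion (RIC)
#'
#' The HIC-analogue computed on the resultant rotational (angular)
#' acceleration in rad/s^2; same windowed maximization as [hic()].
#'
#' @param rot_resultant Resultant rotational acceleration in rad/s^2.
#' @inheritParams hic
#' @return `metric_result` with `value` and the maximizing window.
#' @export
ric <- function(rot_resultant, time = NULL, dt = NULL, max_window = Inf) {
  windowed_severity(rot_resultant, time = time, dt = dt, max_window = max_window)
}

#' Convert linear acceleration from m/s^2 to g
#'
#' @param a_ms2 Acceleration in m/s^2.
#' @return Acceleration in g (standard gravity 9.80665 m/s^2).
#' @export
to_g <- function(a_ms2) a_ms2 / 9.80665

#' Per-record injury metric table
#'
#' Computes, for each impact record, the signed component peaks, resultant
#' peaks, HIC (on the linear resultant, in g) and RIC (on the rotational
#' resultant, in rad/s^2), from the head ground-truth channels.
#'
#' @param records An `impact_dataset` or a list of `impact_record` objects.
#' @param max_window Window bound passed to [hic()] and [ric()].
#' @return A tibble with one row per record: `scenario_id`, `peak_ax`,
#'   `peak_ay`, `peak_az` (m/s^2, signed), `peak_lin` (m/s^2),
#'   `peak_rot` (rad/s^2), `hic`, `ric`.
#' @export
injury_metrics <- function(records, max_window = Inf) {
  recs <- as_record_list(records)
  purrr::map_dfr(recs, function(r) {
    metric_row(r$head_lin, r$head_rot, r$time, r$scenario$scenario_id,
               max_window = max_window)
  })
}

# One metric row from a pair of 3 x T head signal blocks.
metric_row <- function(head_lin, head_rot, time, scenario_id, max_window = Inf) {
  lin_res <- resultant(head_lin)
  rot_res <- resultant(head_rot)
  tibble::tibble(
    scenario_id = scenario_id,
    peak_ax = peak(head_lin[1L, ])$value,
    peak_ay = peak(head_lin[2L, ])$value,
    peak_az = peak(head_lin[3L, ])$value,
    peak_lin = peak(lin_res, signed = FALSE)$value,
    peak_rx = peak(head_rot[1L, ])$value,
    peak_ry = peak(head_rot[2L, ])$value,
    peak_rz = peak(head_rot[3L, ])$value,
    peak_rot = peak(rot_res, signed = FALSE)$value,
    hic = hic(to_g(lin_res), time = time, max_window = max_window)$value,
    ric = ric(rot_res, time = time, max_window = max_window)$value
  )
}
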