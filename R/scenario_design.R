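#' Parameter ranges for impact scenarios
#'
#' The five-parameter impact-scenario space: two ground-orientation angles
#' (beta about the X-axis, gamma about the Y-axis), the normal and tangential
#' impact speed components, and the in-plane orientation of the tangential
#' component.
#'
#' @param beta_deg,gamma_deg Closed angle intervals in degrees.
#' @param vn_ms,vt_ms Closed speed intervals in m/s.
#' @param theta_deg Half-open interval in degrees (default `[0, 360)`).
#' @return A list of class `param_ranges`.
#' @export
param_ranges <- function(beta_deg = c(-100, 100),
                         gamma_deg = c(-125, 115),
                         vn_ms = c(2, 12),
                         vt_ms = c(3, 18),
                         theta_deg = c(0, 360)) {
  rr <- list(beta_deg = beta_deg, gamma_deg = gamma_deg,
             vn_ms = vn_ms, vt_ms = vt_ms, theta_deg = theta_deg)
  for (nm in names(rr)) {
    r <- rr[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1]) {
      rlang::abort(sprintf("range `%s` must be a non-degenerate interval", nm))
    }
  }
  structure(rr, class = "param_ranges")
}

#' Marginal shape for one scenario parameter
#'
#' Either `uniform`, or `u_shaped`: a symmetric piecewise-linear density with
#' value proportional to `tail_to_center_ratio` at the interval ends and 1 at
#' the center. U-shaped orientation-angle marginals push sampled impacts away
#' from the crown and toward the lateral, rear and chin regions of the shell,
#' giving uniform spatial coverage.
#'
#' @param kind `"uniform"` or `"u_shaped"`.
#' @param tail_to_center_ratio Density at the range ends divided by density
#'   at the center; must exceed 1 for `u_shaped`.
#' @return A list of class `marginal_shape`.
#' @export
marginal_shape <- function(kind = c("uniform", "u_shaped"),
                           tail_to_center_ratio = 3) {
  kind <- match.arg(kind)
  if (kind == "u_shaped" && tail_to_center_ratio <= 1) {
    rlang::abort("`tail_to_center_ratio` must be > 1 for u_shaped marginals")
  }
  structure(list(kind = kind, tail_to_center_ratio = tail_to_center_ratio),
            class = "marginal_shape")
}

#' Default per-parameter marginal shapes
#'
#' U-shaped marginals for the orientation angles beta and gamma (ratio 3),
#' uniform for the speed components and theta.
#'
#' @param u_angles If `FALSE`, all five marginals are uniform.
#' @param ratio Tail-to-center density ratio for the u-shaped angles.
#' @return Named list of [marginal_shape()] objects.
#' @export
default_shapes <- function(u_angles = TRUE, ratio = 3) {
  u <- if (u_angles) marginal_shape("u_shaped", ratio) else marginal_shape("uniform")
  list(
    beta_deg = u,
    gamma_deg = u,
    vn_ms = marginal_shape("uniform"),
    vt_ms = marginal_shape("uniform"),
    theta_deg = marginal_shape("uniform")
  )
}

# Quantile function of the symmetric piecewise-linear u-shaped density on
# [0, 1]: f(u) proportional to 1 + (r - 1) * |2u - 1|, r = tail/center ratio.
q_ushaped <- function(p, ratio) {
  stopifnot(all(p >= 0 & p <= 1), ratio > 1)
  z <- (ratio + 1) / 2                       # normalizing constant
  lower <- p <= 0.5
  q <- numeric(length(p))
  # on [0, 0.5]: f(u) = (r - 2(r-1)u) / z; F(u) = (r*u - (r-1)u^2) / z
  inv_lower <- function(pp) {
    disc <- ratio^2 - 4 * (ratio - 1) * z * pp
    (ratio - sqrt(pmax(disc, 0))) / (2 * (ratio - 1))
  }
  q[lower] <- inv_lower(p[lower])
  q[!lower] <- 1 - inv_lower(1 - p[!lower])
  q
}

# CDF of the same density (used by tests to bin samples into
# equal-probability strata).
p_ushaped <- function(u, ratio) {
  stopifnot(all(u >= 0 & u <= 1), ratio > 1)
  z <- (ratio + 1) / 2
  lower <- u <= 0.5
  p <- numeric(length(u))
  p[lower] <- (ratio * u[lower] - (ratio - 1) * u[lower]^2) / z
  p[!lower] <- 1 - (ratio * (1 - u[!lower]) - (ratio - 1) * (1 - u[!lower])^2) / z
  p
}

#' Latin Hypercube sample of impact scenarios
#'
#' Draws `n` scenarios with one sample per equal-probability stratum in each
#' of the five parameters (a Latin hypercube on the probability scale), then
#' maps the stratified uniforms through each parameter's marginal quantile
#' function and into its physical range.
#'
#' @param n Number of scenarios (>= 1).
#' @param ranges A [param_ranges()].
#' @param shapes Named list of [marginal_shape()]s (see [default_shapes()]).
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return Tibble with columns `scenario_id`, `beta_deg`, `gamma_deg`,
#'   `vn_ms`, `vt_ms`, `theta_deg`, `seed`.
#' @examples
#' sc <- lhs_scenarios(10, seed = 1)
#' @export
lhs_scenarios <- function(n, ranges = param_ranges(),
                          shapes = default_shapes(), seed = 1L) {
  if (!is.numeric(n) || n < 1 || n != as.integer(n)) {
    rlang::abort("`n` must be a positive integer")
  }
  stopifnot(inherits(ranges, "param_ranges"))
  nms <- names(unclass(ranges))
  if (!all(nms %in% names(shapes))) {
    rlang::abort("`shapes` must name all five parameters")
  }
  set.seed(seed)
  U <- lhs::randomLHS(as.integer(n), 5L)
  vals <- purrr::map(seq_along(nms), function(j) {
    nm <- nms[j]
    sh <- shapes[[nm]]
    stopifnot(inherits(sh, "marginal_shape"))
    u <- U[, j]
    if (sh$kind == "u_shaped") u <- q_ushaped(u, sh$tail_to_center_ratio)
    r <- ranges[[nm]]
    r[1] + u * (r[2] - r[1])
  })
  names(vals) <- nms
  tibble::tibble(
    scenario_id = seq_len(n),
    beta_deg = vals$beta_deg,
    gamma_deg = vals$gamma_deg,
    vn_ms = vals$vn_ms,
    vt_ms = vals$vt_ms,
    theta_deg = vals$theta_deg,
    seed = as.integer(seed)
  )
}

#' Validate a scenario table against parameter ranges
#'
#' @param scenarios Tibble as returned by [lhs_scenarios()].
#' @param ranges A [param_ranges()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_scenarios <- function(scenarios, ranges = param_ranges()) {
  nms <- names(unclass(ranges))
  if (!all(nms %in% names(scenarios))) {
    rlang::abort("scenario table missing parameter columns")
  }
  for (nm in nms) {
    v <- scenarios[[nm]]
    r <- ranges[[nm]]
    ok <- if (nm == "theta_deg") v >= r[1] & v < r[2] else v >= r[1] & v <= r[2]
    if (!all(ok)) {
      rlang::abort(sprintf("scenario value out of range for `%s`", nm))
    }
  }
  scenarios
}

#' Impact speed vector in the ground frame
#'
#' The velocity of the helmeted head relative to the ground at contact,
#' expressed in the ground frame (Z = ground normal): tangential component of
#' magnitude `vt_ms` at angle `theta_deg` in the ground plane, and normal
#' component of magnitude `vn_ms` directed into the ground (negative Z).
#'
#' @param scenario One-row scenario tibble (or list with `vn_ms`, `vt_ms`,
#'   `theta_deg`).
#' @return Numeric 3-vector in m/s.
#' @export
speed_vector <- function(scenario) {
  vn <- scenario$vn_ms
  vt <- scenario$vt_ms
  th <- scenario$theta_deg * pi / 180
  stopifnot(length(vn) == 1L, vn > 0, vt > 0)
  c(vt * cos(th), vt * sin(th), -vn)
}

#' Ground orientation for a scenario
#'
#' Rotation of the ground frame relative to the (fixed) head frame: the
#' reference ground plane, parallel to the head's transverse plane, is
#' sequentially rotated about the X-axis by `beta_deg`, then about the
#' Y-axis by `gamma_deg`. Columns of the returned matrix are the ground
#' axes expressed in the head frame; the third column is the ground normal.
#'
#' @param scenario One-row scenario tibble (or list with `beta_deg`,
#'   `gamma_deg`).
#' @return 3 x 3 rotation matrix.
#' @export
ground_orientation <- function(scenario) {
  rot_x(scenario$beta_deg * pi / 180) %*% rot_y(scenario$gamma_deg * pi / 180)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' Read / write scenario tables
#'
#' Plain CSV with columns `scenario_id`, `beta_deg`, `gamma_deg`, `vn_ms`,
#' `vt_ms`, `theta_deg`, `seed`.
#'
#' @param scenarios Scenario tibble.
#' @param path File path.
#' @return `write_scenarios()` returns `scenarios` invisibly;
#'   `read_scenarios()` returns the tibble.
#' @export
write_scenarios <- function(scenarios, path) {
  readr::write_csv(scenarios, path)
  invisible(scenarios)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
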