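#' Rigid-body parameters for head or helmet
#'
#' Spherical-surface idealization of one body: mass, principal inertia about
#' the CoG and the contact-surface radius. Defaults describe a crash-dummy
#' like head form; helmet defaults describe a full-face shell.
#'
#' @param mass Mass in kg.
#' @param inertia_diag Principal moments of inertia (kg m^2), length 3.
#' @param radius Contact-surface radius in m (head surface, or helmet outer
#'   shell).
#' @param inner_radius Shell inner (liner) surface radius in m; helmet only.
#' @return List of class `body_params`.
#' @export
body_params <- function(mass, inertia_diag, radius, inner_radius = NULL) {
  stopifnot(mass > 0, length(inertia_diag) == 3L, all(inertia_diag > 0),
            radius > 0)
  structure(
    list(mass = mass, inertia_diag = as.numeric(inertia_diag),
         radius = radius, inner_radius = inner_radius),
    class = "body_params"
  )
}

#' @rdname body_params
#' @export
head_params <- function(mass = 4.54,
                        inertia_diag = c(0.0171, 0.0160, 0.0220),
                        radius = 0.085) {
  body_params(mass, inertia_diag, radius)
}

#' @rdname body_params
#' @export
helmet_params <- function(mass = 1.5,
                          inertia_diag = c(0.016, 0.016, 0.016),
                          radius = 0.135, inner_radius = 0.12) {
  stopifnot(inner_radius < radius)
  body_params(mass, inertia_diag, radius, inner_radius)
}

#' Contact and coupling parameters
#'
#' Penalty ground contact, distributed viscoelastic liner elements
#' (compression only) with regularized Coulomb friction, and a weak
#' centering spring standing in for the chin strap. Defaults are calibrated
#' so that a default scenario batch shows shell-to-head peak attenuation in
#' the 2-10x range reported for helmeted impacts, with rotational peaks
#' reaching beyond 40 krad/s^2 only in a minority of severe oblique impacts.
#'
#' @param liner_stiffness Per-patch liner stiffness, N/m.
#' @param liner_damping Per-patch liner damping, N s/m.
#' @param liner_friction_mu Liner Coulomb friction coefficient, in `[0, 2]`.
#' @param liner_hardening Dimensionless bottoming-out coefficient: the
#'   elastic patch force is `k * d * (1 + h * (d / gap)^2)`, so compression
#'   approaching the full liner gap stiffens sharply, as crushable foam
#'   liners do.
#' @param ground_stiffness Ground penalty stiffness, N/m.
#' @param ground_damping Ground contact damping, N s/m.
#' @param ground_friction_mu Ground friction coefficient, in `[0, 2]`.
#' @param n_liner_patches Number of radial liner elements.
#' @param strap_stiffness,strap_damping Centering spring between body
#'   centers, N/m and N s/m.
#' @param v_eps Friction regularization velocity, m/s (`tanh(v / v_eps)`
#'   slip law).
#' @return List of class `contact_params`.
#' @export
contact_params <- function(liner_stiffness = 1.2e4,
                           liner_damping = 12,
                           liner_friction_mu = 0.5,
                           liner_hardening = 18,
                           ground_stiffness = 2.5e6,
                           ground_damping = 600,
                           ground_friction_mu = 0.5,
                           n_liner_patches = 64L,
                           strap_stiffness = 2000,
                           strap_damping = 20,
                           v_eps = 0.01) {
  stopifnot(liner_stiffness >= 0, liner_damping >= 0, liner_hardening >= 0,
            ground_stiffness >= 0, ground_damping >= 0,
            liner_friction_mu >= 0, liner_friction_mu <= 2,
            ground_friction_mu >= 0, ground_friction_mu <= 2,
            n_liner_patches >= 4, v_eps > 0)
  structure(
    list(liner_stiffness = liner_stiffness, liner_damping = liner_damping,
         liner_friction_mu = liner_friction_mu,
         liner_hardening = liner_hardening,
         ground_stiffness = ground_stiffness, ground_damping = ground_damping,
         ground_friction_mu = ground_friction_mu,
         n_liner_patches = as.integer(n_liner_patches),
         strap_stiffness = strap_stiffness, strap_damping = strap_damping,
         v_eps = v_eps),
    class = "contact_params"
  )
}

# Near-uniform unit directions on the sphere (Fibonacci lattice), 3 x n.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Two orthonormal tangential axes for a radial direction.
tangent_axes <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a1 <- ref - sum(ref * d) * d
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(d[2] * a1[3] - d[3] * a1[2],
          d[3] * a1[1] - d[1] * a1[3],
          d[1] * a1[2] - d[2] * a1[1])
  cbind(a1, a2)
}

#' Accelerometer layout on the shell inner surface
#'
#' Six locations (unit radial directions in the helmet body frame), each
#' carrying two orthonormal sensing axes tangential to the shell — twelve
#' single-axis channels in total. The default places sensors at the front,
#' rear, left, right, crown and chin of the shell. The layout is data: any
#' six-location set with valid tangential axes can be supplied.
#'
#' @param locations 3 x 6 matrix of unit radial directions (columns), helmet
#'   body frame (X forward, Y left, Z up).
#' @return List of class `sensor_layout` with `locations` (3 x 6), `axis1`
#'   and `axis2` (3 x 6 tangential unit axes).
#' @export
sensor_layout <- function(locations = NULL) {
  if (is.null(locations)) {
    locations <- cbind(
      front = c(1, 0, 0), rear = c(-1, 0, 0),
      left = c(0, 1, 0), right = c(0, -1, 0),
      crown = c(0, 0, 1), chin = c(0.5, 0, -sqrt(3) / 2)
    )
  }
  stopifnot(is.matrix(locations), nrow(locations) == 3L, ncol(locations) == 6L)
  locations <- apply(locations, 2L, function(d) d / sqrt(sum(d^2)))
  ax <- apply(locations, 2L, tangent_axes, simplify = FALSE)
  layout <- structure(
    list(locations = locations,
         axis1 = vapply(ax, function(a) a[, 1L], numeric(3)),
         axis2 = vapply(ax, function(a) a[, 2L], numeric(3))),
    class = "sensor_layout"
  )
  validate_layout(layout)
}

validate_layout <- function(layout) {
  tol <- 1e-10
  for (j in seq_len(6L)) {
    d <- layout$locations[, j]
    a1 <- layout$axis1[, j]
    a2 <- layout$axis2[, j]
    if (abs(sum(a1 * d)) > tol || abs(sum(a2 * d)) > tol ||
        abs(sum(a1 * a2)) > tol ||
        abs(sum(a1^2) - 1) > tol || abs(sum(a2^2) - 1) > tol) {
      rlang::abort("sensor layout axes must be orthonormal and tangential")
    }
  }
  layout
}

#' Body-fixed point acceleration from a state history
#'
#' Coordinate acceleration of a body-fixed point, expressed in the body
#' frame: `a_p = R' a_cg + alpha x r + omega x (omega x r)`.
#'
#' @param history Body state history as returned in
#'   `simulate_impact()$history` (list with `quat`, `a_world`, `alpha_body`,
#'   `omega_body` matrices).
#' @param point Body-frame position of the point (length-3, m).
#' @return 3 x T matrix of body-frame acceleration.
#' @export
point_acceleration <- function(history, point) {
  stopifnot(length(point) == 3L)
  cpp_point_acceleration(history$quat, history$a_world,
                         history$alpha_body, history$omega_body,
                         as.numeric(point))
}

#' Project point accelerations onto the sensor axes
#'
#' @param point_acc List of six 3 x T body-frame acceleration matrices, one
#'   per sensor location (layout order).
#' @param layout A [sensor_layout()].
#' @return 12 x T channel matrix; channel order is location-major, axis-1
#'   before axis-2.
#' @export
project_channels <- function(point_acc, layout) {
  stopifnot(inherits(layout, "sensor_layout"), length(point_acc) == 6L)
  validate_layout(layout)
  out <- lapply(seq_len(6L), function(j) {
    a <- point_acc[[j]]
    rbind(drop(crossprod(layout$axis1[, j], a)),
          drop(crossprod(layout$axis2[, j], a)))
  })
  do.call(rbind, out)
}

#' Simulate one helmeted-head ground impact
#'
#' Integrates the two-body surrogate model from the scenario's initial
#' velocity and ground orientation and returns the twelve tangential shell
#' channels together with the head CoG linear and rotational acceleration
#' ground truth.
#'
#' @param scenario One-row scenario tibble (see [lhs_scenarios()]).
#' @param head,helmet [body_params()] for the two bodies.
#' @param contact [contact_params()].
#' @param layout [sensor_layout()].
#' @param duration Event duration in s (>= 0.02).
#' @param dt Integration step in s. The default 1e-6 keeps the stiffest
#'   regularized-friction elements of a bottoming-out impact well inside the
#'   explicit integrator's accurate region (impulse-momentum closure to
#'   ~1e-5).
#' @param dt_out Output sample interval in s (default 5e-5, i.e. 20 kHz).
#' @param initial_gap Initial clearance between shell and ground along the
#'   ground normal, m.
#' @return An `impact_record`: list with `time`, `helmet` (12 x T, m/s^2,
#'   helmet frame), `head_lin` (3 x T, m/s^2, head frame), `head_rot`
#'   (3 x T, rad/s^2, head frame), `scenario`, `dt`, `history` (both-body
#'   state histories) and `meta` (solver settings and diagnostics).
#' @export
simulate_impact <- function(scenario,
                            head = head_params(),
                            helmet = helmet_params(),
                            contact = contact_params(),
                            layout = sensor_layout(),
                            duration = 0.03,
                            dt = 1e-6,
                            dt_out = 5e-5,
                            initial_gap = 0) {
  stopifnot(duration >= 0.02, dt > 0, dt_out >= dt)
  scenario <- as_scenario_row(scenario)
  R_g <- ground_orientation(scenario)
  n_gnd <- R_g %*% c(0, 0, 1)
  v0 <- R_g %*% c(scenario$vt_ms * cos(scenario$theta_deg * pi / 180),
                  scenario$vt_ms * sin(scenario$theta_deg * pi / 180),
                  -scenario$vn_ms)
  patches <- fibonacci_sphere(contact$n_liner_patches)
  sim <- cpp_simulate(unclass(head), unclass(helmet), unclass(contact),
                      patches, as.numeric(n_gnd), initial_gap,
                      as.numeric(v0), duration, dt, dt_out)
  # sensor channels: shell inner-surface point accelerations projected onto
  # the tangential axes
  r_in <- helmet$inner_radius
  pa <- lapply(seq_len(6L), function(j) {
    point_acceleration(sim$helmet, r_in * layout$locations[, j])
  })
  channels <- project_channels(pa, layout)
  # head ground truth in the head body frame
  head_lin <- cpp_point_acceleration(sim$head$quat, sim$head$a_world,
                                     sim$head$alpha_body, sim$head$omega_body,
                                     c(0, 0, 0))
  sim$diagnostics$shell_peak <- max(sqrt(colSums(sim$helmet$a_world^2)))
  sim$diagnostics$head_peak <- max(sqrt(colSums(sim$head$a_world^2)))
  new_impact_record(
    time = as.numeric(sim$time),
    helmet = channels,
    head_lin = head_lin,
    head_rot = sim$head$alpha_body,
    scenario = scenario,
    dt = dt_out,
    history = list(head = sim$head, helmet = sim$helmet),
    meta = list(dt_solver = dt, duration = duration,
                initial_gap = initial_gap,
                diagnostics = sim$diagnostics)
  )
}

#' Shell-to-head peak attenuation ratio
#'
#' Ratio of the helmet shell CoG peak resultant linear acceleration to the
#' head CoG peak resultant, from the solver diagnostics of a record.
#' Helmeted-impact measurements place this ratio between roughly 2 and 10;
#' it is the calibration target of the surrogate's default contact
#' parameters.
#'
#' @param record An `impact_record` produced by [simulate_impact()].
#' @return Dimensionless ratio (> 1 when the liner attenuates).
#' @export
attenuation_ratio <- function(record) {
  d <- record$meta$diagnostics
  if (is.null(d$shell_peak)) {
    rlang::abort("record carries no solver diagnostics")
  }
  d$shell_peak / d$head_peak
}

new_impact_record <- function(time, helmet, head_lin, head_rot, scenario,
                              dt, history = NULL, meta = list()) {
  T <- length(time)
  stopifnot(ncol(helmet) == T, nrow(helmet) == 12L,
            ncol(head_lin) == T, nrow(head_lin) == 3L,
            ncol(head_rot) == T, nrow(head_rot) == 3L, dt > 0)
  if (!all(is.finite(helmet)) || !all(is.finite(head_lin)) ||
      !all(is.finite(head_rot))) {
    rlang::abort("impact record contains non-finite values")
  }
  structure(
    list(time = time, helmet = helmet, head_lin = head_lin,
         head_rot = head_rot, scenario = scenario, dt = dt,
         history = history, meta = meta),
    class = "impact_record"
  )
}

#' @export
print.impact_record <- function(x, ...) {
  cat(sprintf(
    "<impact_record> scenario %s: %d samples @ %.0f Hz (%.1f ms)\n",
    x$scenario$scenario_id, length(x$time), 1 / x$dt,
    1000 * (max(x$time) - min(x$time))))
  cat(sprintf("  peak |head lin| %.1f m/s^2, peak |head rot| %.0f rad/s^2\n",
              max(resultant(x$head_lin)), max(resultant(x$head_rot))))
  invisible(x)
}

as_scenario_row <- function(scenario) {
  scenario <- tibble::as_tibble(as.list(scenario)[
    intersect(names(scenario),
              c("scenario_id", "beta_deg", "gamma_deg", "vn_ms", "vt_ms",
                "theta_deg", "seed"))])
  if (nrow(scenario) != 1L) rlang::abort("expected a single scenario row")
  if (is.null(scenario$scenario_id)) scenario$scenario_id <- 1L
  scenario
}

as_record_list <- function(records) {
  if (inherits(records, "impact_dataset")) return(records$records)
  if (inherits(records, "impact_record")) return(list(records))
  stopifnot(is.list(records), all(purrr::map_lgl(records, inherits,
                                                 "impact_record")))
  records
}

#' Generate a dataset of impact simulations
#'
#' Runs [simulate_impact()] for every row of a scenario table and collects
#' the records with a manifest. Solver failures are recorded in the manifest
#' (status column), not silently dropped.
#'
#' @param scenarios Scenario tibble from [lhs_scenarios()].
#' @param seed Integer seed recorded in the manifest (the surrogate solver
#'   itself is deterministic).
#' @param keep_history Keep full state histories in the records (needed by
#'   [point_acceleration()]; drop to save memory on large batches).
#' @inheritParams simulate_impact
#' @return An `impact_dataset`: list with `records` (named by scenario_id),
#'   `manifest` tibble and `settings`.
#' @export
generate_dataset <- function(scenarios,
                             head = head_params(),
                             helmet = helmet_params(),
                             contact = contact_params(),
                             layout = sensor_layout(),
                             duration = 0.03,
                             dt = 1e-6,
                             dt_out = 5e-5,
                             seed = 1L,
                             keep_history = FALSE) {
  stopifnot(nrow(scenarios) >= 1L)
  settings <- list(head = unclass(head), helmet = unclass(helmet),
                   contact = unclass(contact), duration = duration,
                   dt = dt, dt_out = dt_out, seed = as.integer(seed))
  param_hash <- rlang::hash(settings)
  rows <- list()
  records <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    rec <- tryCatch(
      simulate_impact(sc, head, helmet, contact, layout,
                      duration = duration, dt = dt, dt_out = dt_out),
      error = function(e) e
    )
    id <- as.character(sc$scenario_id)
    if (inherits(rec, "error")) {
      rows[[i]] <- tibble::tibble(scenario_id = sc$scenario_id,
                                  status = "failed",
                                  message = conditionMessage(rec))
    } else {
      if (!keep_history) rec$history <- NULL
      records[[id]] <- rec
      rows[[i]] <- tibble::tibble(scenario_id = sc$scenario_id,
                                  status = "ok", message = NA_character_)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$param_hash <- param_hash
  manifest$seed <- as.integer(seed)
  structure(list(records = records, manifest = manifest, settings = settings),
            class = "impact_dataset")
}

#' @export
print.impact_dataset <- function(x, ...) {
  n_ok <- sum(x$manifest$status == "ok")
  cat(sprintf("<impact_dataset> %d records (%d failed)\n",
              n_ok, nrow(x$manifest) - n_ok))
  invisible(x)
}

#' Write / read an impact dataset
#'
#' Stores one CSV per record (`record_<id>.csv` with columns `time`, the 12
#' helmet channels, and the 6 head channels) plus a JSON manifest carrying
#' the scenario table, solver settings and parameter hash.
#'
#' @param dataset An `impact_dataset`.
#' @param dir Directory to write into (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the `impact_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "impact_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- purrr::map_dfr(dataset$records, "scenario")
  for (id in names(dataset$records)) {
    r <- dataset$records[[id]]
    df <- tibble::as_tibble(cbind(time = r$time, t(r$helmet), t(r$head_lin),
                                  t(r$head_rot)), .name_repair = "minimal")
    names(df) <- c("time", paste0("ch", 1:12),
                   paste0("lin_", c("x", "y", "z")),
                   paste0("rot_", c("x", "y", "z")))
    readr::write_csv(df, file.path(dir, paste0("record_", id, ".csv")))
  }
  jsonlite::write_json(
    list(manifest = dataset$manifest, scenarios = scen,
         settings = dataset$settings),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  manifest <- tibble::as_tibble(man$manifest)
  scen <- tibble::as_tibble(man$scenarios)
  records <- list()
  ok_ids <- manifest$scenario_id[manifest$status == "ok"]
  for (id in ok_ids) {
    df <- readr::read_csv(file.path(dir, paste0("record_", id, ".csv")),
                          show_col_types = FALSE)
    records[[as.character(id)]] <- new_impact_record(
      time = df$time,
      helmet = unname(t(as.matrix(df[paste0("ch", 1:12)]))),
      head_lin = unname(t(as.matrix(df[c("lin_x", "lin_y", "lin_z")]))),
      head_rot = unname(t(as.matrix(df[c("rot_x", "rot_y", "rot_z")]))),
      scenario = scen[scen$scenario_id == id, ],
      dt = df$time[2L] - df$time[1L],
      meta = list(settings = man$settings)
    )
  }
  structure(list(records = records, manifest = manifest,
                 settings = man$settings),
            class = "impact_dataset")
}
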