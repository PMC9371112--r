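#' Squared Pearson correlation
#'
#' The R^2 used throughout the assessment: the squared Pearson correlation
#' between target and estimated summary parameters. For an ordinary
#' least-squares fit with intercept this coincides with the regression
#' coefficient of determination.
#'
#' @param targets,estimates Numeric vectors of equal length (>= 3).
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(targets, estimates) {
  stopifnot(length(targets) == length(estimates), length(targets) >= 3L)
  if (stats::sd(targets) == 0 || stats::sd(estimates) == 0) {
    rlang::abort("correlation undefined: constant targets or estimates")
  }
  stats::cor(targets, estimates)^2
}

#' Exclude impacts beyond a rotational-acceleration threshold
#'
#' Drops records whose ground-truth (target) peak rotational resultant
#' exceeds the threshold. The rule is defined on the simulated truth, not
#' the estimate: its rationale is the physiological limit of survivable
#' head motion, which is a property of the true kinematics.
#'
#' @param metrics Tibble containing a `peak_rot` column of target peaks
#'   (rad/s^2), e.g. from [injury_metrics()].
#' @param threshold Exclusion threshold in rad/s^2 (e.g. `40000`); `Inf`
#'   keeps everything.
#' @return The kept rows, with attribute `n_excluded`.
#' @export
apply_exclusion <- function(metrics, threshold) {
  stopifnot("peak_rot" %in% names(metrics))
  keep <- metrics$peak_rot <= threshold
  out <- metrics[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    rlang::warn("exclusion threshold removed every record")
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# per-quantity R^2 + OLS regression (estimate on target), scatter kept
quantity_stats <- function(target, estimate, quantity, network) {
  fit <- stats::lm(estimate ~ target)
  tibble::tibble(
    network = network,
    quantity = quantity,
    r_squared = r_squared(target, estimate),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = length(target)
  )
}

assessment_table <- function(tm, em) {
  lin_q <- c("peak_ax", "peak_ay", "peak_az", "peak_lin", "hic")
  rot_q <- c("peak_rx", "peak_ry", "peak_rz", "peak_rot", "ric")
  dplyr::bind_rows(
    purrr::map_dfr(lin_q, ~ quantity_stats(tm[[.x]], em[[.x]], .x, "A")),
    purrr::map_dfr(rot_q, ~ quantity_stats(tm[[.x]], em[[.x]], .x, "B"))
  )
}

#' Assess the estimator pair on a test set
#'
#' Predicts every test record with the linear (A) and rotational (B)
#' networks, computes the summary parameters — signed component peaks,
#' resultant peaks, HIC and RIC — on both the target and the estimated time
#' histories, and reports per-quantity R^2 with the least-squares regression
#' line of estimate on target. A reduced variant repeats the analysis after
#' excluding impacts whose target peak rotational resultant exceeds
#' `exclusion_threshold`.
#'
#' The test set must be disjoint from the records either network was
#' trained on; any overlap is a hard failure.
#'
#' @param test Test `impact_dataset` (or record list).
#' @param estimator_a,estimator_b Trained linear / rotational estimators.
#' @param exclusion_threshold Rotational peak threshold in rad/s^2
#'   (default 40000); `Inf` disables the reduced variant.
#' @param max_window Window bound for HIC / RIC.
#' @return List of class `assessment_report`: `full` and `reduced`
#'   per-quantity tibbles, per-record `target_metrics` and
#'   `estimate_metrics`, `n_records`, `n_excluded`,
#'   `exclusion_threshold`, and `underestimation_flags` (quantities whose
#'   regression slope is below 1).
#' @export
assess <- function(test, estimator_a, estimator_b,
                   exclusion_threshold = 40000, max_window = Inf) {
  stopifnot(inherits(estimator_a, "trained_estimator"),
            inherits(estimator_b, "trained_estimator"))
  if (estimator_a$target != "linear" || estimator_b$target != "rotational") {
    rlang::abort("estimator_a must be the linear network, estimator_b the rotational one")
  }
  recs <- as_record_list(test)
  ids <- record_ids(recs)
  overlap <- intersect(ids, c(estimator_a$train_ids, estimator_b$train_ids))
  if (length(overlap) > 0L) {
    rlang::abort(sprintf(
      "test set overlaps the training manifest (scenario ids: %s)",
      paste(utils::head(overlap, 5L), collapse = ", ")))
  }

  pred_lin <- predict(estimator_a, recs)
  pred_rot <- predict(estimator_b, recs)
  tm <- injury_metrics(recs, max_window = max_window)
  em <- purrr::map_dfr(seq_along(recs), function(i) {
    metric_row(pred_lin[[i]], pred_rot[[i]], recs[[i]]$time,
               recs[[i]]$scenario$scenario_id, max_window = max_window)
  })

  full <- assessment_table(tm, em)
  kept <- apply_exclusion(tm, exclusion_threshold)
  n_excluded <- attr(kept, "n_excluded")
  reduced <- if (n_excluded > 0L && nrow(kept) >= 3L) {
    assessment_table(kept, em[tm$peak_rot <= exclusion_threshold, ])
  } else {
    full
  }

  structure(
    list(full = full, reduced = reduced,
         target_metrics = tm, estimate_metrics = em,
         n_records = length(recs), n_excluded = n_excluded,
         exclusion_threshold = exclusion_threshold,
         underestimation_flags = full$quantity[full$slope < 1]),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d test records, %d excluded above %.0f rad/s^2\n",
              x$n_records, x$n_excluded, x$exclusion_threshold))
  cat("full dataset:\n")
  print(as.data.frame(x$full), digits = 3, row.names = FALSE)
  if (x$n_excluded > 0L) {
    cat("reduced dataset:\n")
    print(as.data.frame(x$reduced), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Tidy an assessment report
#'
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @return Tibble of per-quantity statistics with a `dataset` column
#'   (`"full"` / `"reduced"`).
#' @export
tidy.assessment_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$full, dataset = "full"),
    dplyr::mutate(x$reduced, dataset = "reduced")
  )
}

#' One-row summary of an assessment report
#'
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @return One-row tibble with the headline R^2 values.
#' @export
glance.assessment_report <- function(x, ...) {
  get_r2 <- function(tab, q) tab$r_squared[tab$quantity == q]
  tibble::tibble(
    n_records = x$n_records,
    n_excluded = x$n_excluded,
    r2_peak_lin = get_r2(x$full, "peak_lin"),
    r2_hic = get_r2(x$full, "hic"),
    r2_peak_rot = get_r2(x$full, "peak_rot"),
    r2_ric = get_r2(x$full, "ric"),
    r2_peak_rot_reduced = get_r2(x$reduced, "peak_rot"),
    r2_ric_reduced = get_r2(x$reduced, "ric")
  )
}

#' Write an assessment report to disk
#'
#' CSV tables of the per-quantity statistics and per-record scatter data,
#' plus a JSON summary, under a report directory.
#'
#' @param report An `assessment_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report), file.path(dir, "r_squared.csv"))
  scatter <- dplyr::left_join(
    tidyr::pivot_longer(report$target_metrics, -"scenario_id",
                        names_to = "quantity", values_to = "target"),
    tidyr::pivot_longer(report$estimate_metrics, -"scenario_id",
                        names_to = "quantity", values_to = "estimate"),
    by = c("scenario_id", "quantity")
  )
  readr::write_csv(scatter, file.path(dir, "scatter.csv"))
  jsonlite::write_json(
    c(as.list(glance(report)),
      list(exclusion_threshold = report$exclusion_threshold,
           underestimation_flags = report$underestimation_flags)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an assessment report summary written by [write_report()]
#'
#' @param dir Report directory.
#' @return List with `r_squared` tibble, `scatter` tibble, `summary` list.
#' @export
read_report <- function(dir) {
  list(
    r_squared = readr::read_csv(file.path(dir, "r_squared.csv"),
                                show_col_types = FALSE),
    scatter = readr::read_csv(file.path(dir, "scatter.csv"),
                              show_col_types = FALSE),
    summary = jsonlite::read_json(file.path(dir, "summary.json"),
                                  simplifyVector = TRUE)
  )
}
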