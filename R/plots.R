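#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an impact record
#'
#' Helmet channels and head ground-truth components as small-multiple time
#' series.
#'
#' @param object An `impact_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impact_record <- function(object, ...) {
  helmet <- tibble::as_tibble(t(object$helmet), .name_repair = "minimal")
  names(helmet) <- paste0("helmet ch", 1:12)
  head_df <- tibble::as_tibble(t(rbind(object$head_lin, object$head_rot)),
                               .name_repair = "minimal")
  names(head_df) <- c("head ax", "head ay", "head az",
                      "head rx", "head ry", "head rz")
  df <- dplyr::bind_cols(tibble::tibble(time = object$time), helmet, head_df)
  long <- tidyr::pivot_longer(df, -"time", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = unique(long$channel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time * 1000, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 6) +
    ggplot2::labs(x = "time [ms]", y = "acceleration",
                  title = sprintf("scenario %s", object$scenario$scenario_id)) +
    ggplot2::theme_minimal(base_size = 8)
}

#' Plot the training history of a fitted estimator
#'
#' @param object A `trained_estimator`.
#' @param ... Unused.
#' @return A ggplot object with training loss and validation RMSE per epoch.
#' @export
autoplot.trained_estimator <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log,
                            c("train_loss", "val_rmse"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s network training", object$target)) +
    ggplot2::theme_minimal()
}

#' Scatter plots of target versus estimated summary parameters
#'
#' One panel per assessed quantity, with the identity line (dashed) and the
#' least-squares regression line.
#'
#' @param object An `assessment_report`.
#' @param dataset `"full"` or `"reduced"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assessment_report <- function(object, dataset = c("full", "reduced"),
                                       ...) {
  dataset <- match.arg(dataset)
  tm <- object$target_metrics
  em <- object$estimate_metrics
  if (dataset == "reduced") {
    keep <- tm$peak_rot <= object$exclusion_threshold
    em <- em[keep, ]
    tm <- tm[keep, ]
  }
  qs <- setdiff(names(tm), "scenario_id")
  long <- dplyr::left_join(
    tidyr::pivot_longer(tm, -"scenario_id", names_to = "quantity",
                        values_to = "target"),
    tidyr::pivot_longer(em, -"scenario_id", names_to = "quantity",
                        values_to = "estimate"),
    by = c("scenario_id", "quantity")
  )
  long$quantity <- factor(long$quantity, levels = qs)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$estimate)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "target", y = "estimated",
                  title = sprintf("%s test set (n = %d)", dataset,
                                  length(unique(long$scenario_id)))) +
    ggplot2::theme_minimal(base_size = 9)
}
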