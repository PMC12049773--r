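#' Plot the cohort CH curve
#'
#' Mean Calinski-Harabasz score against the candidate cluster count, one
#' line per contrast phase, with the selected `k_star` marked.
#'
#' @param object A `cluster_selection` from [select_k_by_ch()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_selection <- function(object, ...) {
  df <- object$scores |>
    dplyr::group_by(.data$phase, .data$k) |>
    dplyr::summarise(mean_ch = mean(.data$ch, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean_ch,
                                   colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of habitats k", y = "mean CH score",
                  title = sprintf("Cluster-number selection (k* = %d)",
                                  object$k_star))
}

#' Plot the LASSO cross-validation curve
#'
#' @param object A `habitat_signature`.
#' @param ... Unused.
#' @return A ggplot of CV deviance against log(lambda).
#' @export
autoplot.habitat_signature <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = log(.data$lambda),
                                          y = .data$deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$deviance - .data$deviance_se,
                                      ymax = .data$deviance + .data$deviance_se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "cross-validated deviance")
}

#' Plot an evaluation report
#'
#' ROC curve (`which = "roc"`), calibration curve (`"calibration"`), or
#' decision curve (`"decision"`).
#'
#' @param object An `evaluation_report` from [evaluate_scores()].
#' @param which Plot type.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object,
                                       which = c("roc", "calibration",
                                                 "decision"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    y <- object$labels
    thr <- c(Inf, sort(unique(object$scores), decreasing = TRUE))
    roc <- purrr::map_dfr(thr, function(t) {
      pred <- object$scores >= t
      tibble::tibble(fpr = sum(pred & y == 0) / sum(y == 0),
                     tpr = sum(pred & y == 1) / sum(y == 1))
    })
    return(ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
             ggplot2::geom_step() +
             ggplot2::geom_abline(linetype = "dotted") +
             ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                           title = sprintf("%s (%s): AUC %.3f",
                                           object$summary$branch,
                                           object$summary$split,
                                           object$summary$auc)))
  }
  if (which == "calibration") {
    if (is.null(object$calibration)) stop("no calibration bins (scores were not probabilities)")
    return(ggplot2::ggplot(object$calibration,
                           ggplot2::aes(.data$mean_predicted, .data$observed)) +
             ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
             ggplot2::geom_line() +
             ggplot2::geom_abline(linetype = "dotted") +
             ggplot2::labs(x = "mean predicted probability",
                           y = "observed frequency"))
  }
  if (is.null(object$decision)) stop("no decision curve (scores were not probabilities)")
  dc <- tidyr::pivot_longer(object$decision, c("net_benefit", "treat_all",
                                               "treat_none"),
                            names_to = "strategy", values_to = "nb")
  ggplot2::ggplot(dc, ggplot2::aes(.data$pt, .data$nb,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit")
}
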