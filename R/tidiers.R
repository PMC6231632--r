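#' Tidy a texton histogram
#'
#' @param x a `texton_histogram`.
#' @param ... unused.
#' @return a tibble with `label` and `value` (count or frequency).
#' @method tidy texton_histogram
#' @export
tidy.texton_histogram <- function(x, ...) {
  tibble(label = seq_len(x$n_labels) - 1L, value = x$bins)
}

#' @rdname tidy.texton_histogram
#' @method autoplot texton_histogram
#' @export
autoplot.texton_histogram <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "rotation-invariant texton label",
                  y = if (x$normalized) "frequency" else "count") +
    ggplot2::theme_minimal()
}

#' Per-fold results of a nested cross-validation
#'
#' @param x a `qdcp_eval` from [nested_cv()].
#' @param ... unused.
#' @return a tibble with one row per (repeat, outer fold): `acc`, `auc`, the
#'   selected feature set and hyper-parameters.
#' @method tidy qdcp_eval
#' @export
tidy.qdcp_eval <- function(x, ...) x$results

#' One-row summary of a nested cross-validation
#'
#' @inheritParams tidy.qdcp_eval
#' @return a tibble with `classifier`, `acc_mean`, `acc_sd`, `auc_mean`,
#'   `auc_sd`, `n_scores`.
#' @method glance qdcp_eval
#' @export
glance.qdcp_eval <- function(x, ...) {
  tibble(
    classifier = x$classifier,
    acc_mean = mean(x$results$acc), acc_sd = sd(x$results$acc),
    auc_mean = mean(x$results$auc), auc_sd = sd(x$results$auc),
    n_scores = nrow(x$results)
  )
}

#' @rdname tidy.qdcp_eval
#' @method autoplot qdcp_eval
#' @export
autoplot.qdcp_eval <- function(x, ...) {
  long <- tidyr::pivot_longer(x$results, c("acc", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(title = sprintf("%s, %d x %d-fold nested CV",
                                  x$classifier, x$n_repeats, x$outer_k),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sensitivity sweep
#'
#' @param x a `qdcp_sweep` from [threshold_sweep()].
#' @param ... unused.
#' @return a ggplot of accuracy (with +/- 1 sd ribbon) against the
#'   threshold.
#' @method autoplot qdcp_sweep
#' @export
autoplot.qdcp_sweep <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$t_o, y = .data$acc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$acc_mean - .data$acc_sd,
                                      ymax = .data$acc_mean + .data$acc_sd),
                         fill = "grey85") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(T[O]), y = "CV accuracy",
                  title = "Threshold sensitivity") +
    ggplot2::theme_minimal()
}
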