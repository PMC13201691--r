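#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar labs theme_minimal coord_flip
NULL

#' Plot a training history
#'
#' Loss (and, when recorded, AUROC / F1) against epoch.
#'
#' @param object a `squeezevit_history` tibble from [train()]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.squeezevit_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- do.call(rbind, lapply(setdiff(names(df), "epoch"), function(m) {
    tibble::tibble(epoch = df$epoch, metric = m, value = df[[m]])
  }))
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Training history") +
    theme_minimal()
}

#' Plot a per-class evaluation report
#'
#' Per-class AUROC bars with bootstrap CI whiskers when present.
#'
#' @param object a `squeezevit_eval` report
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.squeezevit_eval <- function(object, ...) {
  df <- object$per_class
  p <- ggplot(df, aes(x = stats::reorder(.data$class, .data$auroc),
                      y = .data$auroc)) +
    geom_col(fill = "grey55") +
    coord_flip() +
    labs(x = NULL, y = "AUROC",
         title = sprintf("Class-wise AUROC (average %.3f)", object$average)) +
    theme_minimal()
  if ("ci_low" %in% names(df)) {
    p <- p + geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.3)
  }
  p
}

#' @importFrom rlang .data
NULL
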