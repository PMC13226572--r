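# ggplot2 helpers for the tabular results the pipeline produces.

#' Plot a dual-branch (or plain) training log
#'
#' @param log a `pw_training_log` from [train_maf()] or [train_detector()].
#' @return a ggplot object.
#' @export
plot_training_log <- function(log) {
  df <- as.data.frame(log)
  value_cols <- intersect(c("l_t", "l_main", "l_aux", "loss"), names(df))
  long <- do.call(rbind, lapply(value_cols, function(v)
    data.frame(epoch = df$epoch, loss = df[[v]], term = v)))
  long <- long[is.finite(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = loss,
                                     color = term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pw_training_log <- function(object, ...) plot_training_log(object)

#' Plot an adaptation log (certainty and mask density over the stream)
#'
#' @param log a `pw_adapt_log` from [adapt_stream()].
#' @return a ggplot object.
#' @export
plot_adaptation_log <- function(log) {
  df <- as.data.frame(log)
  long <- rbind(
    data.frame(step = df$step, value = df$mean_certainty, what = "mean certainty"),
    data.frame(step = df$step, value = df$mask_density, what = "mask density"))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = step, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "streamed image", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pw_adapt_log <- function(object, ...) plot_adaptation_log(object)

utils::globalVariables(c("epoch", "loss", "term", "step", "value", "what"))
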