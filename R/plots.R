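summary_by_condition <- function(results, metric = "accuracy",
                                 split = "ood_test") {
  r <- results[results$metric == metric & results$split == split, ]
  conds <- unique(r$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    s <- summarize_replicates(r$value[r$condition == cc])
    data.frame(condition = cc, mean = s[["mean"]], se = s[["se"]])
  }))
  rownames(out) <- NULL
  out
}

#' Plot experiment summaries
#'
#' Convenience mirrors of the study's figures: accuracy versus training-set
#' size (ID and OOD), diverse versus non-diverse OOD accuracy, and accuracy
#' or count error versus noise level. Each returns a ggplot object (ggplot2
#' must be installed); points are condition means, vertical bars the
#' standard error across replications.
#'
#' @param results a long-format results data.frame.
#' @return a ggplot object.
#' @export
plot_size_curve <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  r <- results[results$metric == "accuracy", ]
  agg <- stats::aggregate(value ~ condition + split, data = r, FUN = mean)
  sev <- stats::aggregate(value ~ condition + split, data = r,
                          FUN = function(x) summarize_replicates(x)[["se"]])
  agg$se <- sev$value
  agg$size <- as.numeric(agg$condition)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$size, y = .data$value,
                                    color = .data$split)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.02) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training patches", y = "accuracy")
}

#' @rdname plot_size_curve
#' @export
plot_diversity <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  agg <- summary_by_condition(results)
  agg$diverse <- agg$condition == "diverse"
  ggplot2::ggplot(agg, ggplot2::aes(x = stats::reorder(.data$condition,
                                                       .data$mean),
                                    y = .data$mean,
                                    color = .data$diverse)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "OOD accuracy")
}

#' @rdname plot_size_curve
#' @param metric `"accuracy"` or `"count_error"`.
#' @export
plot_noise_curves <- function(results, metric = "accuracy") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  agg <- summary_by_condition(results, metric = metric)
  parts <- strsplit(agg$condition, ":", fixed = TRUE)
  agg$noise <- vapply(parts, `[`, character(1), 1)
  agg$level <- as.numeric(vapply(parts, `[`, character(1), 2))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::facet_wrap(~noise, scales = "free_x") +
    ggplot2::labs(x = "noise level", y = metric)
}
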