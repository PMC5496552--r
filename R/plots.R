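# ggplot2 displays for the three result types.

#' Plot block or variable importance of a multiblock model
#'
#' Horizontal bars of the importance indices with the equal-share threshold
#' line (`1/K` or `1/P`); bootstrap tolerance intervals are drawn when a
#' [mbra_bootstrap()] result is supplied.
#'
#' @param object A fitted [mbra_fit()] model.
#' @param level `"block"` or `"variable"`.
#' @param boot Optional [mbra_bootstrap()] result for error bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbra <- function(object, level = c("block", "variable"),
                          boot = NULL, ...) {
  level <- match.arg(level)
  df <- if (level == "block") {
    block_importance(object) |> rename(term = "block")
  } else {
    variable_importance(object) |> rename(term = "variable")
  }
  if (!is.null(boot)) {
    iv <- if (level == "block") {
      boot$block_intervals |> rename(term = "block")
    } else {
      boot$variable_intervals |> rename(term = "variable")
    }
    df <- left_join(df, iv |> select("term", "lo", "hi"), by = "term")
  }
  thr <- df$threshold[1]
  p <- ggplot(df, aes(x = .data$importance,
                      y = stats::reorder(.data$term, .data$importance),
                      fill = .data$flag)) +
    geom_col(show.legend = FALSE) +
    geom_vline(xintercept = thr, linetype = "dashed") +
    scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    labs(x = sprintf("%s importance (threshold %.3f)", level, thr), y = NULL)
  if (!is.null(boot)) {
    p <- p + geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.25)
  }
  p
}

#' Plot variation partitioning fractions
#'
#' @param object A [varpart2()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.varpart2 <- function(object, ...) {
  df <- object$fractions |>
    mutate(label = factor(.data$label,
                          levels = c("pure abiotic", "shared", "pure biotic",
                                     "unexplained")))
  ggplot(df, aes(x = .data$label, y = .data$r2_adj, fill = .data$label)) +
    geom_col(show.legend = FALSE) +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "adjusted R² fraction")
}

#' Plot pairwise co-occurrence screening results
#'
#' Observed pair C-scores against their standardized effect sizes, coloured
#' by classification, with mean-Bayes-retained pairs emphasised.
#'
#' @param object A [pairwise_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$ses, y = .data$c_obs,
                 colour = .data$classification)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_point(data = df |> filter(.data$bayesm_flag),
               shape = 21, size = 2.5, stroke = 0.8) +
    scale_colour_manual(values = c(segregated = "#b2182b",
                                   aggregated = "#2166ac",
                                   random = "grey65")) +
    labs(x = "standardized effect size", y = "pair C-score",
         colour = NULL)
}
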