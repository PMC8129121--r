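#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' `tidy()` returns per-repetition mean metrics; `glance()` a one-row
#' summary with the mean and SD of sensitivity, specificity, balanced
#' accuracy and AUC plus the top-ranked feature combination.
#'
#' @param x a `cv_report`.
#' @param ... unused.
#' @export
tidy.cv_report <- function(x, ...) x$repetitions

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(s$mean, s$metric)))
  sdout <- tibble::as_tibble(as.list(stats::setNames(
    s$sd, paste0(s$metric, "_sd"))))
  dplyr::bind_cols(out, sdout,
                   tibble::tibble(top_combination = x$selection$combination[1],
                                  n_repeats = x$n_repeats))
}

#' @export
tidy.alpha_anova <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.alpha_ttest <- function(x, ...) tibble::as_tibble(unclass(x))

#' ROC curve plot with SD band and confidence interval
#'
#' @param object a `cv_report` or `roc_summary`.
#' @param ... unused.
#' @export
autoplot.cv_report <- function(object, ...) autoplot(object$roc, ...)

#' @rdname autoplot.cv_report
#' @export
autoplot.roc_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$tpr_mean - .data$tpr_sd),
      ymax = pmin(1, .data$tpr_mean + .data$tpr_sd)), alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$tpr_lo,
                                      ymax = .data$tpr_hi), alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Bar chart of feature-combination selection frequencies
#'
#' @param report a `cv_report`.
#' @param top_n show at most this many combinations.
#' @export
plot_selection_ranking <- function(report, top_n = 15) {
  sel <- utils::head(ranking_report(report), top_n)
  sel$combination <- stats::reorder(sel$combination, sel$frequency_pct)
  ggplot2::ggplot(sel, ggplot2::aes(.data$frequency_pct, .data$combination,
                                    fill = .data$scope)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Selection frequency (%)", y = NULL,
                  fill = "Hemisphere scope") +
    ggplot2::theme_minimal()
}
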