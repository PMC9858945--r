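#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline labs
#'   theme_minimal facet_wrap geom_col geom_errorbar
NULL

#' @export
ggplot2::autoplot

#' Scatter of paired FFD and NC values against the equality line
#'
#' One point per comparison record; the red equality line separates
#' contexts where the FFD value exceeds the NC value from the rest. When
#' the records carry a `base` column, points are coloured by the weak
#' (A/T) vs strong (G/C) class of the substituted base.
#'
#' @param object A `ctx_comparison` from [compare_contexts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ctx_comparison <- function(object, ...) {
  rec <- object$records
  q <- object$summary$quantity
  p <- if ("base" %in% names(rec)) {
    ggplot(rec, aes(x = .data$value_nc, y = .data$value_ffd,
                    colour = ifelse(.data$base %in% c("A", "T"),
                                    "A/T (W)", "G/C (S)"))) +
      labs(colour = "substituted base")
  } else {
    ggplot(rec, aes(x = .data$value_nc, y = .data$value_ffd))
  }
  p +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    labs(
      x = paste("NC", q), y = paste("FFD", q),
      title = sprintf("FFD vs NC %s (FFD higher in %.1f%% of %d pairs)",
                      q, 100 * object$summary$prop_higher, object$summary$n)
    ) +
    theme_minimal()
}

#' Equilibrium A+T content per context with bootstrap uncertainty
#'
#' @param object A `ctx_equilibrium` from [equilibrium_profile()].
#' @param ... Unused.
#' @return A ggplot: contexts ordered by equilibrium A+T, error bars at
#'   plus/minus one bootstrap SD where available.
#' @export
autoplot.ctx_equilibrium <- function(object, ...) {
  d <- as_tibble(object) |>
    dplyr::filter(.data$flag == "ok") |>
    dplyr::mutate(context = stats::reorder(.data$context, .data$AT_eq))
  p <- ggplot(d, aes(x = .data$context, y = .data$AT_eq)) +
    geom_point(size = 0.8)
  if (any(!is.na(d$AT_boot_sd))) {
    p <- p + geom_errorbar(aes(ymin = .data$AT_eq - .data$AT_boot_sd,
                               ymax = .data$AT_eq + .data$AT_boot_sd),
                           width = 0, alpha = 0.4)
  }
  p +
    facet_wrap(~site_class, scales = "free_x") +
    labs(x = "tetranucleotide context", y = "equilibrium A+T") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Substitution-class breakdown bar chart
#'
#' Proportion of contexts in which the FFD class rate exceeds the NC class
#' rate, per substitution class, with the even-chance line at 0.5.
#'
#' @param breakdown Tibble from [class_breakdown()].
#' @return A ggplot.
#' @export
plot_class_breakdown <- function(breakdown) {
  ggplot(breakdown,
         aes(x = factor(.data$sub_class, levels = substitution_classes()),
             y = .data$prop_higher)) +
    geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "red") +
    labs(x = "substitution class", y = "proportion of contexts FFD > NC") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
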