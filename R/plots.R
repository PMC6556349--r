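# ggplot2 displays for the tabular result types.

#' Plot the LAA volume-time curve
#'
#' Volume against cardiac phase with the automatically detected diastolic
#' (maximum) and systolic (minimum) phases marked.
#'
#' @param object A `laa_function` from [ejection_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot laa_function
#' @export
autoplot.laa_function <- function(object, ...) {
  df <- tidy(object)
  marks <- df[df$is_diastole | df$is_systole, ]
  marks$phase <- ifelse(marks$is_diastole, "diastole", "systole")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_percent, y = .data$volume_cm3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(colour = .data$phase), size = 3) +
    ggplot2::labs(x = "cardiac phase (% RR interval)",
                  y = expression("LAA volume (" * cm^3 * ")"),
                  colour = NULL,
                  title = sprintf("LAA volume curve, EF = %.1f%%",
                                  object$ef_percent)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Paired differences against paired means with the bias line and 95% limits
#' of agreement.
#'
#' @param object A `laa_bland_altman` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot laa_bland_altman
#' @export
autoplot.laa_bland_altman <- function(object, ...) {
  df <- attr(object, "data")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of paired measurements",
                  y = "difference (m1 - m2)",
                  title = sprintf("Bland-Altman: bias %.3f, LoA %s",
                                  object$bias, object$interval)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
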