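# broom-style tidiers and plots for report objects.

#' @describeIn uei_report `tidy()` returns the per-metric value/level
#'   tibble.
#' @param x A `uei_report`.
#' @param ... Unused.
#' @method tidy uei_report
#' @export
tidy.uei_report <- function(x, ...) x$levels

#' @describeIn uei_report `glance()` returns a one-row summary with the
#'   four objective metrics, the MAUQ mean/SD and the feasibility verdict.
#' @method glance uei_report
#' @export
glance.uei_report <- function(x, ...) {
  dplyr::bind_cols(
    x$objective,
    tibble(mauq_mean = if (is.null(x$mauq)) NA_real_ else x$mauq$mean,
           mauq_sd = if (is.null(x$mauq)) NA_real_ else x$mauq$sd,
           mauq_n = if (is.null(x$mauq)) 0L else x$mauq$n_respondents,
           verdict = x$verdict)
  )
}

#' @describeIn uei_report `autoplot()` shows the objective metrics against
#'   the high/low cutoff.
#' @param object A `uei_report`.
#' @method autoplot uei_report
#' @export
autoplot.uei_report <- function(object, ...) {
  d <- object$levels[object$levels$metric != "mauq_mean", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value,
                                  fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction",
                  title = "Objective user-engagement indicators") +
    ggplot2::theme_minimal()
}

#' @describeIn score_mauq `tidy()` returns the per-statement agreement
#'   tibble.
#' @param x A `mauq_summary`.
#' @param ... Unused.
#' @method tidy mauq_summary
#' @export
tidy.mauq_summary <- function(x, ...) x$agreement

#' @describeIn score_mauq `glance()` returns a one-row mean/SD/n summary.
#' @method glance mauq_summary
#' @export
glance.mauq_summary <- function(x, ...) {
  tibble(mauq_mean = x$mean, mauq_sd = x$sd, n_respondents = x$n_respondents,
         statements_full_agreement = sum(x$agreement$agreement == 1))
}
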