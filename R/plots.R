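#' @export
autoplot.pls_profile <- function(object, alpha = NULL, df = NULL, ...) {
  alpha <- alpha %||% object$control$alpha
  df <- df %||% object$control$df
  threshold <- object$chi2_min + qchisq(1 - alpha, df)
  d <- tidy(object)
  ggplot2::ggplot(d[d$converged, ], ggplot2::aes(x = .data$value, y = .data$chi2_pl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$theta_hat[[object$param]],
                        colour = "steelblue") +
    ggplot2::labs(x = bquote(log[10] ~ .(object$param)),
                  y = expression(chi[PL]^2),
                  title = paste0("Profile likelihood of ", object$param)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pls_profiles <- function(object, alpha = NULL, df = NULL, ...) {
  first <- object[[1]]
  alpha <- alpha %||% first$control$alpha
  df <- df %||% first$control$df
  threshold <- first$chi2_min + qchisq(1 - alpha, df)
  d <- tidy(object)
  hats <- tibble(param = names(object),
                 hat = vapply(object, function(p) p$theta_hat[[p$param]],
                              numeric(1)))
  ggplot2::ggplot(d[d$converged, ], ggplot2::aes(x = .data$value, y = .data$chi2_pl)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_vline(data = hats, ggplot2::aes(xintercept = .data$hat),
                        colour = "steelblue") +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = expression(log[10] ~ theta[i]), y = expression(chi[PL]^2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pls_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$s)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = expression(s[i](t[k])),
                  title = paste0("PLS indices for prediction ", object$prediction)) +
    ggplot2::theme_minimal()
}

#' Criterion-space plot for design selection
#'
#' Plots candidates in the (s_tot, J_tot) plane; both coordinates are
#' maximised, and the nondominated (Pareto) candidates are highlighted.
#'
#' @param points Tibble with columns `s_tot`, `J_tot`, an id/prediction
#'   column, and optionally `pareto` (computed if absent).
#' @param label Column used to label points.
#' @return A ggplot object.
#' @export
plot_criterion_space <- function(points, label = intersect(c("id", "prediction"),
                                                           names(points))[1]) {
  if (!("pareto" %in% names(points))) points$pareto <- pareto_front(points)
  ggplot2::ggplot(points, ggplot2::aes(x = .data$s_tot, y = .data$J_tot)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pareto), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data[[label]]),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 name = "Pareto") +
    ggplot2::labs(x = expression(s[tot]), y = expression(J[tot])) +
    ggplot2::theme_minimal()
}
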