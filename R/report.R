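#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted disease-course model
#'
#' One row per scalar parameter: `t0`, the variance components, the prior
#' hyper-parameters, and the fitted position/velocity field values at every
#' node (`p_node_<k>`, `v_node_<k>`) obtained by kernel interpolation of
#' the estimated control-node values.
#'
#' @param x A `course_fit`.
#' @param ... Unused.
#' @return A tibble (`term`, `estimate`).
#' @export
tidy.course_fit <- function(x, ...) {
  p <- x$params
  fl <- param_fields(p, x$graph)
  K <- n_nodes(x$graph)
  tibble::tibble(
    term = c(
      "t0", "sigma_tau2", "sigma_xi2", "sigma2",
      "p_bar", "v_bar", "sigma_p2", "sigma_v2", "sigma_beta2",
      paste0("p_ctrl_", seq_along(p$p_ctrl)),
      paste0("v_ctrl_", seq_along(p$v_ctrl)),
      paste0("p_node_", seq_len(K)),
      paste0("v_node_", seq_len(K))
    ),
    estimate = c(
      p$t0, p$sigma_tau2, p$sigma_xi2, p$sigma2,
      p$p_bar, p$v_bar, p$sigma_p2, p$sigma_v2, p$sigma_beta2,
      p$p_ctrl, p$v_ctrl, fl$p_nodes, fl$v_nodes
    )
  )
}

#' One-row summary of a fitted disease-course model
#'
#' @param x A `course_fit`.
#' @param ... Unused.
#' @return A tibble with data shape, iteration counts, the final noise
#'   standard deviation, final log-likelihood term, and the mean sampling
#'   acceptance rate.
#' @export
glance.course_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subjects), n_obs = x$n_obs,
    n_nodes = n_nodes(x$graph), n_sources = x$params$n_sources,
    n_iter = x$control$n_iter, n_burn_in = x$control$n_burn_in,
    sigma = sqrt(x$params$sigma2), log_lik = x$log_lik,
    mean_accept = mean(x$accept$rate_sampling, na.rm = TRUE)
  )
}

#' Trace plot of an MCMC-SAEM fit
#'
#' Per-iteration traces of the scalar parameters (and optionally the
#' control-node values), the standard convergence diagnostic for the
#' stochastic algorithm.
#'
#' @param object A `course_fit`.
#' @param parameters Character vector of trace names to show (default: the
#'   main scalar parameters).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.course_fit <- function(object,
                                parameters = c("t0", "sigma2", "sigma_tau2",
                                               "sigma_xi2", "log_lik"),
                                ...) {
  df <- dplyr::filter(object$traces, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of reconstruction errors
#'
#' @param object A `course_error_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.course_error_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$mid[1:2]) * 0.95) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "relative reconstruction error", y = "count") +
    ggplot2::theme_minimal()
}

#' Map of per-node mean reconstruction error on the graph
#'
#' @param report A `course_error_report`.
#' @param graph The `netcourse_graph` (for node coordinates).
#' @return A ggplot object (nodes at their x/y coordinates, colored by
#'   mean relative error).
#' @export
plot_error_map <- function(report, graph) {
  df <- dplyr::left_join(report$per_node, graph$nodes, by = "node")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$mean_rel_error)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_gradient2() +
    ggplot2::labs(color = "mean rel. error") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
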