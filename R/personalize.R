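#' Personalize a fitted model to subjects
#'
#' Estimates individual parameters `(xi, tau, s)` for each subject in
#' `data`, holding the population parameters fixed. The default `"map"`
#' mode maximizes the per-subject log-posterior
#' `log p(y_i | z_i, theta) + log p(z_i | theta)` from a zero start
#' (Nelder-Mead search followed by a quasi-Newton polish), and is
#' deterministic. The `"mean"` mode returns posterior means from a
#' Metropolis chain with frozen parameters (see [posterior_sample_ind()]).
#'
#' @param data Dataset of the subjects to personalize (new or training).
#' @param params A fitted `course_params` (e.g. `fit$params`).
#' @param graph The model graph.
#' @param mode `"map"` (default) or `"mean"`.
#' @param ... Passed to [posterior_sample_ind()] in `"mean"` mode.
#' @return A tibble (`subject_id`, `xi`, `tau`, `s_1..s_Ns`, `converged`).
#'   Non-converged optimizations return the best iterate with
#'   `converged = FALSE`.
#' @export
personalize <- function(data, params, graph, mode = c("map", "mean"), ...) {
  mode <- match.arg(mode)
  data <- as_course_data(data)
  if (mode == "mean") {
    out <- posterior_sample_ind(data, params, graph, ...)$mean
    out$converged <- TRUE
    return(out)
  }
  dm <- data_matrices(data)
  fl <- param_fields(params, graph)
  Ns <- params$n_sources
  I <- length(dm$subjects)
  res <- matrix(0, I, 2 + Ns)
  conv <- logical(I)
  for (i in seq_len(I)) {
    sel <- dm$subj == i
    Yi <- dm$Y[sel, , drop = FALSE]
    ti <- dm$t[sel]
    neg_post <- function(z) {
      xi <- z[1]; tau <- z[2]
      w <- if (Ns > 0) as.numeric(fl$A %*% z[-(1:2)]) else 0
      dt <- exp(xi) * (ti - tau - params$t0)
      Ri <- Yi - matrix(fl$p_nodes + w, nrow(Yi), dm$K, byrow = TRUE) -
        outer(dt, fl$v_nodes)
      0.5 * sum(Ri^2) / params$sigma2 +
        xi^2 / (2 * params$sigma_xi2) + tau^2 / (2 * params$sigma_tau2) +
        if (Ns > 0) 2 * sum(abs(z[-(1:2)])) else 0
    }
    o <- optim(rep(0, 2 + Ns), neg_post, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-14))
    o2 <- suppressWarnings(
      optim(o$par, neg_post, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-14))
    )
    if (o2$value <= o$value) o <- o2
    res[i, ] <- o$par
    conv[i] <- o$convergence == 0
  }
  out <- tibble::tibble(subject_id = dm$subjects, xi = res[, 1], tau = res[, 2])
  if (Ns > 0) for (j in seq_len(Ns)) out[[paste0("s_", j)]] <- res[, 2 + j]
  out$converged <- conv
  out
}

#' Reconstruct or extrapolate individual trajectories
#'
#' Evaluates each subject's fitted trajectory at requested ages. Ages
#' outside the subject's observed range are flagged as extrapolations.
#'
#' @param ind Individual parameters (from [personalize()] or `fit$ind`).
#' @param params Fitted `course_params`.
#' @param graph Model graph.
#' @param ages Either a numeric vector of ages applied to every subject, or
#'   a data frame (`subject_id`, `age`).
#' @param observed Optional dataset used to flag extrapolation beyond each
#'   subject's observed age range.
#' @return A long tibble (`subject_id`, `age`, `node`, `value`,
#'   `extrapolated`).
#' @export
reconstruct <- function(ind, params, graph, ages, observed = NULL) {
  fl <- param_fields(params, graph)
  K <- n_nodes(graph)
  if (is.data.frame(ages)) {
    req <- dplyr::select(ages, "subject_id", "age")
  } else {
    req <- tidyr::expand_grid(subject_id = ind$subject_id, age = ages)
  }
  rng <- NULL
  if (!is.null(observed)) {
    rng <- dplyr::summarise(
      dplyr::group_by(as_course_data(observed), .data$subject_id),
      .min = min(.data$age), .max = max(.data$age), .groups = "drop"
    )
  }
  iv <- ind_vectors(ind, ind$subject_id, params$n_sources)
  idx <- match(req$subject_id, ind$subject_id)
  if (anyNA(idx)) abort("Requested subject missing from `ind`.")
  W <- if (params$n_sources > 0) fl$A %*% iv$S else matrix(0, K, nrow(ind))
  dt <- exp(iv$xi[idx]) * (req$age - iv$tau[idx] - params$t0)
  pred <- matrix(fl$p_nodes, nrow(req), K, byrow = TRUE) +
    t(W)[idx, , drop = FALSE] + outer(dt, fl$v_nodes)
  out <- dplyr::bind_cols(
    req,
    tibble::as_tibble(pred, .name_repair = ~ paste0("node_", seq_len(K)))
  )
  out <- tidyr::pivot_longer(out, dplyr::starts_with("node_"),
                             names_to = "node", values_to = "value")
  out$node <- as.integer(sub("node_", "", out$node))
  if (!is.null(rng)) {
    out <- dplyr::left_join(out, rng, by = "subject_id")
    out$extrapolated <- out$age < out$.min | out$age > out$.max
    out$.min <- out$.max <- NULL
  } else {
    out$extrapolated <- NA
  }
  out
}

#' Reconstruction-error report
#'
#' Compares model reconstructions with the observed data at the observed
#' ages. The relative error of a scalar observation is
#' `(predicted - observed) / observed`; observations equal to zero are
#' excluded (their count is reported). The report carries the
#' per-observation errors, per-node mean errors, a histogram, and a
#' one-sample t test of the zero-mean hypothesis for the relative error.
#'
#' @param data Observed dataset.
#' @param ind Individual parameters for the subjects in `data`.
#' @param params Fitted `course_params`.
#' @param graph Model graph.
#' @param bins Number of histogram bins.
#' @return An object of class `course_error_report`: list with `per_obs`,
#'   `per_node`, `histogram`, `summary` (mean, sd, t statistic, p value),
#'   `n_excluded`.
#' @export
error_report <- function(data, ind, params, graph, bins = 50) {
  data <- as_course_data(data)
  dm <- data_matrices(data)
  fl <- param_fields(params, graph)
  iv <- ind_vectors(ind, dm$subjects, params$n_sources)
  R <- residual_matrix(dm, fl, params$t0, iv$xi, iv$tau, iv$S)
  pred <- dm$Y - R
  rel <- (pred - dm$Y) / dm$Y
  keep <- dm$Y != 0
  n_excluded <- sum(!keep)
  rel[!keep] <- NA
  per_obs <- tibble::tibble(
    subject_id = rep(data$subject_id, dm$K),
    age = rep(data$age, dm$K),
    node = rep(seq_len(dm$K), each = nrow(dm$Y)),
    observed = as.numeric(dm$Y),
    predicted = as.numeric(pred),
    rel_error = as.numeric(rel)
  )
  per_node <- tibble::tibble(
    node = seq_len(dm$K),
    mean_rel_error = colMeans(rel, na.rm = TRUE)
  )
  x <- rel[keep]
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  tt <- t.test(x, mu = 0)
  structure(
    list(
      per_obs = per_obs, per_node = per_node,
      histogram = tibble::tibble(
        mid = h$mids, count = h$counts,
        lower = utils::head(h$breaks, -1), upper = h$breaks[-1]
      ),
      summary = tibble::tibble(
        n = length(x), mean = mean(x), sd = sd(x),
        t_statistic = unname(tt$statistic), p_value = tt$p.value
      ),
      n_excluded = n_excluded
    ),
    class = "course_error_report"
  )
}

#' @export
print.course_error_report <- function(x, ...) {
  cat("<course_error_report> n =", x$summary$n,
      "| mean rel. error =", format(x$summary$mean, digits = 3),
      "| sd =", format(x$summary$sd, digits = 3),
      "| excluded (zero obs):", x$n_excluded, "\n")
  invisible(x)
}

#' Compare individual parameters across groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of each individual
#' parameter between every pair of groups, the standard nonparametric
#' comparison for e.g. genotype subgroups.
#'
#' @param ind Individual-parameter table (must contain `subject_id` and
#'   numeric parameter columns).
#' @param groups A data frame (`subject_id`, `group`) or a vector aligned
#'   with `ind`.
#' @param parameters Which parameter columns to test (default: `xi`, `tau`
#'   and any `s_*` columns present).
#' @return A tibble (`parameter`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `p_value`).
#' @export
compare_groups <- function(ind, groups, parameters = NULL) {
  if (is.data.frame(groups)) {
    g <- groups$group[match(ind$subject_id, groups$subject_id)]
  } else {
    g <- groups
  }
  if (anyNA(g)) abort("Every subject needs a group label.")
  lv <- sort(unique(as.character(g)))
  if (length(lv) < 2) abort("Need at least two groups.")
  parameters <- parameters %||%
    intersect(c("xi", "tau", grep("^s_\\d+$", names(ind), value = TRUE)),
              names(ind))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(parameters, function(p) {
    purrr::map_dfr(pairs, function(pr) {
      x <- ind[[p]][g == pr[1]]
      y <- ind[[p]][g == pr[2]]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                         exact = TRUE))
      tibble::tibble(
        parameter = p, group1 = pr[1], group2 = pr[2],
        n1 = length(x), n2 = length(y),
        statistic = unname(wt$statistic), p_value = wt$p.value
      )
    })
  })
}
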