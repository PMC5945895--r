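#' Square-grid network graph
#'
#' Builds the side x side lattice used by the parameter-recovery simulation
#' study: nodes at integer coordinates (row-major, x varying fastest, node 1
#' at the origin), 4-connectivity with unit edges, so geodesic distances are
#' Manhattan distances. For `side >= 3`, the 9 control nodes are the 3 x 3
#' subgrid at rows/columns `{0, floor(side/2), side - 1}`.
#'
#' @param side Nodes per edge (>= 2).
#' @return A `netcourse_graph` with `side^2` nodes.
#' @examples
#' g <- make_grid_graph(7)
#' nrow(g$nodes)      # 49
#' length(g$control)  # 9
#' @export
make_grid_graph <- function(side) {
  if (side < 2) abort("`side` must be at least 2.")
  xy <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
  D <- abs(outer(xy$x, xy$x, "-")) + abs(outer(xy$y, xy$y, "-"))
  nodes <- tibble::tibble(node = seq_len(side^2), x = xy$x, y = xy$y, z = 0)
  ctrl <- integer(0)
  if (side >= 3) {
    pos <- c(0, side %/% 2, side - 1)
    ctrl <- which(xy$x %in% pos & xy$y %in% pos)
  }
  network_graph(nodes, D, control = ctrl)
}

#' Ground truth of the square-grid simulation study
#'
#' Returns the true population parameters used by the grid
#' parameter-recovery experiment. The position and velocity fields are
#' exactly kernel-representable (values at the 9 control nodes, Gaussian
#' kernel with the grid-matched bandwidth 3) and are anchored so that the
#' interpolated field takes prescribed values at six probe nodes:
#' positions 3.0 / 3.714 / 3.9 at nodes 2 / 21 / 47 and velocities
#' 0.03 / 0.0625 / 0.078 at nodes 5 / 22 / 42 (1-based indices on the
#' 49-node grid). The control values are the minimum-norm correction of a
#' smooth planar base field satisfying those anchors, so the truth is
#' deterministic. Scalar truths: `t0 = 70`, `sigma_tau2 = 25`,
#' `sigma_xi2 = 0.15`, `sigma2 = 1e-5`, `n_sources = 2` with a fixed smooth
#' mixing pattern.
#'
#' @param side Grid side (default 7).
#' @param bandwidth Kernel bandwidth (default 3, the control-node spacing).
#' @return A list with `graph`, `params` (a [course_params()]), and
#'   `probes` (tibble of anchored probe nodes and their true values).
#' @export
grid_replica_truth <- function(side = 7, bandwidth = 3) {
  graph <- make_grid_graph(side)
  K <- n_nodes(graph)
  E <- field_evaluator(graph, bandwidth)
  xy <- graph$nodes

  # probe anchors (Table-style): 1-based node indices on the side^2 grid
  p_probe <- c(2L, 21L, 47L)
  p_anchor <- c(3.0, 3.714, 3.9)
  v_probe <- c(5L, 22L, 42L)
  v_anchor <- c(0.03, 0.0625, 0.078)

  anchored_field <- function(base_ctrl, probe, anchor) {
    M <- E[probe, , drop = FALSE]
    r <- anchor - as.numeric(M %*% base_ctrl)
    base_ctrl + as.numeric(t(M) %*% solve(M %*% t(M), r))
  }
  # planar bases through the anchor values
  p_base <- 2.8965 + 0.1035 * xy$x + 0.09825 * xy$y
  v_base <- 0.032846 - 0.0007115 * xy$x + 0.009885 * xy$y
  p_ctrl <- anchored_field(p_base[graph$control], p_probe, p_anchor)
  v_ctrl <- anchored_field(v_base[graph$control], v_probe, v_anchor)

  n_sources <- 2L
  l <- seq_len(K - 1)
  beta <- c(0.05 * sin(2 * pi * l / (K - 1)),
            0.05 * cos(4 * pi * l / (K - 1)))

  params <- course_params(
    t0 = 70, p_ctrl = p_ctrl, v_ctrl = v_ctrl, beta = beta,
    n_sources = n_sources, sigma_tau2 = 25, sigma_xi2 = 0.15,
    sigma2 = 1e-5, bandwidth = bandwidth
  )
  probes <- tibble::tibble(
    parameter = c("p_node_2", "p_node_21", "p_node_47",
                  "v_node_5", "v_node_22", "v_node_42"),
    node = c(p_probe, v_probe),
    field = rep(c("position", "velocity"), each = 3),
    truth = c(p_anchor, v_anchor)
  )
  list(graph = graph, params = params, probes = probes)
}

#' Simulate a longitudinal dataset from a disease-course model
#'
#' Draws individual random effects `xi_i ~ N(0, sigma_xi2)`,
#' `tau_i ~ N(0, sigma_tau2)`, `s_ij ~ Laplace(0, 1/2)` (scale 1/2), visit
#' counts uniform on `visit_range`, a first visit uniform on
#' `t0 + tau_i + first_visit_window`, subsequent visits at
#' `visit_spacing`-year intervals, and observations from the forward model
#' plus `N(0, sigma2)` noise.
#'
#' @param params True population parameters (a [course_params()]).
#' @param graph The model graph.
#' @param n_subjects Number of subjects.
#' @param visit_range Integer range of visits per subject, e.g. `c(4, 12)`.
#' @param first_visit_window Offset window (years) of the first visit
#'   relative to `t0 + tau_i`; default `c(-5, 0)` mimics observation
#'   windows that are short relative to the disease course.
#' @param visit_spacing Years between successive visits (default 1).
#' @param diag_stage_offset If non-`NULL`, adds a `t_diag` column: the age
#'   at which the subject's warped age equals `t0 + diag_stage_offset`,
#'   i.e. diagnosis pinned to a fixed disease stage.
#' @param seed Optional integer seed (fully reproducible draws).
#' @return A list with `data` (wide tibble `subject_id`, `age`,
#'   `node_1..node_K`, plus `t_diag` if requested), `ind` (true individual
#'   parameters), and `params` (the truth, passed through).
#' @export
simulate_course <- function(params, graph, n_subjects,
                            visit_range = c(4L, 12L),
                            first_visit_window = c(-5, 0),
                            visit_spacing = 1,
                            diag_stage_offset = NULL,
                            seed = NULL) {
  if (any(visit_range < 1L) || visit_range[2] < visit_range[1]) {
    abort("`visit_range` must be a valid range of counts >= 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  I <- n_subjects
  Ns <- params$n_sources
  xi <- rnorm(I, 0, sqrt(params$sigma_xi2))
  tau <- rnorm(I, 0, sqrt(params$sigma_tau2))
  S <- if (Ns > 0) matrix(rlaplace(I * Ns, scale = 0.5), Ns, I) else
    matrix(0, 0, I)
  alpha <- exp(xi)

  J <- sample(seq(visit_range[1], visit_range[2]), I, replace = TRUE)
  first <- params$t0 + tau +
    runif(I, first_visit_window[1], first_visit_window[2])
  fl <- param_fields(params, graph)
  W <- if (Ns > 0) fl$A %*% S else matrix(0, n_nodes(graph), I)

  rows <- vector("list", I)
  sdev <- sqrt(params$sigma2)
  for (i in seq_len(I)) {
    ages <- first[i] + visit_spacing * (seq_len(J[i]) - 1)
    dt <- alpha[i] * (ages - tau[i] - params$t0)
    pred <- matrix(fl$p_nodes + W[, i], J[i], n_nodes(graph), byrow = TRUE) +
      outer(dt, fl$v_nodes)
    obs <- pred + matrix(rnorm(length(pred), 0, sdev), nrow(pred))
    colnames(obs) <- paste0("node_", seq_len(ncol(obs)))
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%04d", i), age = ages),
      tibble::as_tibble(obs)
    )
  }
  data <- dplyr::bind_rows(rows)
  ind <- tibble::tibble(subject_id = sprintf("S%04d", seq_len(I)),
                        xi = xi, tau = tau)
  if (Ns > 0) {
    for (j in seq_len(Ns)) ind[[paste0("s_", j)]] <- S[j, ]
  }
  if (!is.null(diag_stage_offset)) {
    t_diag <- params$t0 + tau + diag_stage_offset / alpha
    data <- dplyr::left_join(
      data,
      tibble::tibble(subject_id = ind$subject_id, t_diag = t_diag),
      by = "subject_id"
    )
    ind$t_diag <- t_diag
  }
  list(data = as_course_data(data), ind = ind, params = params)
}

# Laplace(0, scale) draws via inverse CDF (uses the R RNG stream)
rlaplace <- function(n, scale = 0.5) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

dlaplace_log <- function(x, scale = 0.5) -log(2 * scale) - abs(x) / scale

#' Score recovered parameters against a known truth
#'
#' Builds the recovery table of a simulation study: one row per parameter
#' with its estimate, truth, and relative error
#' `|estimate - truth| / |truth| * 100` (percent). Parameters with zero
#' truth are scored by absolute error and flagged.
#'
#' @param estimates Named numeric vector (or single-level list) of
#'   estimated parameters.
#' @param truth Named numeric vector of true values (names matched to
#'   `estimates`).
#' @return A tibble (`parameter`, `estimate`, `truth`, `error`,
#'   `error_type`): `error` is the relative error in percent, or the
#'   absolute error where `truth == 0` (`error_type = "absolute"`).
#' @export
recovery_score <- function(estimates, truth) {
  estimates <- unlist(estimates)
  common <- intersect(names(estimates), names(truth))
  if (length(common) == 0L) abort("No common parameter names.")
  est <- estimates[common]
  tr <- unlist(truth)[common]
  zero <- tr == 0
  err <- ifelse(zero, abs(est - tr), abs(est - tr) / abs(tr) * 100)
  tibble::tibble(
    parameter = common, estimate = unname(est), truth = unname(tr),
    error = unname(err),
    error_type = unname(ifelse(zero, "absolute", "relative_pct"))
  )
}
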