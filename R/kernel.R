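#' Gaussian interpolation kernel
#'
#' `K_b(x, y) = exp(-d(x, y)^2 / b^2)` where `d` is the geodesic distance
#' and `b` the bandwidth. This is the smoothing kernel used to interpolate
#' position and velocity values from the control nodes to every node.
#'
#' @param dist Non-negative distance(s).
#' @param bandwidth Kernel bandwidth `b` (> 0), same units as `dist`.
#' @return Kernel weight(s) in (0, 1].
#' @examples
#' gaussian_kernel(0, 16)   # 1
#' gaussian_kernel(16, 16)  # exp(-1)
#' @export
gaussian_kernel <- function(dist, bandwidth) {
  if (any(bandwidth <= 0)) abort("`bandwidth` must be positive.")
  if (any(dist < 0)) abort("`dist` must be non-negative.")
  exp(-(dist^2) / bandwidth^2)
}

#' Kernel-interpolated scalar field over a graph
#'
#' Represents a smooth field `f(x) = sum_i beta_i K_b(x, x_di)` anchored at
#' the graph's control nodes: the coefficients `beta` solve the linear
#' system `Gram beta = control_values`, so the field reproduces the control
#' values exactly at the control nodes. Away from all control nodes the
#' field decays to 0 (the interpolation is not a partition of unity).
#'
#' If the Gram matrix is ill-conditioned (condition number > 1e10, e.g.
#' near-coincident control nodes), a ridge `lambda I` with
#' `lambda = 1e-9 trace / N_c` is added before solving.
#'
#' @param graph A `netcourse_graph` with control nodes set.
#' @param control_values Numeric vector of field values at the control
#'   nodes, in control-node order.
#' @param bandwidth Kernel bandwidth (> 0).
#' @return An object of class `kernel_field` with elements `control`
#'   (indices), `values`, `coef`, `bandwidth`, `gram`.
#' @export
kernel_field <- function(graph, control_values, bandwidth) {
  stopifnot(inherits(graph, "netcourse_graph"))
  ctrl <- graph$control
  if (length(ctrl) == 0L) abort("Graph has no control nodes.")
  if (length(control_values) != length(ctrl)) {
    abort("`control_values` must match the number of control nodes.")
  }
  G <- kernel_gram(graph, bandwidth)
  coef <- solve_gram(G, control_values)
  structure(
    list(
      control = ctrl, values = as.numeric(control_values),
      coef = as.numeric(coef), bandwidth = bandwidth, gram = G
    ),
    class = "kernel_field"
  )
}

kernel_gram <- function(graph, bandwidth) {
  gaussian_kernel(graph$dist[graph$control, graph$control, drop = FALSE],
                  bandwidth)
}

solve_gram <- function(G, values) {
  if (rcond(G) < 1e-10) {
    G <- G + diag(1e-9 * sum(diag(G)) / nrow(G), nrow(G))
  }
  tryCatch(
    solve(G, values),
    error = function(e) abort("Kernel Gram matrix is singular even after regularization.")
  )
}

#' Evaluate a kernel field at graph nodes
#'
#' @param field A `kernel_field`.
#' @param graph The graph the field was fitted on.
#' @param nodes Node indices at which to evaluate (default: all nodes).
#' @return Numeric vector of field values.
#' @export
evaluate_field <- function(field, graph, nodes = seq_len(n_nodes(graph))) {
  if (any(nodes < 1L) || any(nodes > n_nodes(graph))) {
    abort("Node index out of range.")
  }
  Kx <- gaussian_kernel(graph$dist[nodes, field$control, drop = FALSE],
                        field$bandwidth)
  as.numeric(Kx %*% field$coef)
}

# Linear operator mapping control values to node values:
# E = K_b(nodes, controls) %*% Gram^{-1}. Precomputed once per fit so that
# node fields are a single matrix-vector product per SAEM iteration.
field_evaluator <- function(graph, bandwidth, nodes = seq_len(n_nodes(graph))) {
  G <- kernel_gram(graph, bandwidth)
  if (rcond(G) < 1e-10) {
    G <- G + diag(1e-9 * sum(diag(G)) / nrow(G), nrow(G))
  }
  Kx <- gaussian_kernel(graph$dist[nodes, graph$control, drop = FALSE], bandwidth)
  Kx %*% solve(G)
}

#' Serialize a kernel field to CSV + JSON header
#'
#' Writes `<stem>.csv` with columns (`control`, `value`, `coefficient`) and
#' `<stem>.json` carrying the bandwidth.
#'
#' @param field A `kernel_field`.
#' @param stem Output path stem (without extension).
#' @return The stem, invisibly.
#' @export
write_kernel_field <- function(field, stem) {
  write.csv(
    data.frame(control = field$control, value = field$values,
               coefficient = field$coef),
    paste0(stem, ".csv"), row.names = FALSE
  )
  jsonlite::write_json(list(bandwidth = field$bandwidth),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
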