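# Shared fixtures, all generated in code.

# small path graph as a netcourse_graph (unit spacing)
path_graph <- function(n) {
  nodes <- tibble::tibble(node = seq_len(n), x = seq_len(n) - 1, y = 0, z = 0)
  D <- abs(outer(nodes$x, nodes$x, "-"))
  network_graph(nodes, D)
}

# tiny simulated study: few subjects on a small grid, known truth
tiny_sim <- function(n_subjects = 8, side = 3, n_sources = 1L,
                     sigma2 = 1e-6, sigma_tau2 = 9, sigma_xi2 = 0.05,
                     seed = 42) {
  graph <- make_grid_graph(side)
  K <- side^2
  params <- course_params(
    t0 = 70,
    p_ctrl = 3 + 0.1 * seq_along(graph$control),
    v_ctrl = 0.05 + 0.005 * seq_along(graph$control),
    beta = rep(0.05, (K - 1) * n_sources),
    n_sources = n_sources,
    sigma_tau2 = sigma_tau2, sigma_xi2 = sigma_xi2, sigma2 = sigma2,
    bandwidth = 2
  )
  sim <- simulate_course(params, graph, n_subjects, visit_range = c(4L, 6L),
                         seed = seed)
  list(graph = graph, params = params, sim = sim)
}

# brute-force all-pairs shortest path by path enumeration on tiny graphs
# (Floyd-Warshall over the adjacency; independent of igraph)
brute_shortest_paths <- function(adj) {
  n <- nrow(adj)
  D <- adj
  D[D == 0 & row(D) != col(D)] <- Inf
  for (m in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, m] + D[m, ])
    }
  }
  D
}

# write a small ASCII OFF mesh file, return path
write_off_fixture <- function(vertices, faces) {
  path <- tempfile(fileext = ".off")
  lines <- c(
    "OFF",
    paste(nrow(vertices), nrow(faces), 0),
    apply(vertices, 1, paste, collapse = " "),
    apply(cbind(3, faces - 1), 1, paste, collapse = " ")
  )
  writeLines(lines, path)
  path
}

write_ply_fixture <- function(vertices, faces) {
  path <- tempfile(fileext = ".ply")
  lines <- c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(faces)),
    "property list uchar int vertex_indices",
    "end_header",
    apply(vertices, 1, paste, collapse = " "),
    apply(cbind(3, faces - 1), 1, paste, collapse = " ")
  )
  writeLines(lines, path)
  path
}
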