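#' Network graph of measurement nodes
#'
#' A `netcourse_graph` holds the fixed common graph on which longitudinal
#' signals live: node coordinates, a symmetric geodesic distance matrix, and
#' an ordered subset of control nodes at which the position and velocity
#' fields are parameterized. Node indices are 1-based everywhere, including
#' in all file formats written by the package.
#'
#' @param nodes A data frame with columns `node` (integer id, 1..K), `x`,
#'   `y`, `z` (coordinates, typically mm).
#' @param dist K x K symmetric, non-negative distance matrix with zero
#'   diagonal (geodesic distances between nodes).
#' @param control Integer vector of control-node indices (subset of 1..K,
#'   no duplicates). May be empty and set later with
#'   [select_control_nodes()].
#' @param patch_map Optional data frame (`vertex`, `node`) mapping dense
#'   mesh vertices to graph nodes, as produced by [subsample_mesh()].
#'
#' @return An object of class `netcourse_graph`: a list with elements
#'   `nodes` (tibble), `dist` (matrix), `control` (integer vector) and
#'   `patch_map` (tibble or `NULL`).
#' @examples
#' g <- make_grid_graph(3)
#' g$dist[1, 9] # opposite corners of a 3x3 grid: Manhattan distance 4
#' @export
network_graph <- function(nodes, dist, control = integer(), patch_map = NULL) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("node", "x", "y", "z") %in% names(nodes)))
  K <- nrow(nodes)
  dist <- as.matrix(dist)
  if (!isTRUE(all.equal(dim(dist), c(K, K)))) {
    abort("`dist` must be a K x K matrix matching `nodes`.")
  }
  if (max(abs(dist - t(dist))) > 1e-8) abort("`dist` must be symmetric.")
  if (any(diag(dist) != 0)) abort("`dist` must have a zero diagonal.")
  if (any(dist < 0)) abort("`dist` must be non-negative.")
  control <- as.integer(control)
  if (anyDuplicated(control) || any(control < 1L) || any(control > K)) {
    abort("`control` must be distinct node indices in 1..K.")
  }
  structure(
    list(
      nodes = nodes, dist = unname(dist), control = control,
      patch_map = if (!is.null(patch_map)) tibble::as_tibble(patch_map)
    ),
    class = "netcourse_graph"
  )
}

#' @export
print.netcourse_graph <- function(x, ...) {
  cat(
    "<netcourse_graph> ", nrow(x$nodes), " nodes, ",
    length(x$control), " control nodes, diameter ",
    format(max(x$dist), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$nodes)

#' Geodesic distance matrix of a mesh or weighted graph
#'
#' Computes all-pairs shortest-path (Dijkstra) distances along the edges of
#' a triangle mesh (edge weights are Euclidean edge lengths) or of an
#' arbitrary weighted [igraph::igraph] object. This graph-geodesic distance
#' stands in for a surface geodesic at the resolution of the mesh.
#'
#' @param x A mesh as returned by [read_mesh()] (list with `vertices`,
#'   `faces`) or an `igraph` object with a `weight` edge attribute.
#' @return A symmetric K x K matrix of shortest-path lengths.
#' @examples
#' m <- list(
#'   vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
#'   faces = matrix(c(1, 2, 3), 1)
#' )
#' geodesic_distance_matrix(m)
#' @export
geodesic_distance_matrix <- function(x) {
  g <- if (inherits(x, "igraph")) x else mesh_igraph(x)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    abort(paste0(
      "Input graph is disconnected (", comp$no, " components of sizes ",
      paste(comp$csize, collapse = ", "), ")."
    ))
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- NULL
  D
}

# Mesh -> edge-weighted igraph with Euclidean edge lengths.
mesh_igraph <- function(mesh) {
  v <- as.matrix(mesh$vertices)
  f <- as.matrix(mesh$faces)
  if (any(f < 1L) || any(f > nrow(v))) abort("Face indices out of range.")
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(1, 3), drop = FALSE])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(v)) {
    g <- igraph::add_vertices(g, nrow(v) - igraph::vcount(g))
  }
  g
}

#' Subsample a dense mesh into a network graph of patches
#'
#' Selects `target_K` approximately uniformly spread vertices by
#' farthest-point sampling on the graph-geodesic distance, then assigns
#' every dense vertex to its geodesically nearest selected node. The
#' resulting patches partition the vertex set; [patch_average()] carries a
#' dense per-vertex signal onto the subsampled graph.
#'
#' @param mesh A mesh (list with `vertices`, `faces`) or an `igraph` with
#'   `weight` edge attribute.
#' @param target_K Number of nodes to keep (positive, at most the vertex
#'   count).
#' @param seed Optional integer; when given, the farthest-point sampling is
#'   started from a seeded random vertex instead of vertex 1. Sampling is
#'   deterministic given the start.
#' @return A `netcourse_graph` whose `patch_map` maps every dense vertex to
#'   a node; ties in nearest-node assignment are broken by the lowest node
#'   index.
#' @export
subsample_mesh <- function(mesh, target_K, seed = NULL) {
  if (target_K <= 0) abort("`target_K` must be positive.")
  g <- if (inherits(mesh, "igraph")) mesh else mesh_igraph(mesh)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    abort(paste0("Mesh is disconnected (", comp$no, " components)."))
  }
  nv <- igraph::vcount(g)
  if (target_K > nv) abort("`target_K` exceeds the vertex count.")

  start <- 1L
  if (!is.null(seed)) {
    start <- withr_seed(seed, sample.int(nv, 1L))
  }
  sel <- integer(target_K)
  sel[1L] <- start
  # distance from each vertex to nearest selected node; rows kept for the
  # patch assignment
  dsel <- matrix(NA_real_, target_K, nv)
  dsel[1L, ] <- as.vector(igraph::distances(g, v = start))
  mind <- dsel[1L, ]
  if (target_K > 1L) {
    for (i in 2:target_K) {
      nxt <- which.max(mind) # ties -> lowest index (which.max contract)
      sel[i] <- nxt
      dsel[i, ] <- as.vector(igraph::distances(g, v = nxt))
      mind <- pmin(mind, dsel[i, ])
    }
  }
  assign <- apply(dsel, 2, which.min) # ties -> lowest selected-node index
  verts <- if (inherits(mesh, "igraph")) {
    cbind(
      x = igraph::vertex_attr(g, "x") %||% rep(0, nv),
      y = igraph::vertex_attr(g, "y") %||% rep(0, nv),
      z = igraph::vertex_attr(g, "z") %||% rep(0, nv)
    )
  } else {
    as.matrix(mesh$vertices)
  }
  nodes <- tibble::tibble(
    node = seq_len(target_K),
    x = verts[sel, 1], y = verts[sel, 2],
    z = if (ncol(verts) >= 3) verts[sel, 3] else 0
  )
  D <- dsel[, sel, drop = FALSE]
  D <- (D + t(D)) / 2 # symmetric up to float error already
  network_graph(
    nodes, D,
    patch_map = tibble::tibble(vertex = seq_len(nv), node = as.integer(assign))
  )
}

# run expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Average a dense per-vertex signal over patches
#'
#' @param vertex_values Numeric vector, one value per dense vertex.
#' @param patch_map Data frame (`vertex`, `node`) partitioning the vertices.
#' @param na_skip If `TRUE`, missing vertex values are dropped from their
#'   patch mean; otherwise missing values are an error.
#' @return Numeric vector of length K (number of nodes), the per-patch
#'   arithmetic means.
#' @export
patch_average <- function(vertex_values, patch_map, na_skip = FALSE) {
  patch_map <- as.data.frame(patch_map)
  if (length(vertex_values) != nrow(patch_map)) {
    abort("`vertex_values` must have one value per vertex in `patch_map`.")
  }
  if (anyNA(vertex_values) && !na_skip) {
    abort("Missing vertex values; set `na_skip = TRUE` to drop them.")
  }
  v <- vertex_values[order(patch_map$vertex)]
  nd <- patch_map$node[order(patch_map$vertex)]
  out <- tapply(v, factor(nd, levels = sort(unique(nd))), mean,
                na.rm = na_skip)
  as.vector(out)
}

#' Select control nodes at approximate spacing b
#'
#' Scans the nodes in index order (starting from `first`) and keeps every
#' node at geodesic distance at least `b` from all previously kept nodes
#' (sequential Poisson-disk selection). The selection is deterministic.
#'
#' @param graph A `netcourse_graph`.
#' @param b Minimum spacing between control nodes, in the distance units of
#'   the graph (> 0). A `b` exceeding the graph diameter yields a single
#'   control node, with a warning.
#' @param first Index of the first control node (default 1).
#' @return The graph with its `control` field set.
#' @examples
#' g <- make_grid_graph(7)
#' g <- select_control_nodes(g, b = 3)
#' length(g$control) # 9: the 3x3 corner/edge/center subgrid
#' @export
select_control_nodes <- function(graph, b, first = 1L) {
  stopifnot(inherits(graph, "netcourse_graph"))
  if (b <= 0) abort("`b` must be positive.")
  K <- n_nodes(graph)
  ord <- c(first, setdiff(seq_len(K), first))
  sel <- integer(0)
  for (k in ord) {
    if (length(sel) == 0L || all(graph$dist[k, sel] >= b)) sel <- c(sel, k)
  }
  if (length(sel) == 1L && b > max(graph$dist)) {
    warn("Spacing `b` exceeds the graph diameter; a single control node was selected.")
  }
  graph$control <- as.integer(sel)
  graph
}

#' Write / read a network graph as plain-text files
#'
#' Writes `nodes.csv` (`node`, `x`, `y`, `z`), `distances.csv` (dense K x K),
#' `control_nodes.csv` (one column `node`), and `patch_map.csv` if present,
#' into `dir`. Indices are 1-based.
#'
#' @param graph A `netcourse_graph`.
#' @param dir Directory (created if needed).
#' @return `write_graph_dir()` returns `dir` invisibly; `read_graph_dir()`
#'   returns the graph.
#' @export
write_graph_dir <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(graph$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(as.data.frame(graph$dist), file.path(dir, "distances.csv"),
            row.names = FALSE)
  write.csv(data.frame(node = graph$control),
            file.path(dir, "control_nodes.csv"), row.names = FALSE)
  if (!is.null(graph$patch_map)) {
    write.csv(graph$patch_map, file.path(dir, "patch_map.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_graph_dir
#' @export
read_graph_dir <- function(dir) {
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  D <- as.matrix(read.csv(file.path(dir, "distances.csv")))
  ctrl <- read.csv(file.path(dir, "control_nodes.csv"))$node
  pm_path <- file.path(dir, "patch_map.csv")
  pm <- if (file.exists(pm_path)) read.csv(pm_path)
  network_graph(nodes, D, control = ctrl, patch_map = pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
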