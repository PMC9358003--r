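#' Build the skeleton graph of a channel
#'
#' The skeleton is the Delaunay-dual graph of the channel tetrahedra: one
#' node per tetrahedron, placed at its orthocenter when that lies inside the
#' tetrahedron (barycenter otherwise), with edges between face-adjacent
#' channel tetrahedra.  Orthocenters of complement tetrahedra approximate
#' medial points of the cavity, so the graph approximates the channel's
#' medial axis.  Each node carries a clearance radius, its distance to the
#' nearest probe-inflated atom ball.  Nodes with non-positive clearance lie
#' inside the inflated atoms (wall interstices a probe cannot occupy) and
#' are dropped by default, which concentrates the skeleton on the open
#' lumen.  Only the largest connected component is kept (discarded node
#' counts are reported via a message).
#'
#' @param channel a `cavity_component`.
#' @param T the `tetrahedralization` it belongs to.
#' @param min_clearance keep nodes with clearance above this value
#'   (default 0; use `-Inf` to keep one node per channel tetrahedron).
#' @return an object of class `skeleton_graph` with `nodes` (k x 3),
#'   `clearance`, `edges` (2-column matrix of node ids), `edge_length`,
#'   and `tet_ids` mapping nodes back to tetrahedra.
#' @export
build_skeleton <- function(channel, T, min_clearance = 0) {
  stopifnot(inherits(channel, "cavity_component"),
            inherits(T, "tetrahedralization"))
  tids <- channel$tet_ids
  k <- length(tids)
  nodes <- matrix(NA_real_, k, 3L)
  for (j in seq_len(k)) {
    tid <- tids[j]
    verts <- T$points[T$tets[tid, ], , drop = FALSE]
    oc <- T$orthocenter[tid, ]
    if (points_in_tet(matrix(oc, 1L, 3L), verts)) {
      nodes[j, ] <- oc
    } else {
      nodes[j, ] <- colMeans(verts)
    }
  }
  inflated <- sqrt(T$weights)
  clearance <- rep(Inf, k)
  for (i in seq_len(nrow(T$points))) {
    d <- sqrt((nodes[, 1L] - T$points[i, 1L])^2 +
                (nodes[, 2L] - T$points[i, 2L])^2 +
                (nodes[, 3L] - T$points[i, 3L])^2) - inflated[i]
    clearance <- pmin(clearance, d)
  }
  if (is.finite(min_clearance)) {
    keep <- which(clearance > min_clearance)
    if (length(keep) == 0L)
      stop("no skeleton node clears the probe-inflated atoms")
    nodes <- nodes[keep, , drop = FALSE]
    clearance <- clearance[keep]
    tids <- tids[keep]
    k <- length(keep)
  }
  # edges between face-adjacent channel tets
  pos_of <- integer(nrow(T$tets))
  pos_of[tids] <- seq_len(k)
  ea <- integer(0)
  eb <- integer(0)
  for (i in 1:4) {
    nb <- T$neighbors[tids, i]
    sel <- which(nb > 0L)
    sel <- sel[nb[sel] %in% tids & nb[sel] > tids[sel]]
    ea <- c(ea, sel)
    eb <- c(eb, pos_of[nb[sel]])
  }
  edges <- unique(cbind(ea, eb))
  if (k > 1L && nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      keep <- which(comp$membership == which.max(comp$csize))
      message(sprintf("skeleton: keeping largest component (%d of %d nodes)",
                      length(keep), k))
      remap <- integer(k)
      remap[keep] <- seq_along(keep)
      sel <- edges[, 1L] %in% keep & edges[, 2L] %in% keep
      edges <- cbind(remap[edges[sel, 1L]], remap[edges[sel, 2L]])
      nodes <- nodes[keep, , drop = FALSE]
      clearance <- clearance[keep]
      tids <- tids[keep]
      k <- length(keep)
    }
  }
  el <- if (nrow(edges)) {
    sqrt(rowSums((nodes[edges[, 1L], , drop = FALSE] -
                    nodes[edges[, 2L], , drop = FALSE])^2))
  } else {
    numeric(0)
  }
  structure(list(nodes = nodes, clearance = clearance,
                 edges = unname(edges), edge_length = el, tet_ids = tids),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Tortuousness of a path
#'
#' The mean distance of all path nodes (endpoints included) from the
#' infinite straight line through the first and last node.  Zero for a
#' perfectly rectilinear path.
#'
#' @param positions numeric matrix (k x 3) of ordered node positions.
#' @return tortuousness in Angstrom.
#' @export
path_tortuousness <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) stop("a path needs at least 2 nodes")
  a <- positions[1L, ]
  b <- positions[nrow(positions), ]
  if (vnorm(b - a) < 1e-9)
    stop("path endpoints coincide; tortuousness is undefined")
  mean(point_line_distance(positions, a, b))
}

#' Score of a skeleton path
#'
#' `score = length^2 / max(tortuousness, eps)` where `length` is the number
#' of edges.  The `eps` floor (default 1e-6 A) keeps the score finite for
#' perfectly rectilinear paths, whose tortuousness is zero; paths that are
#' both long and straight receive the highest scores.
#'
#' @param positions ordered node positions (k x 3); a single node scores 0.
#' @param eps tortuousness floor in Angstrom.
#' @return the path score.
#' @export
path_score <- function(positions, eps = 1e-6) {
  positions <- as.matrix(positions)
  n_edges <- nrow(positions) - 1L
  if (n_edges <= 0L) return(0)
  n_edges^2 / max(path_tortuousness(positions), eps)
}

#' Prune a skeleton graph to its core path
#'
#' Considers the shortest path (edge-count metric) between every pair of
#' skeleton nodes, scores each by `length^2 / tortuousness`, and returns the
#' highest-scoring one; this selects the path along which the channel
#' develops, discriminating the two main entrances from lateral branches.
#' Shortest paths are routed by default over clearance-weighted edge costs
#' (`edge_length / mean(node clearances)^2`, the same medial cost as
#' [compute_centerline()]): candidate paths then follow the locally widest
#' part of the cavity, which keeps the search geometric on dense
#' Delaunay-dual skeletons.  The score of a candidate path is its Euclidean
#' length squared over its tortuousness (on uniformly sampled curve
#' skeletons this is the edge-count score up to a constant).  The unweighted
#' edge-count formulation is available with `metric = "hops"`, where for
#' each pair the lexicographically smallest shortest path is used and the
#' score counts edges.  Score ties are broken by the longer path, then by
#' the smallest endpoint ids.
#'
#' By default the tortuousness entering the score is floored at half the
#' median edge length of the graph: straightness below the node spacing is
#' sampling noise, and without the floor a chance-collinear two- or
#' three-edge path would outscore any physically meaningful long path.
#'
#' @param g a `skeleton_graph` with at least 2 nodes.
#' @param eps tortuousness floor in Angstrom; `NULL` (default) uses
#'   `max(1e-6, 0.5 * median edge length)`.
#' @param metric `"clearance"` (default), `"euclidean"` or `"hops"`.
#' @param clearance_exponent exponent on mean edge clearance in the
#'   `"clearance"` routing cost.
#' @return an object of class `skeleton_path`: `node_ids` (ordered),
#'   `positions`, `length` (edge count), `metric_length` (A),
#'   `tortuousness`, `score`, `eps`.
#' @export
prune_skeleton <- function(g, eps = NULL,
                           metric = c("clearance", "euclidean", "hops"),
                           clearance_exponent = 2) {
  metric <- match.arg(metric)
  stopifnot(inherits(g, "skeleton_graph"))
  if (nrow(g$nodes) < 2L)
    stop("cannot prune a single-node skeleton")
  if (nrow(g$edges) == 0L)
    stop("skeleton has no edges")
  if (is.null(eps)) eps <- max(1e-6, 0.5 * median(g$edge_length))
  cost <- numeric(0)
  if (metric == "clearance") {
    cl <- pmax(g$clearance, 1e-6)
    cost <- g$edge_length /
      ((cl[g$edges[, 1L]] + cl[g$edges[, 2L]]) / 2)^clearance_exponent
  }
  res <- rt_prune(g$edges, g$nodes, eps,
                  if (metric == "hops") 0L else 1L, cost)
  if (length(res$path) == 0L)
    stop("no connected node pair in the skeleton")
  structure(list(node_ids = res$path,
                 positions = g$nodes[res$path, , drop = FALSE],
                 length = res$length,
                 metric_length = res$metric_length,
                 tortuousness = res$tortuousness,
                 score = res$score,
                 eps = eps,
                 metric = metric),
            class = "skeleton_path")
}

#' @export
print.skeleton_path <- function(x, ...) {
  cat(sprintf(
    "<skeleton_path> %d edges, tortuousness %.3f A, score %.3g\n",
    x$length, x$tortuousness, x$score))
  invisible(x)
}

#' Import a skeleton graph from CSV files
#'
#' Allows an externally computed skeleton (for example a mean-curvature-flow
#' skeleton of the channel mesh) to replace the built-in Delaunay-dual
#' construction; all downstream stages are skeleton-source-agnostic.
#'
#' @param node_csv CSV with columns `id`, `x`, `y`, `z` and optionally
#'   `clearance`.
#' @param edge_csv CSV with columns `id_a`, `id_b`.
#' @return a `skeleton_graph`.
#' @export
read_skeleton <- function(node_csv, edge_csv) {
  nd <- read.csv(node_csv)
  ed <- read.csv(edge_csv)
  ord <- order(nd$id)
  nd <- nd[ord, , drop = FALSE]
  remap <- match(c(ed$id_a, ed$id_b), nd$id)
  if (anyNA(remap)) stop("edge references an unknown node id")
  edges <- matrix(remap, ncol = 2L)
  nodes <- as.matrix(nd[, c("x", "y", "z")])
  clearance <- if ("clearance" %in% names(nd)) nd$clearance
               else rep(1, nrow(nodes))
  el <- sqrt(rowSums((nodes[edges[, 1L], , drop = FALSE] -
                        nodes[edges[, 2L], , drop = FALSE])^2))
  structure(list(nodes = nodes, clearance = clearance, edges = edges,
                 edge_length = el, tet_ids = nd$id),
            class = "skeleton_graph")
}
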