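# Independent oracles and shared fixtures for the test suite.

# Brute-force regular triangulation: enumerate all 4-subsets of weighted
# points and keep those whose orthosphere is empty (power distance of every
# other point >= -tol).  Vectorized Cramer solves; independent of the
# incremental construction under test.
brute_rt_oracle <- function(pts, w, tol = 1e-9) {
  n <- nrow(pts)
  idx <- utils::combn(n, 4L)
  P1 <- pts[idx[1L, ], , drop = FALSE]
  P2 <- pts[idx[2L, ], , drop = FALSE]
  P3 <- pts[idx[3L, ], , drop = FALSE]
  P4 <- pts[idx[4L, ], , drop = FALSE]
  lift <- rowSums(pts^2) - w
  a1 <- 2 * (P2 - P1)
  a2 <- 2 * (P3 - P1)
  a3 <- 2 * (P4 - P1)
  r1 <- lift[idx[2L, ]] - lift[idx[1L, ]]
  r2 <- lift[idx[3L, ]] - lift[idx[1L, ]]
  r3 <- lift[idx[4L, ]] - lift[idx[1L, ]]
  cx <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- cx(a2, a3)
  c31 <- cx(a3, a1)
  c12 <- cx(a1, a2)
  det <- rowSums(a1 * c23)
  ok <- abs(det) > 1e-12
  z <- (r1 * c23 + r2 * c31 + r3 * c12) / det
  sqr <- rowSums((z - P1)^2) - w[idx[1L, ]]
  empty <- ok
  for (q in seq_len(n)) {
    inset <- idx[1L, ] == q | idx[2L, ] == q | idx[3L, ] == q | idx[4L, ] == q
    pd <- (z[, 1L] - pts[q, 1L])^2 + (z[, 2L] - pts[q, 2L])^2 +
      (z[, 3L] - pts[q, 3L])^2 - w[q] - sqr
    empty <- empty & (inset | pd >= -tol)
  }
  keep <- which(empty)
  if (length(keep) == 0L) return(matrix(integer(0), 0L, 4L))
  t(apply(idx[, keep, drop = FALSE], 2L, sort))
}

tet_key <- function(m) sort(apply(m, 1L, paste, collapse = "-"))

random_weighted_atoms <- function(n, seed, box = 15) {
  set.seed(seed)
  atom_set(matrix(runif(3L * n, 0, box), n, 3L), runif(n, 1, 2))
}

# random connected skeleton graph with 3D positions and clearances
random_skeleton_graph <- function(n, seed, extra = n %/% 3L) {
  set.seed(seed)
  pos <- matrix(runif(3L * n, 0, 20), n, 3L)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  if (extra > 0L) {
    more <- cbind(sample.int(n, extra, replace = TRUE),
                  sample.int(n, extra, replace = TRUE))
    more <- more[more[, 1L] != more[, 2L], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  edges <- unique(t(apply(edges, 1L, sort)))
  el <- sqrt(rowSums((pos[edges[, 1L], , drop = FALSE] -
                        pos[edges[, 2L], , drop = FALSE])^2))
  structure(list(nodes = pos, clearance = runif(n, 0.5, 3), edges = edges,
                 edge_length = el, tet_ids = seq_len(n)),
            class = "skeleton_graph")
}

# independent pruning oracle: igraph shortest paths under the same
# clearance-weighted cost, exhaustively scored over all pairs
prune_oracle <- function(g, eps) {
  n <- nrow(g$nodes)
  cl <- pmax(g$clearance, 1e-6)
  cost <- g$edge_length /
    ((cl[g$edges[, 1L]] + cl[g$edges[, 2L]]) / 2)^2
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  best <- list(score = -1)
  for (s in seq_len(n - 1L)) {
    sp <- suppressWarnings(igraph::shortest_paths(
      ig, from = s, to = (s + 1L):n, weights = cost, output = "vpath"))
    for (k in seq_along(sp$vpath)) {
      vp <- as.integer(sp$vpath[[k]])
      if (length(vp) < 2L) next
      pp <- g$nodes[vp, , drop = FALSE]
      plen <- sum(sqrt(rowSums(diff(pp)^2)))
      tort <- path_tortuousness(pp)
      score <- plen^2 / max(tort, eps)
      if (score > best$score) best <- list(score = score, path = vp)
    }
  }
  best
}

# wrap bare 2D points as a section object for visibility/metric tests
make_section <- function(points2d) {
  points2d <- as.matrix(points2d)
  structure(list(points3d = cbind(points2d, 0), points2d = points2d,
                 p = c(0, 0, 0), normal = c(0, 0, 1),
                 basis = list(u = c(1, 0, 0), v = c(0, 1, 0)),
                 empty = nrow(points2d) == 0L),
            class = "channel_section")
}

# brute-force union-find over an all-pairs distance matrix
uf_components <- function(xy, threshold) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  d <- as.matrix(dist(xy))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

mesh_edge_counts <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(1L, 3L)], tri[, c(2L, 3L)])
  table(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
}

mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
  u <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] - a
  v <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE] - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

mesh_component_count <- function(mesh) {
  g <- igraph::graph_from_edgelist(
    rbind(mesh$triangles[, c(1L, 2L)], mesh$triangles[, c(2L, 3L)]),
    directed = FALSE)
  igraph::components(g)$no
}

# expensive shared fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

cyl_pipeline <- function() {
  cached("cyl", suppressMessages(suppressWarnings({
    fx <- make_fixture("cylinder_pore")
    res <- analyze_structure(fx$atoms, sections = TRUE)
    res$truth <- fx$truth
    res
  })))
}

helix_centerline <- function() {
  cached("helix", {
    fx <- make_fixture("helical_tube")
    ax <- fx$truth$axis
    seg <- sqrt(rowSums(diff(ax)^2))
    cl <- structure(list(points = ax, arclength = c(0, cumsum(seg))),
                    class = "centerline")
    list(cl = frenet(cl), truth = fx$truth)
  })
}
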