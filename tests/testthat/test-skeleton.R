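test_that("tortuousness matches hand-computed values", {
  expect_equal(path_tortuousness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               0)
  expect_equal(path_tortuousness(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))),
               1 / 3)
  expect_error(path_tortuousness(rbind(c(1, 2, 3), c(1, 2, 3))),
               "coincide")
})

test_that("path score follows length^2 over floored tortuousness", {
  p <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  expect_equal(path_score(p), 4 / (1 / 3))
  straight <- cbind(0:5, 0, 0)
  expect_equal(path_score(straight), 25 / 1e-6)
  expect_equal(path_score(matrix(1, 1L, 3L)), 0)
})

test_that("score is monotone in the stated directions", {
  # equal length, increasing tortuousness -> non-increasing score
  mk <- function(h) rbind(c(0, 0, 0), c(1, h, 0), c(2, 0, 0))
  scores <- vapply(c(0.1, 0.5, 1, 2), function(h) path_score(mk(h)),
                   numeric(1L))
  expect_true(all(diff(scores) <= 0))
  # equal tortuousness (all straight), increasing length -> non-decreasing
  lens <- vapply(c(3, 5, 9), function(n) path_score(cbind(0:n, 0, 0)),
                 numeric(1L))
  expect_true(all(diff(lens) >= 0))
})

test_that("a plus-sign skeleton prunes to the straight long bar", {
  bar <- cbind(0:10, 0, 0)
  stub <- cbind(5, c(1, 2, 3, 4), 0)
  nodes <- rbind(bar, stub)
  edges <- rbind(cbind(1:10, 2:11), rbind(c(6L, 12L), c(12L, 13L),
                                          c(13L, 14L), c(14L, 15L)))
  g <- structure(list(nodes = nodes, clearance = rep(1, 15L), edges = edges,
                      edge_length = sqrt(rowSums(
                        (nodes[edges[, 1L], ] - nodes[edges[, 2L], ])^2)),
                      tet_ids = 1:15),
                 class = "skeleton_graph")
  p <- prune_skeleton(g, eps = 1e-6)
  expect_identical(sort(p$node_ids), 1:11)
  expect_equal(p$length, 10L)
  expect_lt(p$tortuousness, 1e-9)
})

test_that("a path graph prunes to the whole path", {
  set.seed(2)
  nodes <- cbind(cumsum(runif(8, 0.5, 1.5)), rnorm(8, sd = 0.05), 0)
  edges <- cbind(1:7, 2:8)
  g <- structure(list(nodes = nodes, clearance = rep(1, 8L), edges = edges,
                      edge_length = sqrt(rowSums(
                        (nodes[1:7, ] - nodes[2:8, ])^2)),
                      tet_ids = 1:8),
                 class = "skeleton_graph")
  p <- prune_skeleton(g)
  expect_identical(p$node_ids, 1:8)
})

test_that("pruning equals exhaustive all-pairs enumeration", {
  for (seed in c(201, 202, 203, 204, 205)) {
    n <- sample(20:50, 1L)
    g <- random_skeleton_graph(n, seed)
    eps <- 1e-6
    impl <- prune_skeleton(g, eps = eps)
    oracle <- prune_oracle(g, eps)
    expect_equal(impl$score, oracle$score, tolerance = 1e-9)
    expect_true(identical(impl$node_ids, oracle$path) ||
                  identical(impl$node_ids, rev(oracle$path)))
  }
})

test_that("single-node or edgeless skeletons are rejected", {
  g1 <- structure(list(nodes = matrix(0, 1L, 3L), clearance = 1,
                       edges = matrix(integer(0), 0L, 2L),
                       edge_length = numeric(0), tet_ids = 1L),
                  class = "skeleton_graph")
  expect_error(prune_skeleton(g1), "single-node")
})

test_that("cylinder skeleton is medial and its pruned path spans the pore", {
  res <- cyl_pipeline()
  sk <- res$skeleton
  r <- sqrt(sk$nodes[, 1L]^2 + sk$nodes[, 2L]^2)
  # all nodes clear the probe-inflated wall, the well-cleared core is axial
  expect_true(all(sk$clearance > 0))
  core <- sk$clearance >= 0.5 * max(sk$clearance)
  expect_lt(median(r[core]), 1)
  # two face-adjacent tets give a single-edge path graph
  ends <- res$path$positions[c(1L, nrow(res$path$positions)), ]
  mouth_centroids <- rbind(c(0, 0, 0), c(0, 0, 30))
  d <- pmin(
    poretrace:::nearest_point_distance(ends, mouth_centroids[1L, , drop = FALSE]),
    poretrace:::nearest_point_distance(ends, mouth_centroids[2L, , drop = FALSE]))
  expect_lt(max(d), 2)
})

test_that("pentalobe skeleton ramifies at the lobes", {
  fx <- make_fixture("pentalobe_tube", length = 20)
  T <- weighted_delaunay(fx$atoms, 1.4)
  comp <- suppressWarnings(select_channel(find_cavities(T)))
  sk <- suppressMessages(build_skeleton(comp, T))
  deg <- tabulate(c(sk$edges), nbins = nrow(sk$nodes))
  expect_gte(sum(deg >= 3L), 5L)
})

test_that("skeleton CSV import round trips", {
  g <- random_skeleton_graph(15, seed = 5)
  nd <- withr::local_tempfile(fileext = ".csv")
  ed <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = seq_len(nrow(g$nodes)), x = g$nodes[, 1L],
                       y = g$nodes[, 2L], z = g$nodes[, 3L],
                       clearance = g$clearance), nd, row.names = FALSE)
  write.csv(data.frame(id_a = g$edges[, 1L], id_b = g$edges[, 2L]), ed,
            row.names = FALSE)
  g2 <- read_skeleton(nd, ed)
  expect_equal(g2$nodes, g$nodes, ignore_attr = TRUE)
  expect_equal(g2$clearance, g$clearance)
  p1 <- prune_skeleton(g)
  p2 <- prune_skeleton(g2)
  expect_identical(p1$node_ids, p2$node_ids)
})
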