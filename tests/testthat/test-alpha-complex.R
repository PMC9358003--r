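test_that("orthosphere matches closed forms and rejects degeneracies", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 3
  os <- orthosphere(v, rep(1, 4L))
  R2 <- sum((v[1L, ] - colMeans(v))^2)
  expect_equal(os$center, colMeans(v), tolerance = 1e-12)
  expect_equal(os$sq_radius, R2 - 1, tolerance = 1e-12)

  # equal weights cancel: center is the unweighted circumcenter
  set.seed(11)
  p <- matrix(rnorm(12), 4L, 3L)
  for (w in c(0, 2.7)) {
    osw <- orthosphere(p, rep(w, 4L))
    d <- sqrt(rowSums(sweep(p, 2L, osw$center)^2))
    expect_lt(diff(range(d)), 1e-9)
  }

  coll <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(orthosphere(coll, rep(1, 4L)), "degenerate")
})

test_that("five cospherical-free points triangulate around the centroid", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 3
  at <- atom_set(rbind(v, colMeans(v)), rep(1, 5L))
  T <- weighted_delaunay(at, probe = 0)
  expect_equal(nrow(T$tets), 4L)
  expect_true(all(apply(T$tets, 1L, function(t) 5L %in% t)))
})

test_that("degenerate and undersized inputs are rejected", {
  flat <- atom_set(cbind(runif(8), runif(8), 0), rep(1, 8L))
  expect_error(weighted_delaunay(flat, jitter = 0), "coplanar")
  small <- atom_set(matrix(runif(12), 4L, 3L), rep(1, 4L))
  expect_error(weighted_delaunay(small), "at least 5")
})

test_that("triangulation equals the brute-force empty-orthosphere oracle", {
  for (seed in c(101, 102, 103)) {
    at <- random_weighted_atoms(30, seed)
    T <- weighted_delaunay(at, probe = 1.4)
    oracle <- brute_rt_oracle(T$points, T$weights)
    expect_identical(tet_key(t(apply(T$tets, 1L, sort))), tet_key(oracle))
  }
})

test_that("every tetrahedron passes the empty-orthosphere test", {
  at <- random_weighted_atoms(50, seed = 77)
  T <- weighted_delaunay(at, probe = 1.4)
  for (r in seq_len(nrow(T$tets))) {
    os <- orthosphere(T$points[T$tets[r, ], ], T$weights[T$tets[r, ]])
    others <- setdiff(seq_len(nrow(T$points)), T$tets[r, ])
    pd <- colSums((t(T$points[others, , drop = FALSE]) - os$center)^2) -
      T$weights[others] - os$sq_radius
    expect_gte(min(pd), -1e-9)
    # stored orthocenter agrees with the standalone primitive
    expect_equal(T$orthocenter[r, ], os$center, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("face adjacency is consistent and tets tile the hull", {
  at <- random_weighted_atoms(60, seed = 5)
  T <- weighted_delaunay(at, 1.4)
  # every internal face shared by exactly 2 tets, hull faces by 1
  keys <- character(0)
  for (i in 1:4) {
    f <- t(apply(T$tets[, -i, drop = FALSE], 1L, sort))
    keys <- c(keys, paste(f[, 1L], f[, 2L], f[, 3L]))
  }
  counts <- table(keys)
  expect_true(all(counts %in% c(1L, 2L)))
  n_hull_faces <- sum(T$neighbors == 0L)
  expect_equal(sum(counts == 1L), n_hull_faces)

  # neighbor relation is symmetric
  for (r in seq_len(nrow(T$tets))) {
    for (i in 1:4) {
      nb <- T$neighbors[r, i]
      if (nb > 0L) expect_true(r %in% T$neighbors[nb, ])
    }
  }

  # signed volumes are positive and sum to the hull volume (divergence
  # theorem over outward-oriented hull faces)
  expect_true(all(T$volume > 0))
  hull_vol <- 0
  for (r in seq_len(nrow(T$tets))) {
    for (i in which(T$neighbors[r, ] == 0L)) {
      f <- T$points[T$tets[r, setdiff(1:4, i)], ]
      d <- T$points[T$tets[r, i], ]
      nrm <- poretrace:::cross3(f[2L, ] - f[1L, ], f[3L, ] - f[1L, ])
      if (sum(nrm * (colMeans(f) - d)) < 0) f <- f[c(1L, 3L, 2L), ]
      hull_vol <- hull_vol +
        sum(f[1L, ] * poretrace:::cross3(f[2L, ], f[3L, ])) / 6
    }
  }
  expect_equal(sum(T$volume), hull_vol, tolerance = 1e-6)
})

test_that("uniform scaling scales orthocenters and preserves combinatorics", {
  at <- random_weighted_atoms(40, seed = 9)
  s <- 2.5
  T1 <- weighted_delaunay(at, probe = 1.4)
  at2 <- atom_set(at$centers * s, at$radii * s)
  T2 <- weighted_delaunay(at2, probe = 1.4 * s)
  expect_identical(tet_key(t(apply(T1$tets, 1L, sort))),
                   tet_key(t(apply(T2$tets, 1L, sort))))
  ord1 <- order(T1$tets[, 1L], T1$tets[, 2L], T1$tets[, 3L], T1$tets[, 4L])
  ord2 <- order(T2$tets[, 1L], T2$tets[, 2L], T2$tets[, 3L], T2$tets[, 4L])
  expect_equal(T2$orthocenter[ord2, ], T1$orthocenter[ord1, ] * s,
               tolerance = 1e-6)
  expect_equal(T2$sq_orthoradius[ord2], T1$sq_orthoradius[ord1] * s^2,
               tolerance = 1e-6)
})

test_that("interior flags follow the sign of the squared orthoradius", {
  # two heavily overlapping balls plus distant padding
  ctr <- rbind(c(0, 0, 0), c(1, 0, 0),
               c(10, 0, 0), c(-10, 2, 0), c(0, 10, 3), c(0, -9, 2),
               c(3, 3, 10))
  at <- atom_set(ctr, c(2, 2, rep(0.5, 5L)))
  T <- weighted_delaunay(at, probe = 0)
  between <- which(apply(T$tets, 1L, function(t) all(c(1L, 2L) %in% t)))
  expect_gt(length(between), 0L)
  for (r in seq_len(nrow(T$tets))) {
    os <- orthosphere(T$points[T$tets[r, ], ], T$weights[T$tets[r, ]])
    expect_equal(unname(T$interior[r]), os$sq_radius <= 1e-9)
  }

  # tiny far-apart balls: nothing is interior
  at2 <- random_weighted_atoms(20, seed = 21, box = 60)
  at2 <- atom_set(at2$centers, rep(0.1, 20L))
  T2 <- weighted_delaunay(at2, probe = 0)
  expect_false(any(T2$interior))
  expect_identical(T2$interior, classify_interior(T2))
})

test_that("no interior tetrahedron crosses the open cylinder lumen", {
  res <- cyl_pipeline()
  T <- res$triangulation
  bary <- (T$points[T$tets[, 1L], ] + T$points[T$tets[, 2L], ] +
             T$points[T$tets[, 3L], ] + T$points[T$tets[, 4L], ]) / 4
  in_lumen <- sqrt(bary[, 1L]^2 + bary[, 2L]^2) < 3 &
    bary[, 3L] > 5 & bary[, 3L] < 25
  expect_false(any(T$interior & in_lumen))
})

test_that("redundant points are hidden and reported", {
  # shell of unit balls, a large ball at the center, and a tiny ball just
  # off-center: the tiny ball's power cell is swallowed by the large one
  i <- seq_len(12L)
  phi <- acos(1 - 2 * (i - 0.5) / 12)
  theta <- pi * (1 + sqrt(5)) * i
  shell <- 8 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  ctr <- rbind(shell, c(0, 0, 0), c(0.05, 0.05, 0.05))
  at <- atom_set(ctr, c(rep(1, 12L), 3, 0.01))
  T <- weighted_delaunay(at, probe = 1.4)
  expect_true(14L %in% T$redundant)
  expect_false(14L %in% as.vector(T$tets))
})
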