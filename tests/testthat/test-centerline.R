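test_that("cylinder centerline tracks the true axis", {
  res <- cyl_pipeline()
  cl <- res$centerline
  axdist <- sqrt(cl$points[, 1L]^2 + cl$points[, 2L]^2)
  expect_lt(sqrt(mean(axdist^2)), 0.5)
  # clearance-cost sanity: the path stays within the high-clearance core
  expect_gt(min(4.5 - axdist), 0.8 * 4.5 - 1)  # never near the wall
  expect_true(all(abs(sqrt(rowSums(cl$tangent^2)) - 1) < 1e-9))
  steps <- diff(cl$arclength)
  expect_true(all(steps > 0.2 * cl$step & steps < 2 * cl$step))
})

test_that("degenerate source/target requests fail cleanly", {
  res <- cyl_pipeline()
  sk <- res$skeleton
  expect_error(compute_centerline(sk, 1L, 1L), "coincide")
  expect_error(compute_centerline(sk, 1L, 10^6L), "outside")
})

test_that("frenet recovers helix and circle closed forms", {
  hx <- helix_centerline()
  cl <- hx$cl
  i <- 20:180
  expect_equal(mean(cl$curvature[i]), hx$truth$curvature, tolerance = 0.05)
  expect_equal(mean(cl$torsion[i]), hx$truth$torsion, tolerance = 0.05)
  expect_true(all(abs(cl$curvature[i] / hx$truth$curvature - 1) < 0.05))
  expect_true(all(abs(cl$torsion[i] / hx$truth$torsion - 1) < 0.05))

  th <- seq(0, 2 * pi, length.out = 300L)
  R <- 7
  circ <- cbind(R * cos(th), R * sin(th), 0)
  ccl <- frenet(structure(list(points = circ,
                               arclength = c(0, cumsum(sqrt(rowSums(diff(circ)^2))))),
                          class = "centerline"))
  expect_true(all(abs(ccl$curvature[20:280] * R - 1) < 0.02))
  expect_true(all(abs(ccl$torsion[20:280]) < 1e-6))

  # straight line: zero curvature, flagged frames, zero torsion
  line <- cbind(seq(0, 10, by = 0.5), 0, 0)
  lcl <- frenet(structure(list(points = line,
                               arclength = seq(0, 10, by = 0.5)),
                          class = "centerline"))
  expect_true(all(lcl$curvature < 1e-9))
  expect_true(all(lcl$torsion == 0))
  expect_false(any(lcl$frame_ok))
})

test_that("reversing source and target reverses the centerline", {
  res <- cyl_pipeline()
  sk <- res$skeleton
  p <- res$path
  s <- p$node_ids[1L]
  t <- p$node_ids[length(p$node_ids)]
  a <- local_radius(compute_centerline(sk, s, t), res$channel_surface)
  b <- local_radius(compute_centerline(sk, t, s), res$channel_surface)
  n <- nrow(a$points)
  expect_equal(b$points, a$points[n:1, ], tolerance = 1e-6)
  expect_equal(b$tangent[2:(n - 1), ], -a$tangent[(n - 1):2, ],
               tolerance = 1e-6)
  expect_equal(b$curvature[2:(n - 1)], a$curvature[(n - 1):2],
               tolerance = 1e-6)
  expect_equal(abs(b$torsion[3:(n - 2)]), abs(a$torsion[(n - 2):3]),
               tolerance = 1e-6)
  expect_equal(b$radius, a$radius[n:1], tolerance = 1e-6)
})

test_that("halving the resampling step barely changes the arclength", {
  res <- cyl_pipeline()
  sk <- res$skeleton
  p <- res$path
  s <- p$node_ids[1L]
  t <- p$node_ids[length(p$node_ids)]
  c1 <- compute_centerline(sk, s, t, step = 0.5)
  c2 <- compute_centerline(sk, s, t, step = 0.25)
  expect_lt(abs(max(c2$arclength) / max(c1$arclength) - 1), 0.01)
})

test_that("the pipeline centerline is rigid-motion equivariant", {
  fx <- make_fixture("cylinder_pore", length = 15)
  ang <- 0.7
  Rm <- rbind(c(cos(ang), -sin(ang), 0),
              c(sin(ang), cos(ang), 0),
              c(0, 0, 1)) %*%
    rbind(c(1, 0, 0),
          c(0, cos(0.4), -sin(0.4)),
          c(0, sin(0.4), cos(0.4)))
  shift <- c(3, -2, 7)
  run <- function(at) suppressMessages(suppressWarnings(
    analyze_structure(at, sections = FALSE)))$centerline$points
  p1 <- run(fx$atoms)
  at2 <- atom_set(fx$atoms$centers %*% t(Rm) +
                    rep(1, nrow(fx$atoms$centers)) %o% shift,
                  fx$atoms$radii)
  p2 <- run(at2)
  back <- sweep(p2, 2L, shift) %*% Rm
  err <- min(max(abs(back - p1)),
             max(abs(back[nrow(back):1, ] - p1)))
  expect_lt(err, 1e-6)
})

test_that("local radius equals brute-force nearest vertex", {
  res <- cyl_pipeline()
  cl <- res$centerline
  sv <- poretrace:::channel_surface_vertices(res$channel_surface)
  set.seed(6)
  for (k in sample(nrow(cl$points), 50L)) {
    d <- sqrt(colSums((t(sv) - cl$points[k, ])^2))
    expect_equal(cl$radius[k], min(d), tolerance = 1e-12)
  }
  expect_true(all(cl$radius > 0))
})

test_that("radius re-binning reproduces hand statistics", {
  s <- data.frame(z = c(1, 1, 5, 5), radius = c(3, 5, 4, 4),
                  frame = c(1L, 2L, 1L, 2L))
  prof <- radius_profile(s, bin_width = 1)
  expect_equal(nrow(prof), 2L)  # empty bins omitted
  expect_equal(prof$mean_radius, c(4, 4))
  expect_equal(prof$sd, c(sqrt(2), 0))
  expect_equal(prof$n, c(2L, 2L))

  # constant radii give zero SD everywhere
  s2 <- data.frame(z = rep(1:10, 3L), radius = 4.2)
  expect_true(all(radius_profile(s2)$sd == 0))

  # a bin wider than the z range pools everything
  expect_equal(radius_profile(s, bin_width = 100)$n, 4L)
  expect_error(radius_profile(s[0, ]), "no radius")
})
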