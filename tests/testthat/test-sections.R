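test_that("a mid-cylinder section is a full circle at the lumen radius", {
  res <- cyl_pipeline()
  cl <- res$centerline
  mid <- which.min(abs(cl$points[, 3L] - 15))
  sec <- cut_section(res$channel_surface, cl$points[mid, ], cl$tangent[mid, ])
  expect_false(sec$empty)
  expect_true(all(abs(sweep(sec$points3d, 2L, cl$points[mid, ]) %*%
                        cl$tangent[mid, ]) < 1e-6))
  r <- sqrt(rowSums(sec$points2d^2))
  expect_true(all(r > 3.5 & r < 5.5))
  ang <- sort(atan2(sec$points2d[, 2L], sec$points2d[, 1L]))
  gaps <- c(diff(ang), 2 * pi - (max(ang) - min(ang)))
  expect_lt(max(gaps) * 180 / pi, 15)
})

test_that("a plane beyond the channel end is an empty section", {
  res <- cyl_pipeline()
  sec <- cut_section(res$channel_surface, c(0, 0, 100), c(0, 0, 1))
  expect_true(sec$empty)
  expect_equal(nrow(sec$points2d), 0L)
  sec <- section_graph(sec)
  sec <- visible_contour(sec)
  expect_length(sec$visible, 0L)
})

test_that("one crossed triangle contributes exactly two section points", {
  mesh <- surface_mesh(rbind(c(0, 0, -1), c(1, 0, 1), c(-1, 0, 1)),
                       matrix(c(1L, 2L, 3L), 1L))
  cs <- structure(list(triangle_ids = 1L,
                       barycenters = matrix(colMeans(mesh$vertices), 1L),
                       nearest_atom = NULL, mesh = mesh),
                  class = "channel_surface")
  sec <- cut_section(cs, c(0, 0, 0), c(0, 0, 1))
  expect_equal(nrow(sec$points3d), 2L)
})

test_that("proximity components match brute-force union-find", {
  set.seed(12)
  for (rep in 1:3) {
    xy <- rbind(matrix(rnorm(60, sd = 1), ncol = 2L),
                matrix(rnorm(40, mean = 8, sd = 1), ncol = 2L))
    sec <- make_section(xy)
    thr <- runif(1L, 0.5, 3)
    sec <- section_graph(sec, threshold = thr)
    expect_identical(unname(table(sec$component))[order(unique(sec$component))],
                     unname(table(uf_components(xy, thr)))[order(unique(uf_components(xy, thr)))])
    # same partition, possibly different labels
    expect_identical(
      unname(split(seq_len(nrow(xy)), sec$component)[
        order(vapply(split(seq_len(nrow(xy)), sec$component), min, 1L))]),
      unname(split(seq_len(nrow(xy)), uf_components(xy, thr))[
        order(vapply(split(seq_len(nrow(xy)), uf_components(xy, thr)), min, 1L))]))
  }
})

test_that("two distant clusters split or merge with the threshold", {
  xy <- rbind(cbind(rnorm(20, 0, 0.3), rnorm(20, 0, 0.3)),
              cbind(rnorm(20, 10, 0.3), rnorm(20, 0, 0.3)))
  s1 <- section_graph(make_section(xy), threshold = 2)
  expect_equal(length(unique(s1$component)), 2L)
  s2 <- section_graph(make_section(xy), threshold = 50)
  expect_equal(length(unique(s2$component)), 1L)
})

test_that("only the lobe containing the anchor is visible in a dumbbell", {
  # the near lobe is sampled at the ray resolution, as a mesh section is
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  th2 <- seq(0, 2 * pi, length.out = 73L)[-73L]
  lobeA <- cbind(3 * cos(th), 3 * sin(th))
  lobeB <- cbind(2 * cos(th2) + 12, 2 * sin(th2))
  sec <- section_graph(make_section(rbind(lobeA, lobeB)), threshold = 1)
  expect_equal(length(unique(sec$component)), 2L)
  sec <- visible_contour(sec, n_rays = 360L)
  expect_true(all(sec$visible[seq_len(360L)]))
  expect_false(any(sec$visible[361:432]))
})

test_that("a convex section is entirely visible", {
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  sec <- section_graph(make_section(cbind(4 * cos(th), 4 * sin(th))))
  sec <- visible_contour(sec, n_rays = 360L)
  expect_true(all(sec$visible))
  # doubling the rays does not change the visible set
  sec2 <- visible_contour(sec, n_rays = 720L)
  expect_identical(sec$visible, sec2$visible)
})

test_that("two openings visible from the anchor give two components", {
  th1 <- seq(pi / 2, 3 * pi / 2, length.out = 40L)
  th2 <- seq(-pi / 3, pi / 3, length.out = 30L)
  pts <- rbind(cbind(3 * cos(th1), 3 * sin(th1)),
               cbind(5 * cos(th2), 5 * sin(th2)))
  sec <- section_graph(make_section(pts), threshold = 1)
  sec <- visible_contour(sec, n_rays = 360L)
  expect_gte(length(sec$visible_components), 2L)
})

test_that("section metrics recover closed-form ellipse geometry", {
  th <- seq(0, 2 * pi, length.out = 61L)[-61L]
  exy <- cbind(5 * cos(th), 3 * sin(th))
  sec <- visible_contour(section_graph(make_section(exy)), 360L)
  m <- section_metrics(sec)
  expect_equal(m$eccentricity, 0.8, tolerance = 0.01)
  expect_equal(m$d_min, 3, tolerance = 1e-6)
  expect_equal(m$d_max, 5, tolerance = 1e-6)

  circ <- cbind(4 * cos(th), 4 * sin(th))
  mc <- section_metrics(visible_contour(section_graph(make_section(circ)),
                                        360L))
  expect_equal(mc$d_min, 4, tolerance = 1e-6)
  expect_equal(mc$d_max, 4, tolerance = 1e-6)
  expect_lt(mc$eccentricity, 0.05)

  four <- make_section(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
  m4 <- section_metrics(visible_contour(section_graph(four, 3), 90L))
  expect_equal(m4$d_min, 1)
  expect_null(m4$ellipse)
  expect_true(is.na(m4$eccentricity))
})

test_that("in-plane rotation changes the ellipse pose, not its shape", {
  th <- seq(0, 2 * pi, length.out = 41L)[-41L]
  exy <- cbind(5 * cos(th), 3 * sin(th))
  f0 <- fit_ellipse(exy)
  ang <- 1.1
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  f1 <- fit_ellipse(exy %*% rot)
  expect_equal(f1$a, f0$a, tolerance = 1e-6)
  expect_equal(f1$b, f0$b, tolerance = 1e-6)
  expect_equal(f1$eccentricity, f0$eccentricity, tolerance = 1e-6)
})

test_that("the pentalobe tube shows exactly five radial lobes", {
  fx <- make_fixture("pentalobe_tube")
  res <- suppressMessages(suppressWarnings(
    analyze_structure(fx$atoms, sections = FALSE)))
  cl <- res$centerline
  mid <- which.min(abs(cl$points[, 3L] - 15))
  sec <- cut_section(res$channel_surface, cl$points[mid, ],
                     cl$tangent[mid, ])
  sec <- visible_contour(section_graph(sec), 360L)
  expect_identical(section_lobes(sec), 5L)
})

test_that("per-section summary aligns d_min with the local radius", {
  res <- cyl_pipeline()
  s <- res$sections
  cl <- res$centerline
  ok <- !s$empty & !is.na(s$d_min)
  expect_gt(mean(ok), 0.95)
  expect_gt(mean(abs(s$d_min[ok] - cl$radius[ok]) < 2 * 0.5), 0.95)
})
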