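# Small geometric helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Distance of points from the line through two anchors
#'
#' @param pts numeric matrix (n x 3).
#' @param a,b two distinct 3D points defining an infinite line.
#' @return numeric vector of point-to-line distances.
#' @keywords internal
point_line_distance <- function(pts, a, b) {
  u <- b - a
  un <- vnorm(u)
  if (un < 1e-12) stop("line endpoints coincide")
  u <- u / un
  d <- sweep(pts, 2L, a)
  proj <- drop(d %*% u)
  res <- d - outer(proj, u)
  sqrt(rowSums(res^2))
}

# Deterministic orthonormal in-plane basis (u, v) for a unit normal t:
# pick the Cartesian axis least aligned with t and Gram-Schmidt it.
plane_basis <- function(t) {
  k <- which.min(abs(t))
  e <- c(0, 0, 0)
  e[k] <- 1
  u <- e - sum(e * t) * t
  u <- u / vnorm(u)
  v <- cross3(t, u)
  list(u = u, v = v)
}

# Minimum distance from each row of `pts` to any of the `ref` points,
# looping over the smaller set to keep memory flat.
nearest_point_distance <- function(pts, ref, return_index = FALSE) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  idx <- rep(NA_integer_, n)
  for (j in seq_len(nrow(ref))) {
    d2 <- (pts[, 1L] - ref[j, 1L])^2 + (pts[, 2L] - ref[j, 2L])^2 +
      (pts[, 3L] - ref[j, 3L])^2
    hit <- d2 < best
    best[hit] <- d2[hit]
    idx[hit] <- j
  }
  if (return_index) list(distance = sqrt(best), index = idx) else sqrt(best)
}

# Deterministic degeneracy-breaking jitter.  Displacements are drawn from a
# fixed linear congruential generator seeded by the atom count and expressed
# in a frame anchored on the centroid and the first two atoms, so that the
# perturbed configuration is exactly covariant under rigid motions and
# uniform scaling of the input.
degeneracy_jitter <- function(centers, rel_amplitude = 1e-8) {
  n <- nrow(centers)
  rng <- (as.double(n) * 2654435761) %% 2147483647
  draws <- numeric(3L * n)
  for (i in seq_len(3L * n)) {
    rng <- (rng * 16807) %% 2147483647
    draws[i] <- rng / 2147483647 * 2 - 1
  }
  disp <- matrix(draws, ncol = 3L)
  ctr <- colMeans(centers)
  bbox <- apply(centers, 2L, range)
  amp <- rel_amplitude * max(vnorm(bbox[2L, ] - bbox[1L, ]), 1e-6)
  # covariant frame from the centroid and the first two atoms
  e1 <- centers[1L, ] - ctr
  if (vnorm(e1) < 1e-9) e1 <- c(1, 0, 0) else e1 <- e1 / vnorm(e1)
  k <- if (n >= 2L) 2L else 1L
  e2 <- centers[k, ] - ctr
  e2 <- e2 - sum(e2 * e1) * e1
  if (vnorm(e2) < 1e-9) {
    b <- plane_basis(e1)
    e2 <- b$u
  } else {
    e2 <- e2 / vnorm(e2)
  }
  e3 <- cross3(e1, e2)
  frame <- rbind(e1, e2, e3)
  centers + amp * (disp %*% frame)
}

# Signed tetrahedron volume for vertex matrices (each n x 3).
tet_signed_volume <- function(a, b, c, d) {
  u <- b - a
  v <- c - a
  w <- d - a
  (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
    u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
    u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (Fitzgibbon's direct method) to
#' 2D points and converts it to center, semi-axes and orientation.
#'
#' @param xy numeric matrix (n x 2), n >= 5.
#' @return list with `center`, `a`, `b` (semi-axes, `a >= b`), `angle`
#'   (radians, orientation of the major axis) and `eccentricity`.
#' @export
fit_ellipse <- function(xy) {
  if (!is.matrix(xy) || ncol(xy) != 2L) stop("xy must be an n x 2 matrix")
  if (nrow(xy) < 5L) stop("need at least 5 points to fit an ellipse")
  x <- xy[, 1L] - mean(xy[, 1L])
  y <- xy[, 2L] - mean(xy[, 2L])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  vals <- Re(ev$values)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1L, ] * vecs[3L, ] - vecs[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("points do not determine an ellipse")
  a1 <- vecs[, ok[1L]]
  coef <- c(a1, drop(Tm %*% a1))  # A B C D E F on centered coordinates
  A <- coef[1L]; B <- coef[2L]; C <- coef[3L]
  D <- coef[4L]; E <- coef[5L]; Fc <- coef[6L]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  axis1 <- -sqrt(num * ((A + C) + s)) / den
  axis2 <- -sqrt(num * ((A + C) - s)) / den
  ang <- 0.5 * atan2(-B, C - A)
  if (axis1 < axis2) {
    tmp <- axis1; axis1 <- axis2; axis2 <- tmp
    ang <- ang + pi / 2
  }
  list(center = c(cx + mean(xy[, 1L]), cy + mean(xy[, 2L])),
       a = axis1, b = axis2,
       angle = ang %% pi,
       eccentricity = sqrt(max(0, 1 - (axis2 / axis1)^2)))
}
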