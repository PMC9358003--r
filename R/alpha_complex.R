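#' Weighted Delaunay (regular) triangulation of probe-inflated atoms
#'
#' Builds the regular triangulation of the atom centers weighted by
#' `(radius + probe)^2`.  The triangulation tiles the convex hull of the
#' centers; faces on the hull are marked with neighbor id 0 and conceptually
#' connect to a point at infinity.  Each tetrahedron carries its orthocenter
#' (the point with equal power distance to its four weighted vertices) and
#' the signed squared orthoradius, from which the alpha complex at alpha = 0
#' is classified: tetrahedra with non-positive squared orthoradius are
#' interior to the molecule, the rest belong to the complement.
#'
#' A deterministic jitter (relative amplitude `1e-8` of the bounding-box
#' diagonal, seed derived from the atom count) breaks cospherical and
#' coplanar degeneracies; the jittered coordinates are stored in the result
#' so that downstream oracles operate on exactly the triangulated input.
#' Points whose power cell is empty (hidden inside another ball's cell) do
#' not appear in any tetrahedron and are listed in `$redundant`.
#'
#' @param atoms an [atom_set] with at least 5 atoms.
#' @param probe solvent probe radius in Angstrom (default 1.4, water).
#' @param jitter relative jitter amplitude; 0 disables degeneracy breaking.
#' @return an object of class `tetrahedralization` with elements `tets`
#'   (m x 4, 1-based atom ids), `neighbors` (m x 4, 0 marks a convex-hull
#'   face), `orthocenter` (m x 3), `sq_orthoradius`, `volume`, `interior`
#'   (logical), `points` (jittered centers), `weights`, `probe`,
#'   `redundant` (atom ids absent from the triangulation).
#' @export
weighted_delaunay <- function(atoms, probe = 1.4, jitter = 1e-8) {
  stopifnot(inherits(atoms, "atom_set"))
  if (probe < 0) stop("probe radius must be non-negative")
  n <- nrow(atoms$centers)
  if (n < 5L) stop("need at least 5 atoms to tetrahedralize")
  ctr <- scale(atoms$centers, scale = FALSE)
  if (min(svd(ctr, nu = 0, nv = 0)$d) < 1e-9 * max(svd(ctr, nu = 0, nv = 0)$d))
    stop("degenerate input: all atom centers are coplanar")
  pts <- if (jitter > 0) degeneracy_jitter(atoms$centers, jitter)
         else atoms$centers
  w <- (atoms$radii + probe)^2
  res <- rt_build(pts, w)
  interior <- res$sq_orthoradius <= 1e-9
  structure(list(tets = res$tets, neighbors = res$neighbors,
                 orthocenter = res$orthocenter,
                 sq_orthoradius = res$sq_orthoradius,
                 volume = res$volume, interior = interior,
                 points = pts, weights = w, probe = probe,
                 radii = atoms$radii,
                 redundant = res$redundant),
            class = "tetrahedralization")
}

#' @export
print.tetrahedralization <- function(x, ...) {
  cat(sprintf(
    "<tetrahedralization> %d tets over %d atoms (%d interior, %d redundant)\n",
    nrow(x$tets), nrow(x$points), sum(x$interior), length(x$redundant)))
  invisible(x)
}

#' Orthosphere of four weighted points
#'
#' Returns the center equidistant (in power distance) from four weighted
#' points and the common power value, the signed squared orthoradius.  With
#' equal weights the center is the ordinary circumcenter and the squared
#' orthoradius is the squared circumradius minus the weight.
#'
#' @param centers numeric matrix (4 x 3).
#' @param weights numeric vector of 4 weights (squared radii).
#' @return list with `center` (length-3) and `sq_radius` (may be negative).
#' @export
orthosphere <- function(centers, weights) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 4L || ncol(centers) != 3L)
    stop("centers must be a 4 x 3 matrix")
  vol <- abs(tet_signed_volume(centers[1L, , drop = FALSE],
                               centers[2L, , drop = FALSE],
                               centers[3L, , drop = FALSE],
                               centers[4L, , drop = FALSE]))
  if (vol < 1e-12)
    stop("degenerate tetrahedron: vertices are (nearly) coplanar")
  a <- centers[1L, ]
  A <- 2 * sweep(centers[2:4, , drop = FALSE], 2L, a)
  lift <- rowSums(centers^2) - weights
  rhs <- lift[2:4] - lift[1L]
  z <- drop(solve(A, rhs))
  list(center = z, sq_radius = sum((z - a)^2) - weights[1L])
}

#' Classify tetrahedra as interior (alpha complex at alpha = 0)
#'
#' A tetrahedron is interior to the molecule exactly when its signed squared
#' orthoradius is non-positive (a small positive tolerance absorbs roundoff).
#'
#' @param T a `tetrahedralization`.
#' @param tol roundoff tolerance on the squared orthoradius.
#' @return logical vector of interior flags (also stored back on the object
#'   when assigned).
#' @export
classify_interior <- function(T, tol = 1e-9) {
  stopifnot(inherits(T, "tetrahedralization"))
  T$sq_orthoradius <= tol
}
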