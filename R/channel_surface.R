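#' Build a triangulated molecular surface from a union of balls
#'
#' Extracts the zero level set of `f(x) = min_i(|x - c_i| - r_i)`, the
#' boundary of the union of atom balls, by marching tetrahedra on a regular
#' grid.  This stands in for a rolling-probe solvent-excluded surface: it is
#' geometrically consistent with the probe-inflated triangulation (a bare
#' cylindrical wall of balls of radius r at axis distance R yields a lumen of
#' radius R - r) and an externally computed SES mesh read with [read_mesh()]
#' can be used in its place everywhere downstream.
#'
#' @param atoms an [atom_set].
#' @param probe probe radius, Angstrom; retained so the surface and the
#'   triangulation are parameterized together (the level set itself is the
#'   union-of-balls boundary at the stored radii).
#' @param grid_spacing marching grid step in Angstrom (default 0.5); must
#'   resolve the smallest atom.
#' @return a closed, outward-oriented [surface_mesh].
#' @export
build_surface <- function(atoms, probe = 1.4, grid_spacing = 0.5) {
  stopifnot(inherits(atoms, "atom_set"))
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (grid_spacing > min(atoms$radii))
    stop(sprintf(
      "grid too coarse: spacing %.2f A exceeds the smallest radius %.2f A",
      grid_spacing, min(atoms$radii)))
  ctr <- atoms$centers
  r <- atoms$radii
  margin <- max(r) + 3 * grid_spacing
  lo <- apply(ctr, 2L, min) - margin
  hi <- apply(ctr, 2L, max) + margin
  dims <- as.integer(ceiling((hi - lo) / grid_spacing)) + 2L
  # distance field: local min-updates over each atom's padded bounding box
  field <- array(1e6, dim = dims)
  ax <- lo[1L] + (seq_len(dims[1L]) - 1L) * grid_spacing
  ay <- lo[2L] + (seq_len(dims[2L]) - 1L) * grid_spacing
  az <- lo[3L] + (seq_len(dims[3L]) - 1L) * grid_spacing
  for (i in seq_len(nrow(ctr))) {
    pad <- r[i] + 4 * grid_spacing
    ix <- which(ax >= ctr[i, 1L] - pad & ax <= ctr[i, 1L] + pad)
    iy <- which(ay >= ctr[i, 2L] - pad & ay <= ctr[i, 2L] + pad)
    iz <- which(az >= ctr[i, 3L] - pad & az <= ctr[i, 3L] + pad)
    dx2 <- (ax[ix] - ctr[i, 1L])^2
    dy2 <- (ay[iy] - ctr[i, 2L])^2
    dz2 <- (az[iz] - ctr[i, 3L])^2
    d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`)) - r[i]
    sub <- field[ix, iy, iz]
    field[ix, iy, iz] <- pmin(sub, d)
  }
  res <- mt_isosurface(as.vector(field), dims, lo, grid_spacing, 0)
  if (nrow(res$vertices) == 0L)
    stop("empty isosurface: grid does not intersect the union of balls")
  surface_mesh(res$vertices, res$triangles)
}

# barycenters of all mesh triangles
triangle_barycenters <- function(mesh) {
  (mesh$vertices[mesh$triangles[, 1L], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]) / 3
}

# which of the query points lie inside the given tetrahedron (4 signed
# volumes with a relative tolerance)
points_in_tet <- function(pts, verts, tol = 1e-9) {
  n <- nrow(pts)
  total <- abs(tet_signed_volume(verts[1L, , drop = FALSE],
                                 verts[2L, , drop = FALSE],
                                 verts[3L, , drop = FALSE],
                                 verts[4L, , drop = FALSE]))
  if (total < 1e-15) return(rep(FALSE, n))
  rep1 <- function(v) matrix(v, n, 3L, byrow = TRUE)
  s1 <- tet_signed_volume(pts, rep1(verts[2L, ]), rep1(verts[3L, ]),
                          rep1(verts[4L, ]))
  s2 <- tet_signed_volume(rep1(verts[1L, ]), pts, rep1(verts[3L, ]),
                          rep1(verts[4L, ]))
  s3 <- tet_signed_volume(rep1(verts[1L, ]), rep1(verts[2L, ]), pts,
                          rep1(verts[4L, ]))
  s4 <- tet_signed_volume(rep1(verts[1L, ]), rep1(verts[2L, ]),
                          rep1(verts[3L, ]), pts)
  eps <- tol * total
  ref <- tet_signed_volume(verts[1L, , drop = FALSE],
                           verts[2L, , drop = FALSE],
                           verts[3L, , drop = FALSE],
                           verts[4L, , drop = FALSE])
  sgn <- sign(ref)
  s1 * sgn >= -eps & s2 * sgn >= -eps & s3 * sgn >= -eps & s4 * sgn >= -eps
}

#' Extract the channel portion of a molecular surface
#'
#' Keeps exactly those mesh triangles whose barycenter lies inside at least
#' one tetrahedron of the channel component; candidate triangles per
#' tetrahedron are restricted by a bounding-box prefilter before the exact
#' signed-volume containment test.
#'
#' @param mesh a [surface_mesh] of the whole molecule.
#' @param channel a `cavity_component` (normally from [select_channel()]).
#' @param T the `tetrahedralization` the channel belongs to.
#' @param atoms optional [atom_set]; when given, each kept triangle is
#'   annotated with its nearest atom.
#' @return an object of class `channel_surface`: `triangle_ids`,
#'   `barycenters`, `nearest_atom`, plus the `mesh` it refers to.
#' @export
extract_channel_surface <- function(mesh, channel, T, atoms = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(channel, "cavity_component"),
            inherits(T, "tetrahedralization"))
  bary <- triangle_barycenters(mesh)
  inside <- logical(nrow(bary))
  for (tid in channel$tet_ids) {
    verts <- T$points[T$tets[tid, ], , drop = FALSE]
    lo <- apply(verts, 2L, min) - 1e-9
    hi <- apply(verts, 2L, max) + 1e-9
    cand <- which(!inside &
                    bary[, 1L] >= lo[1L] & bary[, 1L] <= hi[1L] &
                    bary[, 2L] >= lo[2L] & bary[, 2L] <= hi[2L] &
                    bary[, 3L] >= lo[3L] & bary[, 3L] <= hi[3L])
    if (length(cand) == 0L) next
    hit <- points_in_tet(bary[cand, , drop = FALSE], verts)
    inside[cand[hit]] <- TRUE
  }
  ids <- which(inside)
  if (length(ids) == 0L)
    stop("channel tetrahedra do not overlap the surface mesh; ",
         "inputs are inconsistent")
  nearest <- NULL
  if (!is.null(atoms)) {
    nn <- nearest_point_distance(bary[ids, , drop = FALSE], atoms$centers,
                                 return_index = TRUE)
    nearest <- nn$index
  }
  structure(list(triangle_ids = ids,
                 barycenters = bary[ids, , drop = FALSE],
                 nearest_atom = nearest,
                 mesh = mesh),
            class = "channel_surface")
}

#' @export
print.channel_surface <- function(x, ...) {
  cat(sprintf("<channel_surface> %d of %d triangles\n",
              length(x$triangle_ids), nrow(x$mesh$triangles)))
  invisible(x)
}

# vertices referenced by the channel triangles (deduplicated)
channel_surface_vertices <- function(cs) {
  vid <- unique(as.vector(cs$mesh$triangles[cs$triangle_ids, , drop = FALSE]))
  cs$mesh$vertices[vid, , drop = FALSE]
}

#' Annotate the pore lumen with atom and residue identities
#'
#' Maps each channel-surface triangle to the atom nearest to its barycenter
#' and summarizes which residues line the lumen.
#'
#' @param cs a `channel_surface` from [extract_channel_surface()].
#' @param atoms the [atom_set] the surface was built from.
#' @return list with `triangles` (per-triangle data.frame of labels) and
#'   `residues` (occurrence table of residues facing the lumen).  Unlabeled
#'   atoms are reported as `"UNK"`.
#' @export
annotate_lumen <- function(cs, atoms) {
  stopifnot(inherits(cs, "channel_surface"), inherits(atoms, "atom_set"))
  nn <- nearest_point_distance(cs$barycenters, atoms$centers,
                               return_index = TRUE)
  idx <- nn$index
  if (is.null(atoms$labels)) {
    lab <- data.frame(atom = "UNK", resid = "UNK",
                      resno = NA_integer_, chain = "UNK")[rep(1L, length(idx)), ]
  } else {
    lab <- atoms$labels[idx, , drop = FALSE]
  }
  lab$triangle_id <- cs$triangle_ids
  lab$atom_id <- idx
  lab$distance <- nn$distance
  rownames(lab) <- NULL
  res_key <- paste(lab$resid, lab$resno, lab$chain)
  list(triangles = lab,
       residues = as.data.frame(table(residue = res_key),
                                stringsAsFactors = FALSE))
}
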