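# Planar cross-sections of the channel surface, visibility filtering and
# per-section shape metrics.

#' Cut the channel surface with a plane
#'
#' Intersects every channel triangle with the plane through `p` orthogonal
#' to the unit vector `t_p` and collects the segment endpoints, deduplicated
#' at 1e-6 A and expressed both in 3D and in a deterministic orthonormal
#' in-plane basis.
#'
#' @param cs a `channel_surface`.
#' @param p 3D anchor point (normally a centerline point).
#' @param t_p unit plane normal (normally the centerline tangent at `p`).
#' @return an object of class `channel_section` with `points3d`, `points2d`,
#'   `p`, `normal`, `basis`, and `empty` flag; an empty section (plane
#'   missing the surface) is returned flagged rather than as an error.
#' @export
cut_section <- function(cs, p, t_p) {
  stopifnot(inherits(cs, "channel_surface"))
  if (abs(vnorm(t_p) - 1) > 1e-6) stop("t_p must be a unit vector")
  mesh <- cs$mesh
  tri <- mesh$triangles[cs$triangle_ids, , drop = FALSE]
  sd_all <- drop(sweep(mesh$vertices, 2L, p) %*% t_p)
  s1 <- sd_all[tri[, 1L]]
  s2 <- sd_all[tri[, 2L]]
  s3 <- sd_all[tri[, 3L]]
  crosses <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  basis <- plane_basis(t_p)
  if (!any(crosses)) {
    return(structure(list(points3d = matrix(numeric(0), 0L, 3L),
                          points2d = matrix(numeric(0), 0L, 2L),
                          p = p, normal = t_p, basis = basis, empty = TRUE),
                     class = "channel_section"))
  }
  tri <- tri[crosses, , drop = FALSE]
  sv <- cbind(s1[crosses], s2[crosses], s3[crosses])
  pts <- matrix(numeric(0), 0L, 3L)
  combos <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (cb in combos) {
    a <- sv[, cb[1L]]
    b <- sv[, cb[2L]]
    hit <- which(a * b < 0)
    if (length(hit) == 0L) next
    va <- mesh$vertices[tri[hit, cb[1L]], , drop = FALSE]
    vb <- mesh$vertices[tri[hit, cb[2L]], , drop = FALSE]
    tfrac <- a[hit] / (a[hit] - b[hit])
    pts <- rbind(pts, va + tfrac * (vb - va))
  }
  # deduplicate at 1e-6 A
  key <- paste(round(pts[, 1L] * 1e6), round(pts[, 2L] * 1e6),
               round(pts[, 3L] * 1e6))
  pts <- pts[!duplicated(key), , drop = FALSE]
  rel <- sweep(pts, 2L, p)
  p2 <- cbind(drop(rel %*% basis$u), drop(rel %*% basis$v))
  structure(list(points3d = pts, points2d = p2, p = p, normal = t_p,
                 basis = basis, empty = FALSE),
            class = "channel_section")
}

#' @export
print.channel_section <- function(x, ...) {
  cat(sprintf("<channel_section> %d points%s\n", nrow(x$points3d),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Proximity graph over section points
#'
#' Connects pairs of section points closer (in-plane) than a threshold and
#' labels the connected components.  The default threshold is 3 times the
#' median nearest-neighbor distance of the section, which adapts to mesh
#' resolution.
#'
#' @param section a `channel_section`.
#' @param threshold connection distance in Angstrom, or `NULL` for the
#'   adaptive default.
#' @return the section with `component` (per-point labels) and `threshold`
#'   attached.
#' @export
section_graph <- function(section, threshold = NULL) {
  stopifnot(inherits(section, "channel_section"))
  n <- nrow(section$points2d)
  if (n == 0L) {
    section$component <- integer(0)
    section$threshold <- threshold
    return(section)
  }
  d <- as.matrix(dist(section$points2d))
  if (is.null(threshold)) {
    diag(d) <- Inf
    nnd <- apply(d, 1L, min)
    threshold <- 3 * median(nnd[is.finite(nnd)])
    diag(d) <- 0
  }
  if (threshold <= 0) stop("threshold must be positive")
  adj <- d < threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  section$component <- as.integer(igraph::components(g)$membership)
  section$threshold <- threshold
  section
}

#' Visible contour of a section
#'
#' Shoots `n_rays` uniformly spaced in-plane rays from the anchor point.
#' For each ray, among the section points within half a ray spacing of its
#' direction, the one closest to the anchor is selected and its proximity
#' component collected; the union of collected components is the part of the
#' section visible from the centerline.
#'
#' @param section a `channel_section` with components from [section_graph()].
#' @param n_rays number of rays (>= 8; default 360).
#' @return the section with `visible` (logical per point) and
#'   `visible_components` attached.
#' @export
visible_contour <- function(section, n_rays = 360L) {
  stopifnot(inherits(section, "channel_section"))
  if (n_rays < 8L) stop("need at least 8 rays")
  if (is.null(section$component))
    stop("run section_graph() before visible_contour()")
  n <- nrow(section$points2d)
  if (n == 0L) {
    section$visible <- logical(0)
    section$visible_components <- integer(0)
    return(section)
  }
  ang <- atan2(section$points2d[, 2L], section$points2d[, 1L])
  rad <- sqrt(rowSums(section$points2d^2))
  spacing <- 2 * pi / n_rays
  half <- spacing / 2
  hit_components <- integer(0)
  for (k in seq_len(n_rays)) {
    theta <- -pi + (k - 1L) * spacing
    delta <- abs(((ang - theta + pi) %% (2 * pi)) - pi)
    cand <- which(delta <= half)
    if (length(cand) == 0L) next
    hit_components <- c(hit_components,
                        section$component[cand[which.min(rad[cand])]])
  }
  vis_comp <- sort(unique(hit_components))
  section$visible <- section$component %in% vis_comp
  section$visible_components <- vis_comp
  section
}

#' Shape metrics of a section's visible contour
#'
#' Closest and farthest visible points from the anchor (and their
#' distances), plus a direct least-squares ellipse fit of the visible points
#' with eccentricity `e = sqrt(1 - b^2 / a^2)`.  The ellipse is omitted
#' (NA) when fewer than 5 points are visible or the fit degenerates.
#'
#' @param section a `channel_section` after [visible_contour()].
#' @return list with `d_min`, `d_max`, `n_visible`, `n_components`,
#'   `ellipse` (or `NULL`) and `eccentricity` (or `NA`).
#' @export
section_metrics <- function(section) {
  stopifnot(inherits(section, "channel_section"))
  if (is.null(section$visible))
    stop("run visible_contour() before section_metrics()")
  vis <- which(section$visible)
  if (length(vis) == 0L) {
    return(list(d_min = NA_real_, d_max = NA_real_, n_visible = 0L,
                n_components = 0L, ellipse = NULL, eccentricity = NA_real_))
  }
  rad <- sqrt(rowSums(section$points2d[vis, , drop = FALSE]^2))
  ell <- NULL
  ecc <- NA_real_
  if (length(vis) >= 5L) {
    ell <- tryCatch(fit_ellipse(section$points2d[vis, , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(ell)) ecc <- ell$eccentricity
  }
  list(d_min = min(rad), d_max = max(rad),
       n_visible = length(vis),
       n_components = length(section$visible_components),
       ellipse = ell, eccentricity = ecc)
}

#' Cross-section summary along a centerline
#'
#' Cuts one section per centerline point (optionally strided), reduces each
#' to its visible contour and tabulates the per-section metrics.
#'
#' @param cs a `channel_surface`.
#' @param cl a `centerline`.
#' @param stride keep every `stride`-th centerline point (default 1).
#' @param n_rays rays for the visibility filter.
#' @param threshold proximity threshold for [section_graph()] (`NULL` =
#'   adaptive).
#' @return data.frame with one row per section: `arclength`, `d_min`,
#'   `d_max`, `a`, `b`, `eccentricity`, `n_visible`, `n_components`,
#'   `empty`.
#' @export
channel_sections <- function(cs, cl, stride = 1L, n_rays = 360L,
                             threshold = NULL) {
  stopifnot(inherits(cs, "channel_surface"), inherits(cl, "centerline"))
  idx <- seq(1L, nrow(cl$points), by = stride)
  rows <- lapply(idx, function(i) {
    sec <- cut_section(cs, cl$points[i, ], cl$tangent[i, ])
    if (sec$empty) {
      return(data.frame(arclength = cl$arclength[i], d_min = NA_real_,
                        d_max = NA_real_, a = NA_real_, b = NA_real_,
                        eccentricity = NA_real_, n_visible = 0L,
                        n_components = 0L, empty = TRUE))
    }
    sec <- visible_contour(section_graph(sec, threshold), n_rays)
    m <- section_metrics(sec)
    data.frame(arclength = cl$arclength[i], d_min = m$d_min,
               d_max = m$d_max,
               a = if (is.null(m$ellipse)) NA_real_ else m$ellipse$a,
               b = if (is.null(m$ellipse)) NA_real_ else m$ellipse$b,
               eccentricity = m$eccentricity, n_visible = m$n_visible,
               n_components = m$n_components, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count radial lobes of a section
#'
#' Bins the visible contour's distance-to-anchor function by angle, smooths
#' it with a circular moving average, and counts strict circular local
#' maxima.  Used to quantify lobed (symmetry-broken) channel sections.
#'
#' @param section a `channel_section` after [visible_contour()].
#' @param n_bins angular bins (default 72, i.e. 5 degrees).
#' @param smooth_bins circular moving-average half-window in bins
#'   (default 2).
#' @return integer number of local maxima of the radial profile.
#' @export
section_lobes <- function(section, n_bins = 72L, smooth_bins = 2L) {
  stopifnot(inherits(section, "channel_section"))
  vis <- which(section$visible)
  if (length(vis) < n_bins / 2L) stop("too few visible points to bin")
  ang <- atan2(section$points2d[vis, 2L], section$points2d[vis, 1L])
  rad <- sqrt(rowSums(section$points2d[vis, , drop = FALSE]^2))
  bin <- floor((ang + pi) / (2 * pi) * n_bins) %% n_bins + 1L
  prof <- rep(NA_real_, n_bins)
  agg <- vapply(split(rad, bin), mean, numeric(1L))
  prof[as.integer(names(agg))] <- agg
  # fill empty bins by circular interpolation from neighbors
  while (anyNA(prof)) {
    na <- which(is.na(prof))
    for (i in na) {
      nb <- c(prof[(i - 2L) %% n_bins + 1L], prof[i %% n_bins + 1L])
      if (!all(is.na(nb))) prof[i] <- mean(nb, na.rm = TRUE)
    }
  }
  sm <- prof
  for (i in seq_len(n_bins)) {
    j <- ((i - smooth_bins - 1L):(i + smooth_bins - 1L)) %% n_bins + 1L
    sm[i] <- mean(prof[j])
  }
  nxt <- sm[c(2:n_bins, 1L)]
  prv <- sm[c(n_bins, 1:(n_bins - 1L))]
  sum(sm > prv & sm >= nxt)
}
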