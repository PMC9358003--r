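#' Compute a smooth centerline between two skeleton nodes
#'
#' Finds the minimum-cost path on the skeleton graph with edge cost
#' `edge_length / mean(clearance of endpoints)^2`, which pulls the path
#' toward maximal inscribed spheres (a Voronoi-style centerline), then
#' smooths the node positions with a moving average of window 5 and
#' resamples the curve at a uniform arclength step.  Frenet frames,
#' curvature and torsion are attached by [frenet()].
#'
#' @param g a `skeleton_graph`.
#' @param source,target node ids in `g` (normally the pruned path endpoints).
#' @param step resampling step in Angstrom (default 0.5).
#' @param smooth_window moving-average window over path nodes (default 5).
#' @param clearance_exponent exponent on the mean clearance in the edge cost
#'   (default 2; larger values penalize wall-hugging more strongly).
#' @return an object of class `centerline` with `points`, `arclength`,
#'   `tangent`, `normal`, `binormal`, `curvature`, `torsion`, `frame_ok`
#'   and a `radius` slot filled by [local_radius()].
#' @export
compute_centerline <- function(g, source, target, step = 0.5,
                               smooth_window = 5L, clearance_exponent = 2) {
  stopifnot(inherits(g, "skeleton_graph"))
  k <- nrow(g$nodes)
  if (source < 1L || source > k || target < 1L || target > k)
    stop("source/target outside the skeleton")
  if (source == target)
    stop("source and target coincide; no centerline between them")
  if (step <= 0) stop("step must be positive")
  cl <- pmax(g$clearance, 1e-6)
  w <- g$edge_length /
    ((cl[g$edges[, 1L]] + cl[g$edges[, 2L]]) / 2)^clearance_exponent
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, k - igraph::vcount(ig)))
  sp <- suppressWarnings(
    igraph::shortest_paths(ig, from = source, to = target, weights = w,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1L]])
  if (length(vp) < 2L)
    stop("source and target are not connected in the skeleton")
  pts <- g$nodes[vp, , drop = FALSE]
  # clearance^2-weighted smoothing: within each window the widest (most
  # medial) nodes dominate the average, pulling the curve onto the axis
  pts <- moving_average_rows(pts, smooth_window,
                             weights = pmax(g$clearance[vp], 0.1)^2)
  pts <- moving_average_rows(pts, smooth_window)
  res <- resample_polyline(pts, step)
  cl <- structure(list(points = res$points, arclength = res$arclength,
                       source = source, target = target, step = step),
                  class = "centerline")
  frenet(cl)
}

# centered (optionally weighted) moving average, truncated at the ends
moving_average_rows <- function(pts, window, weights = NULL) {
  n <- nrow(pts)
  if (window <= 1L || n < 3L) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- if (is.null(weights)) rep(1, length(j)) else weights[j]
    out[i, ] <- colSums(pts[j, , drop = FALSE] * w) / sum(w)
  }
  out
}

# uniform arclength resampling by linear interpolation
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L)
    return(list(points = pts, arclength = 0))
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  ns <- max(2L, round(total / step) + 1L)
  si <- seq(0, total, length.out = ns)
  out <- cbind(approx(s, pts[, 1L], xout = si)$y,
               approx(s, pts[, 2L], xout = si)$y,
               approx(s, pts[, 3L], xout = si)$y)
  list(points = out, arclength = si)
}

#' Frenet frames, curvature and torsion of a centerline
#'
#' Differentiates the arclength-parametrized points by central finite
#' differences (one-sided at the endpoints): curvature
#' `kappa = |c' x c''| / |c'|^3` and torsion from the standard
#' triple-product formula `tau = det(c', c'', c''') / |c' x c''|^2`.
#' Where curvature vanishes (below 1e-9) the normal and binormal are
#' undefined; such frames are flagged and torsion is reported as 0.
#'
#' @param cl a `centerline` (at least 5 points for meaningful results).
#' @return the centerline with `tangent`, `normal`, `binormal`,
#'   `curvature`, `torsion` and `frame_ok` filled in.
#' @export
frenet <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  s <- cl$arclength
  n <- nrow(p)
  if (n < 3L) {
    cl$tangent <- matrix(rep(c(1, 0, 0), each = n), n, 3L)
    cl$curvature <- rep(0, n)
    cl$torsion <- rep(0, n)
    cl$frame_ok <- rep(FALSE, n)
    return(cl)
  }
  d1 <- fd_derivative(p, s)
  d2 <- fd_derivative(d1, s)
  d3 <- fd_derivative(d2, s)
  cr <- cbind(d1[, 2L] * d2[, 3L] - d1[, 3L] * d2[, 2L],
              d1[, 3L] * d2[, 1L] - d1[, 1L] * d2[, 3L],
              d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L])
  crn <- sqrt(rowSums(cr^2))
  d1n <- sqrt(rowSums(d1^2))
  kappa <- crn / pmax(d1n, 1e-300)^3
  tau <- rowSums(cr * d3) / pmax(crn, 1e-300)^2
  ok <- kappa >= 1e-9
  tau[!ok] <- 0
  tangent <- d1 / pmax(d1n, 1e-300)
  normal <- matrix(NA_real_, n, 3L)
  binormal <- matrix(NA_real_, n, 3L)
  if (any(ok)) {
    b <- cr[ok, , drop = FALSE] / crn[ok]
    binormal[ok, ] <- b
    tn <- tangent[ok, , drop = FALSE]
    normal[ok, ] <- cbind(b[, 2L] * tn[, 3L] - b[, 3L] * tn[, 2L],
                          b[, 3L] * tn[, 1L] - b[, 1L] * tn[, 3L],
                          b[, 1L] * tn[, 2L] - b[, 2L] * tn[, 1L])
  }
  cl$tangent <- tangent
  cl$normal <- normal
  cl$binormal <- binormal
  cl$curvature <- kappa
  cl$torsion <- tau
  cl$frame_ok <- ok
  cl
}

# derivative of rows with respect to (possibly non-uniform) arclength
fd_derivative <- function(y, s) {
  n <- nrow(y)
  out <- matrix(NA_real_, n, ncol(y))
  out[1L, ] <- (y[2L, ] - y[1L, ]) / (s[2L] - s[1L])
  out[n, ] <- (y[n, ] - y[n - 1L, ]) / (s[n] - s[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    out[i, ] <- (y[i + 1L, , drop = FALSE] - y[i - 1L, , drop = FALSE]) /
      (s[i + 1L] - s[i - 1L])
  }
  out
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arclength %.1f A\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' Local pore radius along a centerline
#'
#' Distance from each centerline point to the nearest vertex of the channel
#' surface; this matches the minimum visible-contour distance of the section
#' at that point to within the mesh resolution.
#'
#' @param cl a `centerline`.
#' @param cs a `channel_surface`.
#' @return the centerline with a `radius` vector attached.
#' @export
local_radius <- function(cl, cs) {
  stopifnot(inherits(cl, "centerline"), inherits(cs, "channel_surface"))
  sv <- channel_surface_vertices(cs)
  if (nrow(sv) == 0L) stop("channel surface has no vertices")
  cl$radius <- nearest_point_distance(cl$points, sv)
  cl
}

#' Pore radius profile along the z axis
#'
#' Re-bins per-frame `(z, radius)` samples along the axial coordinate and
#' reports mean, sample standard deviation and sample count per bin; bins
#' without samples are omitted.
#'
#' @param samples data.frame with columns `z` and `radius` (and optionally
#'   `frame`), typically pooled across trajectory frames.
#' @param bin_width bin width in Angstrom (default 1).
#' @return data.frame with `z` (bin center), `mean_radius`, `sd`, `n`.
#' @export
radius_profile <- function(samples, bin_width = 1) {
  if (is.null(samples) || nrow(samples) == 0L)
    stop("no radius samples to bin")
  if (bin_width <= 0) stop("bin_width must be positive")
  z0 <- min(samples$z)
  bin <- floor((samples$z - z0) / bin_width)
  agg <- split(samples$radius, bin)
  out <- data.frame(
    z = z0 + (as.integer(names(agg)) + 0.5) * bin_width,
    mean_radius = vapply(agg, mean, numeric(1L)),
    sd = vapply(agg, function(v) if (length(v) > 1L) sd(v) else 0,
                numeric(1L)),
    n = lengths(agg))
  rownames(out) <- NULL
  out[order(out$z), , drop = FALSE]
}
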