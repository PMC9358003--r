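#' Analyze a single structure end to end
#'
#' Runs the full pipeline on one atom set: weighted Delaunay triangulation,
#' discrete-flow cavity segmentation, channel selection, surface extraction,
#' skeletonization, pruning (or externally supplied endpoints for warm
#' starts), centerline with local radii, and per-section metrics.
#'
#' @param atoms an [atom_set].
#' @param probe probe radius, A (default 1.4).
#' @param grid_spacing surface grid step, A (default 0.5).
#' @param step centerline resampling step, A (default 0.5).
#' @param mesh optional externally computed [surface_mesh] used instead of
#'   the built-in union-of-balls surface.
#' @param skeleton optional externally computed `skeleton_graph`.
#' @param endpoints optional length-2 list of 3D points; when given, the
#'   pruning stage is skipped and the skeleton nodes nearest to these points
#'   (within `capture` A) are used as centerline endpoints.
#' @param capture warm-start capture radius, A (default 5).
#' @param require_mouths passed to [select_channel()].
#' @param sections compute per-section metrics (default TRUE).
#' @param section_stride stride over centerline points for sections.
#' @return list with the intermediate objects (`triangulation`, `cavities`,
#'   `channel`, `surface`, `channel_surface`, `skeleton`, `path`,
#'   `centerline`, `sections`) plus `radius_samples` (z, radius per
#'   centerline point).
#' @export
analyze_structure <- function(atoms, probe = 1.4, grid_spacing = 0.5,
                              step = 0.5, mesh = NULL, skeleton = NULL,
                              endpoints = NULL, capture = 5,
                              require_mouths = TRUE, sections = TRUE,
                              section_stride = 1L) {
  T <- weighted_delaunay(atoms, probe)
  cavities <- find_cavities(T)
  channel <- select_channel(cavities, require_mouths = require_mouths)
  surf <- if (is.null(mesh)) build_surface(atoms, probe, grid_spacing)
          else mesh
  cs <- extract_channel_surface(surf, channel, T, atoms)
  skel <- if (is.null(skeleton)) build_skeleton(channel, T) else skeleton

  path <- NULL
  if (is.null(endpoints)) {
    path <- prune_skeleton(skel)
    src <- path$node_ids[1L]
    tgt <- path$node_ids[length(path$node_ids)]
  } else {
    snap <- function(pt) {
      d <- sqrt(colSums((t(skel$nodes) - pt)^2))
      i <- which.min(d)
      if (d[i] > capture) NA_integer_ else i
    }
    src <- snap(endpoints[[1L]])
    tgt <- snap(endpoints[[2L]])
    if (is.na(src) || is.na(tgt) || src == tgt)
      stop("warm-start endpoints not captured by the new skeleton")
  }
  cl <- compute_centerline(skel, src, tgt, step = step)
  cl <- local_radius(cl, cs)
  secs <- if (sections) channel_sections(cs, cl, stride = section_stride)
          else NULL
  list(triangulation = T, cavities = cavities, channel = channel,
       surface = surf, channel_surface = cs, skeleton = skel, path = path,
       centerline = cl, sections = secs,
       # warm starts snap these to the next frame's skeleton nodes, so the
       # unsmoothed node positions (exactly recoverable on a static frame)
       # are carried rather than the smoothed centerline tips
       endpoints = list(skel$nodes[src, ], skel$nodes[tgt, ]),
       radius_samples = data.frame(z = cl$points[, 3L], radius = cl$radius))
}
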