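# Discrete-flow segmentation of the complement tetrahedra.
#
# Adjacent complement tetrahedra are partially ordered by the flow relation:
# A flows into B when A's orthocenter lies strictly beyond their shared face,
# on B's side.  Complement tetrahedra whose flow escapes to infinity (through
# a convex-hull face, possibly transitively) form the bulk solvent; the
# remaining complement tetrahedra are cavities.  A cavity component with no
# mouth is a void, one mouth a pocket, two or more a channel.

# Face-level alpha test.  For each tetrahedron face, the orthocircle of its
# three weighted vertices (the circle in the face plane with equal power
# distance to the three inflated balls) has squared radius <= 0 exactly when
# the balls seal the face; such faces belong to the alpha complex and block
# passage between the two incident tetrahedra even when both are complement.
face_blocked <- function(T, tol = 1e-9) {
  m <- nrow(T$tets)
  P <- T$points
  W <- T$weights
  out <- matrix(TRUE, m, 4L)
  for (i in 1:4) {
    idx <- setdiff(1:4, i)
    A <- P[T$tets[, idx[1L]], , drop = FALSE]
    B <- P[T$tets[, idx[2L]], , drop = FALSE]
    C <- P[T$tets[, idx[3L]], , drop = FALSE]
    wa <- W[T$tets[, idx[1L]]]
    wb <- W[T$tets[, idx[2L]]]
    wc <- W[T$tets[, idx[3L]]]
    m1 <- 2 * (B - A)
    m2 <- 2 * (C - A)
    m3 <- cbind(m1[, 2L] * m2[, 3L] - m1[, 3L] * m2[, 2L],
                m1[, 3L] * m2[, 1L] - m1[, 1L] * m2[, 3L],
                m1[, 1L] * m2[, 2L] - m1[, 2L] * m2[, 1L]) / 2
    r1 <- (rowSums(B^2) - wb) - (rowSums(A^2) - wa)
    r2 <- (rowSums(C^2) - wc) - (rowSums(A^2) - wa)
    r3 <- rowSums(m3 * A)
    cx <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    c23 <- cx(m2, m3)
    c31 <- cx(m3, m1)
    c12 <- cx(m1, m2)
    det <- rowSums(m1 * c23)
    z <- (r1 * c23 + r2 * c31 + r3 * c12) / det
    sqr <- rowSums((z - A)^2) - wa
    out[, i] <- !is.finite(sqr) | sqr <= tol
  }
  out
}

# Signed side of each tet's orthocenter relative to each of its 4 faces:
# flows_out[t, i] is TRUE when the orthocenter of t lies strictly on the
# opposite side of face i from the tet's own i-th vertex.
flow_out_faces <- function(T) {
  m <- nrow(T$tets)
  out <- matrix(FALSE, m, 4L)
  P <- T$points
  oc <- T$orthocenter
  for (i in 1:4) {
    idx <- setdiff(1:4, i)
    a <- P[T$tets[, idx[1L]], , drop = FALSE]
    b <- P[T$tets[, idx[2L]], , drop = FALSE]
    c <- P[T$tets[, idx[3L]], , drop = FALSE]
    opp <- P[T$tets[, i], , drop = FALSE]
    s_opp <- tet_signed_volume(a, b, c, opp)
    s_oc <- tet_signed_volume(a, b, c, oc)
    out[, i] <- s_opp * s_oc < 0
  }
  out
}

#' Discrete-flow relation over complement tetrahedra
#'
#' Returns the directed flow arcs between face-adjacent non-interior
#' tetrahedra, plus the virtual arcs that couple the triangulation to the
#' point at infinity: every hull-incident complement tetrahedron receives an
#' in-arc from infinity (id 0), and emits an out-arc to infinity when its
#' orthocenter lies beyond its hull face.
#'
#' @param T a `tetrahedralization` from [weighted_delaunay()].
#' @return data.frame with columns `from` and `to` (tetrahedron ids; 0 is
#'   the point at infinity).
#' @export
flow_relation <- function(T) {
  stopifnot(inherits(T, "tetrahedralization"))
  fo <- flow_out_faces(T)
  open <- !face_blocked(T)
  noninterior <- !T$interior
  from <- integer(0)
  to <- integer(0)
  for (i in 1:4) {
    nb <- T$neighbors[, i]
    # tet -> tet arcs between complement tetrahedra across open faces
    sel <- which(noninterior & fo[, i] & open[, i] & nb > 0L)
    sel <- sel[noninterior[nb[sel]]]
    from <- c(from, sel)
    to <- c(to, nb[sel])
    # arcs to infinity: orthocenter beyond an own open hull face
    sel_inf <- which(noninterior & fo[, i] & open[, i] & nb == 0L)
    from <- c(from, sel_inf)
    to <- c(to, rep(0L, length(sel_inf)))
    # virtual in-arcs from infinity through every open hull face
    sel_in <- which(noninterior & open[, i] & nb == 0L)
    from <- c(from, rep(0L, length(sel_in)))
    to <- c(to, sel_in)
  }
  unique(data.frame(from = from, to = to))
}

# cluster a set of faces (rows of vertex triples) by shared-edge adjacency
mouth_clusters <- function(faces) {
  nf <- nrow(faces)
  if (nf == 0L) return(integer(0))
  edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  keys <- cbind(edge_key(faces[, 1L], faces[, 2L]),
                edge_key(faces[, 1L], faces[, 3L]),
                edge_key(faces[, 2L], faces[, 3L]))
  parent <- seq_len(nf)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      key <- keys[f, k]
      other <- seen[[key]]
      if (is.null(other)) {
        assign(key, f, envir = seen)
      } else {
        ra <- find(f)
        rb <- find(other)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1L))
  match(roots, unique(roots))
}

#' Segment complement tetrahedra into cavity components
#'
#' The complement tetrahedra carrying a convex-hull face form the bulk
#' solvent boundary layer (they are the tetrahedra the point at infinity
#' flows into).  The remaining complement tetrahedra are grouped by face
#' adjacency into cavity components and classified by mouth count: `void`
#' (0), `pocket` (1) or `channel` (>= 2), where mouths are edge-connected
#' clusters of the component's faces opening into the bulk layer.  Each
#' component also records whether the discrete flow descending from
#' infinity reaches it (`flow_connected`); enclosed voids never are.
#'
#' @param T a `tetrahedralization`.
#' @return list of `cavity_component` objects sorted by decreasing volume;
#'   each has `tet_ids`, `volume` (A^3), `mouth_count`, `mouth_faces`,
#'   `flow_connected` and `cls`; bulk tet ids are attached to the list as
#'   attribute `bulk`.
#' @export
find_cavities <- function(T) {
  stopifnot(inherits(T, "tetrahedralization"))
  m <- nrow(T$tets)
  noninterior <- which(!T$interior)
  if (length(noninterior) == 0L) {
    out <- list()
    attr(out, "bulk") <- integer(0)
    return(out)
  }
  fo <- flow_out_faces(T)
  open <- !face_blocked(T)

  # bulk layer: complement tets with an open convex-hull face (the
  # tetrahedra the point at infinity flows into)
  is_complement <- !T$interior
  open_hull <- T$neighbors == 0L & open
  bulk <- noninterior[rowSums(open_hull[noninterior, , drop = FALSE]) > 0L]
  in_bulk <- logical(m)
  in_bulk[bulk] <- TRUE

  # discrete flow descending from infinity: enters every bulk tet, then
  # follows obtuse arcs A -> B (A's orthocenter beyond the shared open face)
  reached <- logical(m)
  reached[bulk] <- TRUE
  queue <- bulk
  while (length(queue)) {
    nxt <- integer(0)
    for (i in 1:4) {
      src <- queue[fo[queue, i] & open[queue, i]]
      dst <- T$neighbors[src, i]
      dst <- dst[dst > 0L]
      dst <- dst[is_complement[dst] & !reached[dst]]
      nxt <- c(nxt, dst)
    }
    nxt <- unique(nxt)
    reached[nxt] <- TRUE
    queue <- nxt
  }

  cavity <- setdiff(noninterior, bulk)
  if (length(cavity) == 0L) {
    out <- list()
    attr(out, "bulk") <- bulk
    return(out)
  }

  # components of cavity tets connected through open faces
  in_cavity <- logical(m)
  in_cavity[cavity] <- TRUE
  ef <- integer(0)
  et <- integer(0)
  for (i in 1:4) {
    nb <- T$neighbors[, i]
    sel <- which(in_cavity & open[, i] & nb > 0L)
    sel <- sel[in_cavity[nb[sel]] & nb[sel] > sel]
    ef <- c(ef, sel)
    et <- c(et, nb[sel])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ef), to = as.character(et)),
    directed = FALSE,
    vertices = data.frame(name = as.character(cavity)))
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(cavity)]

  comps <- lapply(seq_len(comp$no), function(ci) {
    tids <- sort(cavity[membership == ci])
    # open boundary faces into the bulk solvent layer
    mf_tet <- integer(0)
    mf_face <- integer(0)
    for (i in 1:4) {
      nb <- T$neighbors[tids, i]
      open_face <- nb > 0L & in_bulk[pmax(nb, 1L)] & open[tids, i]
      mf_tet <- c(mf_tet, tids[open_face])
      mf_face <- c(mf_face, rep(i, sum(open_face)))
    }
    faces <- if (length(mf_tet)) {
      t(vapply(seq_along(mf_tet), function(k) {
        sort(T$tets[mf_tet[k], setdiff(1:4, mf_face[k])])
      }, integer(3L)))
    } else {
      matrix(integer(0), 0L, 3L)
    }
    nmouth <- if (nrow(faces)) max(mouth_clusters(faces)) else 0L
    structure(list(tet_ids = tids,
                   volume = sum(T$volume[tids]),
                   mouth_count = nmouth,
                   mouth_faces = faces,
                   flow_connected = any(reached[tids]),
                   cls = if (nmouth == 0L) "void"
                         else if (nmouth == 1L) "pocket" else "channel"),
              class = "cavity_component")
  })
  comps <- comps[order(vapply(comps, `[[`, numeric(1L), "volume"),
                       decreasing = TRUE)]
  attr(comps, "bulk") <- bulk
  comps
}

#' @export
print.cavity_component <- function(x, ...) {
  cat(sprintf("<cavity_component> %s: %d tets, volume %.1f A^3, %d mouth(s)\n",
              x$cls, length(x$tet_ids), x$volume, x$mouth_count))
  invisible(x)
}

#' Count the mouths of a cavity component
#'
#' Mouths are the edge-connected clusters of the component's boundary faces
#' that open to the outside world; two clusters touching only at a single
#' vertex count as distinct.
#'
#' @param component a `cavity_component` from [find_cavities()].
#' @param T the `tetrahedralization` it came from (kept for interface
#'   symmetry; the faces are stored on the component).
#' @return non-negative integer mouth count.
#' @export
count_mouths <- function(component, T = NULL) {
  stopifnot(inherits(component, "cavity_component"))
  if (nrow(component$mouth_faces) == 0L) return(0L)
  max(mouth_clusters(component$mouth_faces))
}

#' Select the channel among cavity components
#'
#' Picks the largest-volume component among those with at least two mouths;
#' if none has two mouths the overall largest component is returned with a
#' warning.  Ties are broken by the smallest leading tetrahedron id.
#'
#' @param components list from [find_cavities()].
#' @param require_mouths if `FALSE`, select purely by volume.
#' @return the selected `cavity_component`.
#' @export
select_channel <- function(components, require_mouths = TRUE) {
  if (length(components) == 0L)
    stop("no cavity components: nothing resembling a channel was found")
  pick_largest <- function(lst) {
    vols <- vapply(lst, `[[`, numeric(1L), "volume")
    best <- which(vols == max(vols))
    if (length(best) > 1L) {
      lead <- vapply(lst[best], function(c) min(c$tet_ids), integer(1L))
      best <- best[which.min(lead)]
    }
    lst[[best]]
  }
  if (require_mouths) {
    chans <- Filter(function(c) c$mouth_count >= 2L, components)
    if (length(chans)) return(pick_largest(chans))
    warning("no component with >= 2 mouths; returning the largest cavity")
  }
  pick_largest(components)
}
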