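# Triangle-mesh I/O in the two plain-text formats used by surface tools.

#' Construct a surface mesh object
#'
#' @param vertices numeric matrix (n x 3).
#' @param triangles integer matrix (m x 3) of 1-based vertex ids.
#' @param normals optional per-vertex outward unit normals (n x 3); computed
#'   from area-weighted triangle normals when omitted.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(vertices) <- "double"
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (is.null(normals) && nrow(triangles) > 0L) {
    a <- vertices[triangles[, 1L], , drop = FALSE]
    u <- vertices[triangles[, 2L], , drop = FALSE] - a
    v <- vertices[triangles[, 3L], , drop = FALSE] - a
    fn <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    normals <- matrix(0, nrow(vertices), 3L)
    for (k in 1:3) {
      normals[, 1L] <- normals[, 1L] +
        tabulate2(triangles[, k], fn[, 1L], nrow(vertices))
      normals[, 2L] <- normals[, 2L] +
        tabulate2(triangles[, k], fn[, 2L], nrow(vertices))
      normals[, 3L] <- normals[, 3L] +
        tabulate2(triangles[, k], fn[, 3L], nrow(vertices))
    }
    len <- sqrt(rowSums(normals^2))
    len[len < 1e-300] <- 1
    normals <- normals / len
  }
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals),
            class = "surface_mesh")
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Read a triangle mesh from an OFF or PLY file
#'
#' Only triangular faces are accepted; the stored orientation is preserved.
#' Format is chosen from the file header, not the extension.
#'
#' @param path path to an OFF or ASCII PLY file.
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[1L])
  if (identical(first, "OFF")) {
    read_off_lines(lines)
  } else if (identical(first, "ply")) {
    read_ply_lines(lines)
  } else {
    stop("unreadable mesh header (expected OFF or ply): ", first)
  }
}

read_off_lines <- function(lines) {
  body <- lines[-1L]
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
  counts <- as.numeric(strsplit(trimws(body[1L]), "\\s+")[[1L]])
  nv <- counts[1L]
  nf <- counts[2L]
  vert_rows <- strsplit(trimws(body[1L + seq_len(nv)]), "\\s+")
  verts <- t(vapply(vert_rows, function(f) as.numeric(f[1:3]), numeric(3L)))
  face_rows <- strsplit(trimws(body[1L + nv + seq_len(nf)]), "\\s+")
  tris <- t(vapply(face_rows, function(f) {
    f <- as.numeric(f)
    if (f[1L] != 3) stop("non-triangular face in OFF file")
    f[2:4] + 1
  }, numeric(3L)))
  surface_mesh(verts, tris)
}

read_ply_lines <- function(lines) {
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("unreadable mesh header: no end_header in PLY")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face", hdr, value = TRUE)[1L]))
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vert_rows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vert_rows, function(f) as.numeric(f[1:3]), numeric(3L)))
  face_rows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tris <- t(vapply(face_rows, function(f) {
    f <- as.numeric(f)
    if (f[1L] != 3) stop("non-triangular face in PLY file")
    f[2:4] + 1
  }, numeric(3L)))
  surface_mesh(verts, tris)
}

#' Write a triangle mesh
#'
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @param format `"off"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("off", "ply")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  vt <- apply(mesh$vertices, 1L,
              function(r) paste(sprintf("%.6f", r), collapse = " "))
  ft <- apply(mesh$triangles - 1L, 1L,
              function(r) paste(c(3L, r), collapse = " "))
  if (format == "off") {
    writeLines(c("OFF", paste(nv, nf, 0L), vt, ft), path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nv),
             "property float x", "property float y", "property float z",
             paste("element face", nf),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, vt, ft), path)
  }
  invisible(path)
}
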