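#' Write per-frame channel results to a directory
#'
#' For each analyzed frame writes the channel surface as OFF
#' (`frame_{i}_channel.off`), the centerline as CSV (`frame_{i}_centerline.csv`
#' with columns x, y, z, tx, ty, tz, curvature, torsion, radius, arclength),
#' the section metrics as CSV (`frame_{i}_sections.csv`), plus one
#' `summary.csv` across frames.  Frame indices are zero-padded to six
#' digits; failed frames contribute only a summary row.
#'
#' @param results a `trajectory_result` from [analyze_trajectory()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "trajectory_result"))
  if (length(results$frames) == 0L) stop("no frame results to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  summary_rows <- list()
  for (r in results$frames) {
    tag <- sprintf("frame_%06d", r$frame - 1L)
    if (identical(r$status, "failed")) {
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(frame = r$frame - 1L, status = r$status,
                   n_points = 0L, mean_radius = NA_real_,
                   volume = NA_real_, mouths = NA_integer_)
      next
    }
    cl <- r$centerline
    cl_df <- data.frame(x = cl$points[, 1L], y = cl$points[, 2L],
                        z = cl$points[, 3L],
                        tx = cl$tangent[, 1L], ty = cl$tangent[, 2L],
                        tz = cl$tangent[, 3L],
                        curvature = cl$curvature, torsion = cl$torsion,
                        radius = if (is.null(cl$radius)) NA_real_
                                 else cl$radius,
                        arclength = cl$arclength)
    f1 <- file.path(out_dir, paste0(tag, "_centerline.csv"))
    write.csv(cl_df, f1, row.names = FALSE)
    written <- c(written, f1)
    if (!is.null(r$sections)) {
      f2 <- file.path(out_dir, paste0(tag, "_sections.csv"))
      write.csv(r$sections, f2, row.names = FALSE)
      written <- c(written, f2)
    }
    if (!is.null(r$channel_surface)) {
      cs <- r$channel_surface
      sub <- surface_mesh(cs$mesh$vertices,
                          cs$mesh$triangles[cs$triangle_ids, , drop = FALSE])
      f3 <- file.path(out_dir, paste0(tag, "_channel.off"))
      write_mesh(sub, f3, "off")
      written <- c(written, f3)
    }
    summary_rows[[length(summary_rows) + 1L]] <-
      data.frame(frame = r$frame - 1L, status = r$status,
                 n_points = nrow(cl$points),
                 mean_radius = if (is.null(cl$radius)) NA_real_
                               else mean(cl$radius),
                 volume = r$channel$volume,
                 mouths = r$channel$mouth_count)
  }
  fs <- file.path(out_dir, "summary.csv")
  write.csv(do.call(rbind, summary_rows), fs, row.names = FALSE)
  invisible(c(written, fs))
}
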