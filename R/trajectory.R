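# Trajectory orchestration: full pipeline on the first frame, warm starts
# afterwards, with reinitialization when consecutive centerlines disagree.

#' Symmetric discrepancy between two centerlines
#'
#' Symmetric mean closest-point distance between the two point sets: the
#' average of (mean distance from each point of `a` to its nearest point of
#' `b`) and the converse.
#'
#' @param a,b `centerline` objects (or plain point matrices).
#' @return discrepancy in Angstrom.
#' @export
centerline_discrepancy <- function(a, b) {
  pa <- if (inherits(a, "centerline")) a$points else as.matrix(a)
  pb <- if (inherits(b, "centerline")) b$points else as.matrix(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("empty centerline")
  (mean(nearest_point_distance(pa, pb)) +
     mean(nearest_point_distance(pb, pa))) / 2
}

#' Analyze a trajectory of structures
#'
#' The first frame runs the full pipeline including skeleton pruning.  Each
#' later frame reuses the previous frame's centerline endpoints as an
#' initial guess: they are snapped to the nearest nodes of the new frame's
#' skeleton (within `capture` A) and pruning is skipped.  If snapping fails
#' or the new centerline deviates from the previous one by more than
#' `discrepancy` A, the frame is reinitialized with a full pruning pass.
#' A frame that fails entirely (for example no channel) is recorded with
#' status `failed` and the run continues.
#'
#' @param frames list of [atom_set] objects.
#' @param probe,grid_spacing,step passed to [analyze_structure()].
#' @param capture warm-start capture radius, A (default 5).
#' @param discrepancy reinitialization threshold, A (default 5).
#' @param cold_start analyze every frame independently with full pruning.
#' @param sections,section_stride passed to [analyze_structure()].
#' @return object of class `trajectory_result`: per-frame list with
#'   `status` (`full_init`, `warm_start`, `reinitialized` or `failed`),
#'   the frame result (or failure reason), pooled `radius_samples`, and a
#'   per-status `summary` table.
#' @export
analyze_trajectory <- function(frames, probe = 1.4, grid_spacing = 0.5,
                               step = 0.5, capture = 5, discrepancy = 5,
                               cold_start = FALSE, sections = FALSE,
                               section_stride = 1L) {
  stopifnot(length(frames) >= 1L)
  results <- vector("list", length(frames))
  prev_cl <- NULL
  prev_endpoints <- NULL
  for (f in seq_along(frames)) {
    run <- function(endpoints) {
      analyze_structure(frames[[f]], probe = probe,
                        grid_spacing = grid_spacing, step = step,
                        endpoints = endpoints, capture = capture,
                        sections = sections,
                        section_stride = section_stride)
    }
    status <- NULL
    res <- NULL
    if (f == 1L || cold_start || is.null(prev_endpoints)) {
      res <- tryCatch(run(NULL), error = function(e) e)
      status <- "full_init"
    } else {
      res <- tryCatch(run(prev_endpoints), error = function(e) e)
      status <- "warm_start"
      needs_reinit <- inherits(res, "error") ||
        centerline_discrepancy(res$centerline, prev_cl) > discrepancy
      if (needs_reinit) {
        res <- tryCatch(run(NULL), error = function(e) e)
        status <- "reinitialized"
      }
    }
    if (inherits(res, "error")) {
      results[[f]] <- list(frame = f, status = "failed",
                           reason = conditionMessage(res))
      prev_cl <- NULL
      prev_endpoints <- NULL
    } else {
      results[[f]] <- list(frame = f, status = status,
                           channel = res$channel,
                           centerline = res$centerline,
                           sections = res$sections,
                           radius_samples = cbind(res$radius_samples,
                                                  frame = f),
                           channel_surface = res$channel_surface,
                           endpoints = res$endpoints)
      prev_cl <- res$centerline
      prev_endpoints <- res$endpoints
    }
  }
  samples <- do.call(rbind, lapply(results, function(r) r$radius_samples))
  statuses <- vapply(results, `[[`, character(1L), "status")
  structure(list(frames = results,
                 radius_samples = samples,
                 summary = as.data.frame(table(status = statuses),
                                         stringsAsFactors = FALSE)),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %d frames: %s\n", length(x$frames),
              paste(sprintf("%s=%d", x$summary$status, x$summary$Freq),
                    collapse = ", ")))
  invisible(x)
}

#' Compare ion positions with per-frame centerlines
#'
#' For each recorded ion position, computes its distance to the centerline
#' of the same frame, then re-bins along the z axis: per bin the mean
#' lateral displacement from the centerline, the mean ion position and the
#' sample count.
#'
#' @param centerlines list of `centerline` objects indexed by frame.
#' @param ions data.frame with columns `frame`, `x`, `y`, `z`.
#' @param bin_width z bin width, A (default 1).
#' @return data.frame with `z`, `mean_displacement`, `mean_x`, `mean_y`,
#'   `mean_z`, `n`; empty when no ion falls in a frame with a centerline.
#' @export
compare_ion_paths <- function(centerlines, ions, bin_width = 1) {
  empty <- data.frame(z = numeric(0), mean_displacement = numeric(0),
                      mean_x = numeric(0), mean_y = numeric(0),
                      mean_z = numeric(0), n = integer(0))
  if (is.null(ions) || nrow(ions) == 0L) return(empty)
  keep <- ions$frame >= 1L & ions$frame <= length(centerlines) &
    !vapply(centerlines[pmax(ions$frame, 1L)], is.null, logical(1L))
  ions <- ions[keep, , drop = FALSE]
  if (nrow(ions) == 0L) return(empty)
  disp <- vapply(seq_len(nrow(ions)), function(i) {
    cl <- centerlines[[ions$frame[i]]]
    min(nearest_point_distance(matrix(unlist(ions[i, c("x", "y", "z")]),
                                      1L, 3L), cl$points))
  }, numeric(1L))
  z0 <- min(ions$z)
  bin <- floor((ions$z - z0) / bin_width)
  agg <- function(v) vapply(split(v, bin), mean, numeric(1L))
  out <- data.frame(z = z0 + (as.integer(names(agg(disp))) + 0.5) * bin_width,
                    mean_displacement = agg(disp),
                    mean_x = agg(ions$x), mean_y = agg(ions$y),
                    mean_z = agg(ions$z),
                    n = lengths(split(disp, bin)))
  rownames(out) <- NULL
  out[order(out$z), , drop = FALSE]
}
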