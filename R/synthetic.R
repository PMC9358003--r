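# Synthetic toy "molecules" with analytically known channel geometry.
#
# Walls are built from overlapping balls (center spacing a fixed fraction of
# the ball radius, 1.4 by default, within the <= 1.5 bound that keeps the
# probe-inflated wall watertight), so each fixture's cavity class, mouth
# count, axis and lumen radius are known by construction.

ring_points <- function(center, radius, normal, n, phase = 0) {
  b <- plane_basis(normal / vnorm(normal))
  ang <- phase + 2 * pi * (seq_len(n) - 1L) / n
  sweep(outer(cos(ang), radius * b$u) + outer(sin(ang), radius * b$v),
        2L, center, `+`)
}

#' Generate a synthetic fixture with known channel geometry
#'
#' Available kinds:
#' * `cylinder_pore`: open tube along z; a channel with two mouths and lumen
#'   radius `axis_radius - ball_radius`.
#' * `torus_channel`: a donut of balls; the through-hole is a channel with
#'   two mouths.
#' * `pocket`: an open bowl (hemispherical shell); one mouth.
#' * `sealed_void`: a closed spherical shell; an internal void, no mouth.
#' * `helical_tube`: a tube whose axis is the circular helix
#'   `(a cos t, a sin t, b t)` with curvature `a / (a^2 + b^2)` and torsion
#'   `b / (a^2 + b^2)`; its ground truth is the axis geometry (the
#'   mouth-based class is undefined because the tube openings do not face
#'   the convex hull).
#' * `pentalobe_tube`: a tube whose wall radius is modulated as
#'   `R(theta) = axis_radius + lobe_amplitude * cos(n_lobes * theta)`,
#'   emulating a five-fold symmetric pore.
#'
#' @param kind fixture kind (see above).
#' @param axis_radius wall-center distance from the axis (tube fixtures), A.
#' @param ball_radius wall ball radius, A.
#' @param length tube length along the axis, A.
#' @param ring_radius center-circle radius of the torus, A.
#' @param torus_minor tube (minor) radius of the torus surface, A.
#' @param shell_radius sphere radius of the bowl/shell fixtures, A.
#' @param helix_radius,helix_pitch helix parameters `a` and `b`, A.
#' @param tube_radius axis distance of the helical tube wall, A.
#' @param turns helix turns (default 0.75; below one full turn the tube
#'   cannot stack onto itself, so the lumen stays open end to end).
#' @param lobe_amplitude,n_lobes wall modulation of the pentalobe tube.
#' @param spacing_factor wall-ball center spacing as a multiple of
#'   `ball_radius` (must stay <= 1.5 for a watertight wall).
#' @param probe probe radius used only to validate that the lumen stays open.
#' @return list with `atoms` (an [atom_set]) and `truth` (expected class,
#'   mouth count, axis polyline, lumen radius, and closed-form curvature and
#'   torsion for the helical axis).
#' @export
make_fixture <- function(kind = c("cylinder_pore", "torus_channel", "pocket",
                                  "sealed_void", "helical_tube",
                                  "pentalobe_tube"),
                         axis_radius = 6, ball_radius = 1.5, length = 30,
                         ring_radius = 8, torus_minor = 2.5, shell_radius = 6,
                         helix_radius = 5, helix_pitch = 2, tube_radius = 4,
                         turns = 0.75, lobe_amplitude = 1.5, n_lobes = 5L,
                         spacing_factor = 1.4, probe = 1.4) {
  kind <- match.arg(kind)
  if (spacing_factor <= 0 || spacing_factor > 1.5)
    stop("spacing_factor must be in (0, 1.5] for a watertight wall")
  stopifnot(ball_radius > 0)
  spacing <- spacing_factor * ball_radius
  # five lobes need throats wider than two probe diameters to stay open at
  # the alpha level; the default pentalobe tube is therefore wider
  if (kind == "pentalobe_tube" && missing(axis_radius)) axis_radius <- 9

  if (kind == "cylinder_pore" || kind == "pentalobe_tube") {
    base_r <- if (kind == "pentalobe_tube") axis_radius - lobe_amplitude
              else axis_radius
    if (base_r <= ball_radius + probe)
      stop("lumen sealed: axis_radius must exceed ball_radius + probe")
    nz <- max(2L, ceiling(length / spacing) + 1L)
    zs <- seq(0, length, length.out = nz)
    pts <- NULL
    for (iz in seq_along(zs)) {
      if (kind == "cylinder_pore") {
        nr <- max(6L, ceiling(2 * pi * axis_radius / spacing))
        phase <- if (iz %% 2L == 0L) pi / nr else 0
        pts <- rbind(pts, ring_points(c(0, 0, zs[iz]), axis_radius,
                                      c(0, 0, 1), nr, phase))
      } else {
        nr <- max(12L, ceiling(2 * pi * (axis_radius + lobe_amplitude) /
                                 spacing))
        phase <- if (iz %% 2L == 0L) pi / nr else 0
        ang <- phase + 2 * pi * (seq_len(nr) - 1L) / nr
        rr <- axis_radius + lobe_amplitude * cos(n_lobes * ang)
        pts <- rbind(pts, cbind(rr * cos(ang), rr * sin(ang), zs[iz]))
      }
    }
    atoms <- atom_set(pts, rep(ball_radius, nrow(pts)))
    truth <- list(kind = kind, class = "channel", mouths = 2L,
                  axis = rbind(c(0, 0, 0), c(0, 0, length)),
                  lumen_radius = base_r - ball_radius,
                  n_lobes = if (kind == "pentalobe_tube") n_lobes else NULL)
    return(list(atoms = atoms, truth = truth))
  }

  if (kind == "torus_channel") {
    minor <- torus_minor
    hole <- ring_radius - minor - ball_radius
    if (hole <= ball_radius + probe)
      stop("hole sealed: ring_radius too small for the tube and ball radii")
    # torus surface shell: horizontal rings of balls stacked around the tube
    nv <- max(6L, ceiling(2 * pi * minor / spacing))
    pts <- NULL
    for (iv in seq_len(nv)) {
      v <- 2 * pi * (iv - 1L) / nv
      rim <- ring_radius + minor * cos(v)
      z <- minor * sin(v)
      nr <- max(8L, ceiling(2 * pi * rim / spacing))
      phase <- if (iv %% 2L == 0L) pi / nr else 0
      pts <- rbind(pts, ring_points(c(0, 0, z), rim, c(0, 0, 1), nr, phase))
    }
    atoms <- atom_set(pts, rep(ball_radius, nrow(pts)))
    return(list(atoms = atoms,
                truth = list(kind = kind, class = "channel", mouths = 2L,
                             axis = rbind(c(0, 0, -minor), c(0, 0, minor)),
                             lumen_radius = hole)))
  }

  if (kind == "pocket" || kind == "sealed_void") {
    if (shell_radius <= ball_radius + probe)
      stop("shell too tight: no open interior")
    theta_lo <- if (kind == "pocket") pi / 2 else 0
    nth <- max(3L, ceiling((pi - theta_lo) * shell_radius / spacing) + 1L)
    thetas <- seq(theta_lo, pi, length.out = nth)
    pts <- NULL
    for (th in thetas) {
      rim <- shell_radius * sin(th)
      z <- shell_radius * cos(th)
      if (rim < spacing / 2) {
        pts <- rbind(pts, c(0, 0, z))
      } else {
        nr <- max(6L, ceiling(2 * pi * rim / spacing))
        pts <- rbind(pts, ring_points(c(0, 0, z), rim, c(0, 0, 1), nr))
      }
    }
    atoms <- atom_set(pts, rep(ball_radius, nrow(pts)))
    return(list(atoms = atoms,
                truth = list(kind = kind,
                             class = if (kind == "pocket") "pocket" else "void",
                             mouths = if (kind == "pocket") 1L else 0L,
                             axis = NULL,
                             lumen_radius = shell_radius - ball_radius)))
  }

  # helical_tube
  if (tube_radius <= ball_radius + probe)
    stop("lumen sealed: tube_radius must exceed ball_radius + probe")
  a <- helix_radius
  b <- helix_pitch
  speed <- sqrt(a^2 + b^2)
  t_max <- 2 * pi * turns
  # ring spacing must stay tight on the outer side of the bend, where the
  # curvature stretches consecutive rings apart by 1 + kappa * wall reach
  kappa <- a / (a^2 + b^2)
  stretch <- 1 + kappa * (tube_radius + ball_radius)
  nt <- max(3L, ceiling(t_max * speed * stretch / spacing) + 1L)
  ts <- seq(0, t_max, length.out = nt)
  pts <- NULL
  for (i in seq_along(ts)) {
    t <- ts[i]
    c0 <- c(a * cos(t), a * sin(t), b * t)
    tang <- c(-a * sin(t), a * cos(t), b) / speed
    nr <- max(6L, ceiling(2 * pi * tube_radius / spacing))
    phase <- if (i %% 2L == 0L) pi / nr else 0
    pts <- rbind(pts, ring_points(c0, tube_radius, tang, nr, phase))
  }
  axis_t <- seq(0, t_max, length.out = 200L)
  axis <- cbind(a * cos(axis_t), a * sin(axis_t), b * axis_t)
  atoms <- atom_set(pts, rep(ball_radius, nrow(pts)))
  # a partial-turn tube's openings face the concave region between the coil
  # and the hull, not the hull itself, so the mouth-based cavity class is
  # not well defined for this fixture; its ground truth is the axis geometry
  list(atoms = atoms,
       truth = list(kind = kind, class = NA_character_, mouths = NA_integer_,
                    axis = axis,
                    lumen_radius = tube_radius - ball_radius,
                    curvature = a / (a^2 + b^2),
                    torsion = b / (a^2 + b^2)))
}

#' Generate a jittered synthetic trajectory
#'
#' Frame 1 is the clean fixture; every later frame adds i.i.d. uniform
#' jitter in `[-jitter, jitter]` to each coordinate.  Deterministic given
#' the seed; the global RNG state is left untouched.
#'
#' @param fixture output of [make_fixture()].
#' @param n_frames number of frames (>= 1).
#' @param jitter per-coordinate displacement bound, A.
#' @param seed RNG seed.
#' @return list of [atom_set] frames, with the fixture `truth` attached as
#'   an attribute.
#' @export
make_trajectory <- function(fixture, n_frames, jitter = 0.1, seed = 1L) {
  stopifnot(n_frames >= 1L, jitter >= 0)
  atoms <- fixture$atoms
  n <- nrow(atoms$centers)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  frames <- vector("list", n_frames)
  frames[[1L]] <- atoms
  for (f in seq_len(n_frames)[-1L]) {
    disp <- matrix(runif(3L * n, -jitter, jitter), n, 3L)
    frames[[f]] <- atom_set(atoms$centers + disp, atoms$radii, atoms$labels)
  }
  attr(frames, "truth") <- fixture$truth
  frames
}
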