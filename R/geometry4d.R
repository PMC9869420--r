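#' Map an in-plane contour to world coordinates
#'
#' Rigidly embeds a 2D contour from a frame's image plane into 3D using the
#' probe-tracker pose of that frame: `p_world = R (x, y, 0)' + T`.
#'
#' @param contour n x 2 matrix of in-plane points, mm.
#' @param pose A list with `translation` (length-3, mm) and `quaternion`
#'   (length-4, `(w, x, y, z)`, unit norm).
#' @return n x 3 matrix of world points, mm.
#' @export
contour_to_world <- function(contour, pose) {
  q <- pose$quaternion
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6) stop("pose quaternion must have unit norm")
  R <- quat_to_rotmat(q)
  p <- cbind(as.matrix(contour), 0)
  sweep(p %*% t(R), 2, pose$translation, "+")
}

#' Build the 3D centerline from end-diastolic contour centres
#'
#' Cubic-spline interpolation through the ED centres parameterised by
#' cumulative chord length, densely resampled (default 0.5 mm), followed by a
#' component-wise moving-average filter with a 15-sample kernel (shrinking
#' window at the ends) to smooth the line.
#'
#' @param ed_centers_world m x 3 matrix of ED ellipse centres in world
#'   coordinates (m >= 4).
#' @param resample_mm Dense resampling step before smoothing, mm. The
#'   moving-average kernel is specified in samples, so this step sets the
#'   effective smoothing length (recorded in the output attributes).
#' @param ma_window Moving-average kernel size, samples.
#' @return A list of class `"centerline3d"` with `points` (n x 3) and
#'   `arclength` (cumulative, mm).
#' @export
build_centerline <- function(ed_centers_world, resample_mm = 0.5,
                             ma_window = 15) {
  p <- as.matrix(ed_centers_world)
  if (nrow(p) < 4) stop("too few cardiac cycles captured: need >= 4 ED centres")
  chord <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (any(diff(chord) <= 0)) stop("coincident consecutive ED centres")
  ss <- seq(0, chord[length(chord)], by = resample_mm)
  if (ss[length(ss)] < chord[length(chord)])
    ss <- c(ss, chord[length(chord)])
  dense <- sapply(1:3, function(j)
    stats::spline(chord, p[, j], xout = ss, method = "natural")$y)
  sm <- apply(dense, 2, moving_average, window = ma_window)
  arc <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  structure(list(points = sm, arclength = arc,
                 resample_mm = resample_mm, ma_window = ma_window),
            class = "centerline3d")
}

# centred moving average with shrinking window at the edges
moving_average <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Intersect the centerline with every frame's image plane
#'
#' Each frame's origin for the polar conversion is the point where the
#' piecewise-linear centerline crosses that frame's plane. With multiple
#' crossings the one nearest the previous frame's origin is kept (first
#' frame: nearest to the supplied reference point). Frames whose plane the
#' centerline never crosses fall back to the orthogonal projection of the
#' nearest centerline point onto the plane and are flagged.
#'
#' @param centerline A [build_centerline()] result.
#' @param poses List of per-frame poses (`translation`, `quaternion`).
#' @param first_reference World point anchoring the first frame's choice
#'   (typically its segmented ellipse centre); default the first centerline
#'   point.
#' @return A data.frame with world origin (`x`, `y`, `z`), in-plane origin
#'   (`u`, `v`), arclength `s` along the centerline, and logical `fallback`.
#' @export
frame_origins <- function(centerline, poses, first_reference = NULL) {
  cl <- centerline$points
  arc <- centerline$arclength
  if (is.null(first_reference)) first_reference <- cl[1, ]
  prev <- first_reference
  out <- matrix(NA_real_, length(poses), 6)
  fallback <- logical(length(poses))
  for (k in seq_along(poses)) {
    pose <- poses[[k]]
    R <- quat_to_rotmat(pose$quaternion)
    nrm <- R[, 3]
    d <- as.vector((cl %*% nrm) - sum(nrm * pose$translation))
    cross <- which(d[-length(d)] * d[-1] <= 0 & (d[-length(d)] != 0 | d[-1] != 0))
    if (length(cross) > 0) {
      cands <- t(vapply(cross, function(i) {
        f <- d[i] / (d[i] - d[i + 1])
        c(cl[i, ] + f * (cl[i + 1, ] - cl[i, ]),
          arc[i] + f * (arc[i + 1] - arc[i]))
      }, numeric(4)))
      pick <- which.min(rowSums(sweep(cands[, 1:3, drop = FALSE], 2, prev)^2))
      pt <- cands[pick, 1:3]; s_here <- cands[pick, 4]
    } else {
      ni <- which.min(abs(d))
      pt <- cl[ni, ] - d[ni] * nrm       # orthogonal projection onto the plane
      s_here <- arc[ni]
      fallback[k] <- TRUE
    }
    uv <- as.vector(t(R) %*% (pt - pose$translation))[1:2]
    out[k, ] <- c(pt, uv, s_here)
    prev <- pt
  }
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
             u = out[, 4], v = out[, 5], s = out[, 6], fallback = fallback)
}

#' Resample a planar contour to equidistant polar angles
#'
#' Converts a closed contour to polar coordinates about a given origin and
#' returns the radius at equidistant angles, intersecting each ray with the
#' contour polygon (linear interpolation between vertices). Angle zero is the
#' in-plane +x axis, counterclockwise.
#'
#' @param contour n x 2 matrix of in-plane contour points (closed implicitly).
#' @param origin Length-2 origin, strictly inside the contour.
#' @param n_angles Number of equidistant angles.
#' @return Numeric vector of radii (mm), one per angle
#'   `theta_i = 2*pi*(i-1)/n_angles`.
#' @export
polar_resample <- function(contour, origin, n_angles = 72) {
  p <- as.matrix(contour)
  px <- p[, 1] - origin[1]; py <- p[, 2] - origin[2]
  if (!point_in_polygon(0, 0, px, py)) stop("origin outside lumen")
  th <- atan2(py, px)
  r <- sqrt(px^2 + py^2)
  if (any(r < 1e-12)) stop("origin outside lumen")  # on the contour
  ord <- order(th)
  th <- th[ord]; r <- r[ord]
  # wrap for interpolation across the branch cut
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  r_ext <- rep(r, 3)
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  theta_q <- ifelse(theta > pi, theta - 2 * pi, theta)
  # linear interpolation in (theta, r) == ray/segment intersection for
  # densely sampled contours; exact at the vertices
  ray_polygon_radius(theta_q, th_ext, r_ext)
}

# radius along each query angle by intersecting the ray with the polygon
# whose vertices are given in sorted (angle, radius) form
ray_polygon_radius <- function(theta_q, th, r) {
  vapply(theta_q, function(a) {
    i <- findInterval(a, th)
    if (i < 1 || i >= length(th)) return(NA_real_)
    th1 <- th[i]; th2 <- th[i + 1]
    r1 <- r[i]; r2 <- r[i + 1]
    if (th2 - th1 < 1e-12) return(r1)
    # intersect ray at angle a with the chord (th1,r1)-(th2,r2)
    p1 <- c(r1 * cos(th1), r1 * sin(th1))
    p2 <- c(r2 * cos(th2), r2 * sin(th2))
    dirv <- c(cos(a), sin(a))
    dd <- p2 - p1
    den <- dirv[1] * (-dd[2]) - dirv[2] * (-dd[1])
    if (abs(den) < 1e-14) return((r1 + r2) / 2)
    tpar <- (p1[1] * (-dd[2]) - p1[2] * (-dd[1])) / den
    max(tpar, 1e-12)
  }, numeric(1))
}

point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  cross <- (py > y) != (py[j] > y)
  xi <- px[j] + (y - py[j]) / (py - py[j]) * (px - px[j])
  sum(cross & x < xi, na.rm = TRUE) %% 2 == 1
}

#' Assemble the (theta, r, t) polar grid for a sweep
#'
#' @param contours Per-frame segmented [ellipse()] objects (or n x 2 contour
#'   matrices in image coordinates).
#' @param origins [frame_origins()] result (`u`, `v` in-plane origins).
#' @param timestamps Frame timestamps, s.
#' @param n_angles Equidistant angle count (default 72, i.e. 5 degrees).
#' @return A list of class `"polar_grid"`: `radii` (n_angles x n_frames
#'   matrix, mm), `theta`, `t`, `origins`.
#' @export
build_polar_grid <- function(contours, origins, timestamps, n_angles = 72) {
  nf <- length(contours)
  rad <- matrix(NA_real_, n_angles, nf)
  for (k in seq_len(nf)) {
    cc <- contours[[k]]
    pts <- if (inherits(cc, "us_ellipse"))
      ellipse_points(cc, seq(0, 2 * pi, length.out = 181)[-181]) else as.matrix(cc)
    rad[, k] <- polar_resample(pts, c(origins$u[k], origins$v[k]), n_angles)
  }
  structure(list(radii = rad,
                 theta = seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)],
                 t = timestamps, origins = origins),
            class = "polar_grid")
}

#' Per-angle envelope detection on the radius--time grid
#'
#' For each angle, local maxima of `r(t)` separated by at least the minimal
#' cardiac period anchor the end-systolic envelope; the signal is negated and
#' the same detection yields the end-diastolic envelope. Between anchors the
#' envelope is interpolated with a shape-preserving monotone cubic; before
#' the first and after the last anchor it is extended with the nearest anchor
#' value. Angles with fewer than two anchors fall back to the global min/max
#' of their signal and are flagged.
#'
#' @param grid A [build_polar_grid()] result.
#' @param hf A [detect_heart_frequency()] result.
#' @return A list with `r_ed`, `r_es` (matrices matching `grid$radii`) and
#'   logical `degenerate` per angle.
#' @export
envelope_radii <- function(grid, hf) {
  t <- grid$t
  if ((t[length(t)] - t[1]) < 2 / hf$f_high)
    stop("sweep too short: grid spans fewer than two cardiac periods")
  dt <- stats::median(diff(t))
  min_sep <- (1 / hf$f_high) / dt
  na <- nrow(grid$radii)
  r_es <- r_ed <- matrix(NA_real_, na, ncol(grid$radii))
  degenerate <- logical(na)
  for (i in seq_len(na)) {
    x <- grid$radii[i, ]
    up <- envelope_1d(x, t, min_sep)
    dn <- envelope_1d(-x, t, min_sep)
    if (is.null(up) || is.null(dn)) {
      degenerate[i] <- TRUE
      r_es[i, ] <- max(x)
      r_ed[i, ] <- min(x)
    } else {
      r_es[i, ] <- up
      r_ed[i, ] <- -dn
    }
  }
  list(r_ed = r_ed, r_es = r_es, degenerate = degenerate)
}

# upper envelope of x(t) through its constrained local maxima; NULL if < 2
envelope_1d <- function(x, t, min_sep) {
  idx <- local_minima(-x, min_sep)  # maxima of x
  if (length(idx) < 2) return(NULL)
  ta <- t[idx]; xa <- x[idx]
  f <- stats::splinefun(ta, xa, method = "monoH.FC")
  out <- f(pmin(pmax(t, ta[1]), ta[length(ta)]))
  out
}

#' Mean-arterial-pressure radius from the ED and ES radii
#'
#' `r_map = r_ed + 0.5 * (r_es - r_ed)`: the radius midway between the
#' end-diastolic and end-systolic envelopes.
#'
#' @param r_ed,r_es Radii, mm (vectorised); `r_es >= r_ed > 0`.
#' @return The MAP-state radii, mm.
#' @export
map_radius <- function(r_ed, r_es) {
  if (any(r_ed <= 0)) stop("radii must be positive")
  if (any(r_es < r_ed)) stop("envelope inversion: r_es < r_ed")
  r_ed + 0.5 * (r_es - r_ed)
}

#' Refit phase contours and map them to 3D
#'
#' Per-angle envelope interpolation can leave local irregularities, so for
#' every frame and phase the `(theta, r_phase)` samples are converted to
#' in-plane Cartesian points about the frame origin, an ellipse is refit, the
#' ellipse is sampled at the grid angles, and the contour is mapped to world
#' coordinates through the frame's pose.
#'
#' @param envelopes [envelope_radii()] result.
#' @param grid The [build_polar_grid()] used for the envelopes.
#' @param poses Per-frame poses.
#' @return A named list of three `"phase_geometry"` objects (`ED`, `ES`,
#'   `MAP`), each with `phase`, `contours` (list of n_angles x 3 world-point
#'   matrices), `ellipses`, `origins`, `frames` (indices kept) and `t`.
#' @export
refit_phase_contours <- function(envelopes, grid, poses) {
  r_map <- map_radius(envelopes$r_ed, envelopes$r_es)
  phases <- list(ED = envelopes$r_ed, ES = envelopes$r_es, MAP = r_map)
  theta <- grid$theta
  lapply(names(phases), function(ph) {
    rmat <- phases[[ph]]
    contours <- list(); ellipses <- list(); kept <- integer(0)
    for (k in seq_len(ncol(rmat))) {
      u0 <- grid$origins$u[k]; v0 <- grid$origins$v[k]
      pts <- cbind(u0 + rmat[, k] * cos(theta), v0 + rmat[, k] * sin(theta))
      e <- tryCatch(fit_ellipse(pts), error = function(err) NULL)
      if (is.null(e)) {
        warning(sprintf("%s phase: ellipse refit failed on frame %d; skipped", ph, k))
        next
      }
      smp <- ellipse_points(e, theta)
      contours[[length(contours) + 1L]] <- contour_to_world(smp, poses[[k]])
      ellipses[[length(ellipses) + 1L]] <- e
      kept <- c(kept, k)
    }
    structure(list(phase = ph, contours = contours, ellipses = ellipses,
                   origins = grid$origins[kept, , drop = FALSE],
                   frames = kept, t = grid$t[kept], theta = theta),
              class = "phase_geometry")
  }) |> stats::setNames(names(phases))
}

#' @export
print.phase_geometry <- function(x, ...) {
  cat(sprintf("phase geometry %s: %d contours x %d angles\n",
              x$phase, length(x$contours), length(x$theta)))
  invisible(x)
}
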