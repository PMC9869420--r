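#' Specification of a synthetic pulsating-vessel phantom
#'
#' Describes a straight or curved vessel with an axially varying base radius
#' `r0(s)`, a fractional pulsation amplitude `eps(s)` between end diastole and
#' end systole, and a probe that sweeps along the vessel at constant speed
#' while frames are sampled at a fixed rate. The frame radius is
#' `r(s, t) = r0(s) * (1 + eps(s) * w(t))` with `w(t)` in `[0, 1]`, `w = 0`
#' at end diastole and `w = 1` at end systole.
#'
#' @param centerline_control_points Matrix of 3D points (mm) the vessel axis
#'   passes through; default a straight segment along +z.
#' @param base_radius Either a single radius (mm) or a function `r0(s)` of
#'   arclength s (mm).
#' @param distension Either a single fractional amplitude or a function
#'   `eps(s)`; `eps >= 0`.
#' @param heart_rate Beats per minute, within 40--120.
#' @param waveform `"sinusoid"` (raised cosine, unambiguous ED/ES extrema) or
#'   `"skewed-systolic"` (faster upstroke, slower decay).
#' @param probe_speed Probe translation speed along the sweep axis, mm/s.
#' @param sweep_duration Acquisition length, s.
#' @param sample_rate Frame rate, Hz (acquisition systems of this kind store
#'   at 25 Hz).
#' @param pixel_spacing mm/pixel (isotropic).
#' @param image_size Image side length, pixels (square frames).
#' @param speckle_sd Multiplicative speckle-like noise SD (0 = noiseless).
#' @param jitter_pos_sd Tracker positional jitter SD, mm.
#' @param jitter_rot_sd Tracker angular jitter SD, degrees.
#' @param wall_thickness Rendered bright wall band thickness, mm.
#' @param lateral_attenuation Contrast scale (0--1) applied to the wall band in
#'   the lateral sectors (around +/- x); 1 = no attenuation.
#' @param ed_pressure,es_pressure Aortic pressures at ED and ES, kPa.
#' @param seed Integer seed controlling all phantom randomness.
#' @return A validated list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(centerline_control_points = NULL,
                         base_radius = 10,
                         distension = 0.1,
                         heart_rate = 60,
                         waveform = c("sinusoid", "skewed-systolic"),
                         probe_speed = 3,
                         sweep_duration = 10,
                         sample_rate = 25,
                         pixel_spacing = 0.5,
                         image_size = 96,
                         speckle_sd = 0,
                         jitter_pos_sd = 0,
                         jitter_rot_sd = 0,
                         wall_thickness = 2,
                         lateral_attenuation = 1,
                         ed_pressure = 10.6,
                         es_pressure = 16.0,
                         seed = 1L) {
  waveform <- match.arg(waveform)
  r0 <- if (is.function(base_radius)) base_radius else function(s) rep(base_radius, length(s))
  epsf <- if (is.function(distension)) distension else function(s) rep(distension, length(s))
  length_mm <- probe_speed * sweep_duration
  s_chk <- seq(0, length_mm, length.out = 101)
  if (any(r0(s_chk) <= 0)) stop("invalid phantom_spec: base_radius must be > 0 everywhere")
  if (any(epsf(s_chk) < 0)) stop("invalid phantom_spec: distension must be >= 0 everywhere")
  if (heart_rate < 40 || heart_rate > 120)
    stop("invalid phantom_spec: heart_rate must lie in 40..120 beats/min")
  if (sample_rate * sweep_duration < 2)
    stop("invalid phantom_spec: sample_rate * sweep_duration must give >= 2 frames")
  if (es_pressure <= ed_pressure)
    stop("invalid phantom_spec: es_pressure must exceed ed_pressure")
  if (pixel_spacing <= 0) stop("invalid phantom_spec: pixel_spacing must be > 0")
  if (is.null(centerline_control_points))
    centerline_control_points <- cbind(0, 0, c(0, length_mm))
  structure(list(
    centerline_control_points = centerline_control_points,
    r0 = r0, eps = epsf,
    heart_rate = heart_rate, waveform = waveform,
    probe_speed = probe_speed, sweep_duration = sweep_duration,
    sample_rate = sample_rate, pixel_spacing = pixel_spacing,
    image_size = as.integer(image_size),
    speckle_sd = speckle_sd, jitter_pos_sd = jitter_pos_sd,
    jitter_rot_sd = jitter_rot_sd,
    wall_thickness = wall_thickness,
    lateral_attenuation = lateral_attenuation,
    ed_pressure = ed_pressure, es_pressure = es_pressure,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' Gaussian-bulge aneurysm radius profile
#'
#' `r0(s) = r_base + (r_max - r_base) * exp(-(s - s0)^2 / (2 sigma^2))`:
#' a smooth focal dilatation capturing the large axial change in vessel
#' dimension typical of an aneurysm.
#'
#' @param r_base Radius away from the bulge, mm.
#' @param r_max Peak radius, mm.
#' @param s0 Bulge centre arclength, mm.
#' @param sigma Bulge width, mm.
#' @return A function of arclength `s` (mm).
#' @export
aneurysm_profile <- function(r_base, r_max, s0, sigma) {
  force(r_base); force(r_max); force(s0); force(sigma)
  function(s) r_base + (r_max - r_base) * exp(-(s - s0)^2 / (2 * sigma^2))
}

# cardiac waveform w(t) in [0, 1]; w = 0 at ED, w = 1 at ES
phantom_waveform <- function(t, heart_rate, shape) {
  f <- heart_rate / 60
  if (shape == "sinusoid") {
    0.5 - 0.5 * cos(2 * pi * f * t)
  } else {
    # skewed systole: fast upstroke, slower decay, same period and extrema
    ph <- (f * t) %% 1
    k <- 0.3  # fraction of the cycle spent on the upstroke
    ifelse(ph < k,
           0.5 - 0.5 * cos(pi * ph / k),
           0.5 + 0.5 * cos(pi * (ph - k) / (1 - k)))
  }
}

#' Generate a synthetic tracked sweep
#'
#' Produces an ordered series of tracked frames (2D image + probe pose +
#' timestamp) of a pulsating vessel, together with exact analytic ground truth
#' for every downstream stage: per-frame true contours, ED/ES contours at each
#' frame location, the true local distensibility profile, true ED/ES volumes,
#' the true heart frequency and the true ED frame indices. Output is fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param render If `FALSE`, images are skipped (poses/contours only); useful
#'   for fast geometry-level tests.
#' @return A list with elements `frames` (list of tracked frames, each with
#'   `image`, `pose`, `timestamp`, `frame_index`), `truth` (ground-truth list)
#'   and `spec`.
#' @export
generate_sweep <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- as.integer(floor(spec$sweep_duration * spec$sample_rate))
  t <- (seq_len(n) - 1L) / spec$sample_rate
  s <- spec$probe_speed * t                    # probe arclength position, mm
  w <- phantom_waveform(t, spec$heart_rate, spec$waveform)
  r0 <- spec$r0(s)
  eps <- spec$eps(s)
  r_t <- r0 * (1 + eps * w)                    # instantaneous radius per frame

  n_theta <- 64L
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  # world centreline: straight along z by construction of default control pts;
  # general control points are interpolated linearly in arclength
  cp <- spec$centerline_control_points
  axis_pts <- centerline_point_at(cp, s)

  jp <- spec$jitter_pos_sd
  jr <- spec$jitter_rot_sd * pi / 180

  frames <- vector("list", n)
  true_contours <- vector("list", n)
  for (k in seq_len(n)) {
    trans <- axis_pts[k, ]
    ang <- c(0, 0, 0)
    if (jp > 0) trans <- trans + stats::rnorm(3, 0, jp)
    if (jr > 0) ang <- stats::rnorm(3, 0, jr)
    Rm <- rot_xyz(ang)
    q <- rotmat_to_quat(Rm)
    pose <- list(translation = trans, quaternion = q, timestamp = t[k])
    # true in-plane contour (circle of radius r_t[k]) expressed in image-plane
    # coordinates of the (possibly jittered) pose: world pt = R p + T
    world <- cbind(r_t[k] * cos(theta), r_t[k] * sin(theta), 0)
    world <- sweep(world, 2, axis_pts[k, ], "+")
    inplane <- t(t(Rm) %*% (t(world) - trans))[, 1:2, drop = FALSE]
    img <- NULL
    if (render) img <- render_frame(inplane, spec)
    frames[[k]] <- list(image = img, pose = pose, timestamp = t[k],
                        frame_index = k, pixel_spacing = spec$pixel_spacing)
    true_contours[[k]] <- inplane
  }

  dP <- spec$es_pressure - spec$ed_pressure
  d_true <- function(ss) ((1 + spec$eps(ss))^2 - 1) / dP
  # true volumes by fine quadrature of pi r^2 ds over the swept extent
  L <- spec$probe_speed * spec$sweep_duration
  sq <- seq(0, L, length.out = 2001)
  v_ed <- sum(pi * spec$r0(sq)^2) * (sq[2] - sq[1]) / 1000
  v_es <- sum(pi * (spec$r0(sq) * (1 + spec$eps(sq)))^2) * (sq[2] - sq[1]) / 1000

  f <- spec$heart_rate / 60
  ed_times <- seq(0, spec$sweep_duration - 1e-9, by = 1 / f)
  ed_idx <- vapply(ed_times, function(tt) which.min(abs(t - tt)), integer(1))

  truth <- list(
    contours = true_contours,
    radius = r_t, base_radius = r0, eps = eps, arclength = s,
    ed_radius = r0, es_radius = r0 * (1 + eps),
    d_local = d_true, pulse_pressure = dP,
    v_ed_ml = v_ed, v_es_ml = v_es,
    heart_frequency = f, ed_frames = unique(ed_idx),
    axis_points = axis_pts, timestamps = t)
  list(frames = frames, truth = truth, spec = spec)
}

#' Render one cross-sectional phantom image
#'
#' Dark lumen, bright wall band, mid-grey background, optional lateral
#' contrast attenuation and multiplicative speckle-like noise. The maximal
#' dark-to-bright intensity step along any ray from the vessel centre sits on
#' the true contour by construction.
#'
#' @param true_contour In-plane contour points (n x 2 matrix, mm) of the
#'   lumen--wall interface for this frame.
#' @param spec A [phantom_spec()] (pixel spacing, image size, noise, wall
#'   thickness and attenuation are taken from it).
#' @return A square numeric intensity matrix in `[0, 1]` (rows = y, cols = x).
#' @export
render_frame <- function(true_contour, spec) {
  np <- spec$image_size
  half_fov <- np * spec$pixel_spacing / 2
  if (any(abs(true_contour) > half_fov - spec$wall_thickness))
    stop("contour exceeds the field of view")
  ctr <- colMeans(true_contour)
  g <- (seq_len(np) - (np + 1) / 2) * spec$pixel_spacing
  xs <- matrix(g, np, np, byrow = TRUE)
  ys <- matrix(g, np, np)
  dx <- xs - ctr[1]; dy <- ys - ctr[2]
  rr <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  # radius of the true contour at each pixel's angle (contour is star-shaped)
  cth <- atan2(true_contour[, 2] - ctr[2], true_contour[, 1] - ctr[1])
  ord <- order(cth)
  cth_s <- cth[ord]
  crad <- sqrt((true_contour[, 1] - ctr[1])^2 + (true_contour[, 2] - ctr[2])^2)[ord]
  r_at <- stats::approx(c(cth_s - 2 * pi, cth_s, cth_s + 2 * pi),
                        rep(crad, 3), xout = as.vector(ang), rule = 2)$y
  r_at <- matrix(r_at, np, np)

  # partial-volume edge: intensity ramps over ~0.7 px (finite beam width),
  # keeping the transition midpoint exactly on the true contour
  ramp <- function(x, w) pmin(pmax(x / w + 0.5, 0), 1)
  w_edge <- 0.7 * spec$pixel_spacing
  s1 <- ramp(rr - r_at, w_edge)                          # lumen -> wall
  s2 <- ramp(rr - (r_at + spec$wall_thickness), w_edge)  # wall -> background
  img <- 0.08 + (0.95 - 0.08) * s1 + (0.35 - 0.95) * s2
  if (spec$lateral_attenuation < 1) {
    # signal dropout in the sectors around the +/- x axis: the whole image
    # fades towards the background level (poor lateral echogenicity)
    lat <- abs(cos(ang)) > cos(pi / 6)
    img[lat] <- 0.35 + spec$lateral_attenuation * (img[lat] - 0.35)
  }
  if (spec$speckle_sd > 0) {
    img <- img * (1 + spec$speckle_sd * matrix(stats::rnorm(np * np), np, np))
    img <- pmin(pmax(img, 0), 1.5)
  }
  img
}

# --- small internal linear-algebra helpers -------------------------------

rot_xyz <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    S <- sqrt(tr + 1) * 2
    q <- c(S / 4, (R[3, 2] - R[2, 3]) / S, (R[1, 3] - R[3, 1]) / S,
           (R[2, 1] - R[1, 2]) / S)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    S <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / S, S / 4, (R[1, 2] + R[2, 1]) / S,
           (R[1, 3] + R[3, 1]) / S)
  } else if (R[2, 2] > R[3, 3]) {
    S <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / S, (R[1, 2] + R[2, 1]) / S, S / 4,
           (R[2, 3] + R[3, 2]) / S)
  } else {
    S <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / S, (R[1, 3] + R[3, 1]) / S,
           (R[2, 3] + R[3, 2]) / S, S / 4)
  }
  q / sqrt(sum(q^2))
}

quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# piecewise-linear point on a control polyline at given arclengths
centerline_point_at <- function(cp, s) {
  cp <- as.matrix(cp)
  seg <- sqrt(rowSums(diff(cp)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(cp) - 1L)
  frac <- (s - cum[idx]) / seg[idx]
  cp[idx, , drop = FALSE] + frac * (cp[idx + 1L, , drop = FALSE] - cp[idx, , drop = FALSE])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
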