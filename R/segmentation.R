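#' Euclidean shortening flow despeckling
#'
#' Edge-preserving despeckling by curvature motion: each iteration updates
#' `I <- I + dt * kappa * |grad I|` where `kappa` is the curvature of the
#' intensity level sets, so level curves shrink proportionally to their
#' curvature while straight edges are left untouched. Obeys a maximum
#' principle: the global intensity range never expands (the update is clamped
#' to the input range to keep the discretisation faithful to it).
#'
#' @param img Numeric intensity matrix.
#' @param n_iter Number of iterations (`0` returns the input unchanged).
#' @param dt Time step; must lie in `(0, 0.25]` for stability.
#' @return The filtered matrix.
#' @export
esf_despeckle <- function(img, n_iter = 8, dt = 0.2) {
  if (!all(is.finite(img))) stop("non-finite intensities in input image")
  stopifnot(n_iter >= 0, dt > 0, dt <= 0.25)
  if (n_iter == 0) return(img)
  lo <- min(img); hi <- max(img)
  eps <- 1e-8
  for (it in seq_len(n_iter)) {
    p <- pad_replicate(img)
    n <- nrow(img); m <- ncol(img)
    ic <- 2:(n + 1); jc <- 2:(m + 1)
    Ix  <- (p[ic, jc + 1] - p[ic, jc - 1]) / 2
    Iy  <- (p[ic + 1, jc] - p[ic - 1, jc]) / 2
    Ixx <- p[ic, jc + 1] - 2 * p[ic, jc] + p[ic, jc - 1]
    Iyy <- p[ic + 1, jc] - 2 * p[ic, jc] + p[ic - 1, jc]
    Ixy <- (p[ic + 1, jc + 1] - p[ic + 1, jc - 1] -
            p[ic - 1, jc + 1] + p[ic - 1, jc - 1]) / 4
    num <- Ixx * Iy^2 - 2 * Ixy * Ix * Iy + Iyy * Ix^2
    den <- Ix^2 + Iy^2
    img <- img + dt * num / (den + eps)
    img[img < lo] <- lo
    img[img > hi] <- hi
  }
  img
}

#' 3x3 Gaussian smoothing
#'
#' Convolution with the normalised 3x3 Gaussian kernel
#' `[1 2 1; 2 4 2; 1 2 1] / 16` using replicated (reflective at one pixel)
#' borders, so constant images are unchanged and the image sum is preserved
#' to within numerical tolerance.
#'
#' @param img Numeric intensity matrix.
#' @return The smoothed matrix.
#' @export
gaussian_smooth3 <- function(img) {
  p <- pad_replicate(img)
  n <- nrow(img); m <- ncol(img)
  ic <- 2:(n + 1); jc <- 2:(m + 1)
  (4 * p[ic, jc] +
     2 * (p[ic, jc - 1] + p[ic, jc + 1] + p[ic - 1, jc] + p[ic + 1, jc]) +
     (p[ic - 1, jc - 1] + p[ic - 1, jc + 1] +
        p[ic + 1, jc - 1] + p[ic + 1, jc + 1])) / 16
}

pad_replicate <- function(img) {
  n <- nrow(img); m <- ncol(img)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- img
  p[1, 2:(m + 1)] <- img[1, ]
  p[n + 2, 2:(m + 1)] <- img[n, ]
  p[, 1] <- p[, 2]
  p[, m + 2] <- p[, m + 1]
  p
}

#' Construct the radial search band around a reference ellipse
#'
#' The band is extruded both inwards and outwards from the reference contour.
#' The total radial thickness is 2.5 mm for healthy aortas and 7 mm for
#' aneurysms (where morphological change between frames adds to the pulsatile
#' change); the split is symmetric, capped so the inner edge stays strictly
#' inside the lumen.
#'
#' @param reference An [ellipse()] (previous frame's segmentation).
#' @param vessel_class `"healthy"` or `"aaa"`.
#' @param thickness Optional explicit total radial thickness, mm.
#' @return A list with `reference`, `inward`, `outward`, `thickness`.
#' @export
search_band <- function(reference, vessel_class = c("healthy", "aaa"),
                        thickness = NULL) {
  vessel_class <- match.arg(vessel_class)
  if (is.null(thickness))
    thickness <- if (vessel_class == "healthy") 2.5 else 7
  inward <- min(thickness / 2, 0.9 * reference$b)
  outward <- thickness - inward
  list(reference = reference, inward = inward, outward = outward,
       thickness = thickness)
}

#' Star edge detection within a radial search band
#'
#' Casts equiangular rays from the reference-ellipse centre and searches for
#' the strongest dark-to-bright step along each ray, restricted to the radial
#' band around the reference contour. The edge response is the correlation
#' with a symmetric step kernel (`w` samples of -1 followed by `w` of +1);
#' rays whose best response falls below `accept_frac` of the frame's maximal
#' response yield no candidate, which keeps attenuated lateral sectors from
#' injecting spurious points.
#'
#' @param img Intensity matrix (rows = y, cols = x).
#' @param band A [search_band()].
#' @param pixel_spacing mm/pixel.
#' @param n_rays Number of equiangular rays (default 64).
#' @param step_mm Radial sampling step along each ray, mm.
#' @param kernel_w Half-width of the step kernel, samples.
#' @param accept_frac Relative acceptance threshold.
#' @return A data.frame with columns `theta`, `x`, `y` (mm, image coordinates)
#'   and `score`; at most one row per ray.
#' @export
star_edge_candidates <- function(img, band, pixel_spacing,
                                 n_rays = 64, step_mm = 0.1,
                                 kernel_w = 5, accept_frac = 0.3) {
  e <- band$reference
  np_r <- nrow(img); np_c <- ncol(img)
  half_r <- (np_r + 1) / 2; half_c <- (np_c + 1) / 2
  theta <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  r_ref <- ellipse_radius(e, theta)
  pad <- kernel_w * step_mm
  r_lo <- pmax(r_ref - band$inward - pad, step_mm)
  r_hi <- r_ref + band$outward + pad
  n_s <- max(ceiling((max(r_hi) - min(r_lo)) / step_mm)) + 1L

  # common radial sample count per ray; per-ray offsets
  n_samp <- ceiling((r_hi - r_lo) / step_mm)
  n_max <- max(n_samp)
  rs <- outer(rep(1, n_rays), 0:(n_max - 1)) * step_mm + r_lo  # n_rays x n_max
  valid <- sweep(matrix(0:(n_max - 1), n_rays, n_max, byrow = TRUE), 1,
                 n_samp, "<")
  xs <- e$cx + rs * cos(theta)
  ys <- e$cy + rs * sin(theta)
  # mm -> fractional pixel indices (col from x, row from y)
  ci <- xs / pixel_spacing + half_c
  ri <- ys / pixel_spacing + half_r
  if (any(valid & (ci < 1 | ci > np_c | ri < 1 | ri > np_r)))
    stop("search band extends outside the image")
  vals <- bilinear_sample(img, ri, ci)
  vals[!valid] <- NA_real_

  res <- matrix(NA_real_, n_rays, n_max)
  # step response: sum of next kernel_w samples minus sum of previous kernel_w
  cs <- t(apply(vals, 1, function(v) cumsum(ifelse(is.na(v), 0, v))))
  for (i in seq_len(n_rays)) {
    nv <- n_samp[i]
    if (nv < 2 * kernel_w + 1) next
    pos <- (kernel_w + 1):(nv - kernel_w)
    after <- cs[i, pos + kernel_w] - cs[i, pos]
    before <- cs[i, pos] - cs[i, pos - kernel_w]
    res[i, pos] <- (after - before) / kernel_w
  }
  best <- apply(res, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  top <- max(best, na.rm = TRUE)
  if (!is.finite(top) || top <= 1e-9)
    return(data.frame(theta = numeric(0), x = numeric(0), y = numeric(0),
                      score = numeric(0)))
  keep <- which(is.finite(best) & best >= accept_frac * top & best > 1e-9)
  if (length(keep) == 0)
    return(data.frame(theta = numeric(0), x = numeric(0), y = numeric(0),
                      score = numeric(0)))
  idx <- vapply(keep, function(i) which.max(res[i, ]), integer(1))
  # the discrete response peaks half a sample before the transition midpoint
  r_edge <- rs[cbind(keep, idx)] + 0.5 * step_mm
  # sub-sample refinement: parabolic interpolation of the response peak
  for (j in seq_along(keep)) {
    i <- keep[j]; p <- idx[j]
    if (p > 1 && p < n_max &&
        is.finite(res[i, p - 1]) && is.finite(res[i, p + 1])) {
      denom <- res[i, p - 1] - 2 * res[i, p] + res[i, p + 1]
      if (denom < -1e-12) {
        off <- 0.5 * (res[i, p - 1] - res[i, p + 1]) / denom
        r_edge[j] <- r_edge[j] + max(min(off, 0.5), -0.5) * step_mm
      }
    }
  }
  data.frame(theta = theta[keep],
             x = e$cx + r_edge * cos(theta[keep]),
             y = e$cy + r_edge * sin(theta[keep]),
             score = best[keep])
}

bilinear_sample <- function(img, ri, ci) {
  n <- nrow(img); m <- ncol(img)
  r0 <- pmin(pmax(floor(ri), 1), n - 1)
  c0 <- pmin(pmax(floor(ci), 1), m - 1)
  fr <- ri - r0; fc <- ci - c0
  fr[!is.finite(fr)] <- 0; fc[!is.finite(fc)] <- 0
  i00 <- img[cbind(as.vector(r0), as.vector(c0))]
  i01 <- img[cbind(as.vector(r0), as.vector(c0 + 1))]
  i10 <- img[cbind(as.vector(r0 + 1), as.vector(c0))]
  i11 <- img[cbind(as.vector(r0 + 1), as.vector(c0 + 1))]
  out <- (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
  matrix(out, nrow(ri), ncol(ri))
}

#' One Kalman predict--update step for the ellipse tracker
#'
#' The state is the 5-parameter ellipse `(cx, cy, a, b, phi)` with random-walk
#' dynamics: predict adds the process covariance, update blends prediction and
#' measurement by the Kalman gain. With vanishing measurement noise the
#' posterior converges to the measurement; with vanishing process noise it
#' sticks to the prediction.
#'
#' @param state A list with `ellipse` (an [ellipse()]), `P` (5x5 state
#'   covariance), `Q` (process noise), `R` (measurement noise).
#' @param measurement The fitted [ellipse()] for the current frame.
#' @return The updated state (same structure).
#' @export
kalman_step <- function(state, measurement) {
  chk_psd <- function(M, name) {
    if (any(abs(M - t(M)) > 1e-8) || any(eigen(M, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-8))
      stop(sprintf("%s covariance must be symmetric positive semi-definite", name))
  }
  chk_psd(state$P, "state"); chk_psd(state$Q, "process"); chk_psd(state$R, "measurement")
  x <- ellipse_state_vec(state$ellipse)
  z <- ellipse_state_vec(measurement)
  # the rotation lives on [0, pi); take the representative nearest the state
  dphi <- (z[5] - x[5] + pi / 2) %% pi - pi / 2
  z[5] <- x[5] + dphi
  P <- state$P + state$Q
  K <- P %*% solve(P + state$R)
  xn <- as.vector(x + K %*% (z - x))
  Pn <- (diag(5) - K) %*% P
  state$ellipse <- ellipse(xn[1], xn[2], xn[3], xn[4], xn[5])
  state$P <- (Pn + t(Pn)) / 2
  state
}

ellipse_state_vec <- function(e) c(e$cx, e$cy, e$a, e$b, e$phi)

#' Default Kalman covariances for the ellipse tracker
#' @param process_sd_mm Random-walk SD per frame for centres and semi-axes, mm.
#' @param process_sd_rad Random-walk SD per frame for the rotation, rad.
#' @param meas_sd_mm Measurement SD for centres and semi-axes, mm.
#' @param meas_sd_rad Measurement SD for the rotation, rad.
#' @return A list with `P`, `Q`, `R` 5x5 matrices.
#' @export
kalman_defaults <- function(process_sd_mm = 0.3, process_sd_rad = 0.02,
                            meas_sd_mm = 0.5, meas_sd_rad = 0.05) {
  Q <- diag(c(rep(process_sd_mm^2, 4), process_sd_rad^2))
  R <- diag(c(rep(meas_sd_mm^2, 4), meas_sd_rad^2))
  list(P = R, Q = Q, R = R)
}

#' Segment a full sweep with the star--Kalman tracker
#'
#' For each frame: despeckle (Euclidean shortening flow), smooth (3x3
#' Gaussian), detect edge candidates along rays within a search band built on
#' the previous frame's ellipse, fit an ellipse through them, and stabilise
#' frame to frame with a Kalman filter. A frame whose fit fails inherits the
#' previous ellipse with a warning; more than `max_failures` consecutive
#' failures aborts with "track lost".
#'
#' @param frames List of frames; each needs `image` (matrix) and
#'   `pixel_spacing` (or pass `pixel_spacing`).
#' @param init Manually defined initial [ellipse()] at the aorta location in
#'   the first frame.
#' @param vessel_class `"healthy"` (band 2.5 mm) or `"aaa"` (band 7 mm).
#' @param pixel_spacing mm/pixel; taken from the frames if absent.
#' @param n_rays Number of star rays.
#' @param esf_iter,esf_dt Despeckling iterations and step.
#' @param max_failures Consecutive fit failures tolerated before aborting.
#' @param kalman Covariances from [kalman_defaults()], or `NULL` to disable
#'   stabilisation.
#' @return A list of one [ellipse()] per frame, with attribute `"failures"`
#'   (frame indices that inherited the previous contour).
#' @export
segment_sweep <- function(frames, init, vessel_class = c("healthy", "aaa"),
                          pixel_spacing = NULL, n_rays = 64,
                          esf_iter = 8, esf_dt = 0.2,
                          max_failures = 10, kalman = kalman_defaults()) {
  vessel_class <- match.arg(vessel_class)
  if (is.null(pixel_spacing)) pixel_spacing <- frames[[1]]$pixel_spacing
  out <- vector("list", length(frames))
  prev <- init
  state <- if (!is.null(kalman)) c(list(ellipse = init), kalman) else NULL
  fails <- integer(0)
  consec <- 0
  for (k in seq_along(frames)) {
    img <- if (is.list(frames[[k]])) frames[[k]]$image else frames[[k]]
    fitted <- tryCatch({
      f <- gaussian_smooth3(esf_despeckle(img, esf_iter, esf_dt))
      band <- search_band(prev, vessel_class)
      cand <- star_edge_candidates(f, band, pixel_spacing, n_rays = n_rays)
      if (nrow(cand) < 5) stop("insufficient edge support")
      e <- fit_ellipse(cand[, c("x", "y")])
      # measurement noise from the fit residuals: radial misfit of the edge
      # points, floored at half the ray sampling step
      th <- atan2(cand$y - e$cy, cand$x - e$cx)
      res <- sqrt((cand$x - e$cx)^2 + (cand$y - e$cy)^2) - ellipse_radius(e, th)
      attr(e, "fit_rms") <- max(sqrt(mean(res^2)), 0.05)
      e
    }, error = function(e) e)
    if (inherits(fitted, "error")) {
      consec <- consec + 1
      fails <- c(fails, k)
      if (consec > max_failures)
        stop(sprintf("track lost at frame %d (%d consecutive fit failures)",
                     k, consec))
      warning(sprintf("frame %d: %s; propagating previous ellipse",
                      k, conditionMessage(fitted)))
      out[[k]] <- prev
      next
    }
    consec <- 0
    if (!is.null(state)) {
      rms <- attr(fitted, "fit_rms")
      if (!is.null(rms)) {
        sd_rad <- max(rms / mean(c(fitted$a, fitted$b)), 0.01)
        state$R <- diag(c(rep(rms^2, 4), sd_rad^2))
      }
      state <- kalman_step(state, fitted)
      out[[k]] <- state$ellipse
    } else {
      out[[k]] <- fitted
    }
    prev <- out[[k]]
  }
  attr(out, "failures") <- fails
  out
}
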