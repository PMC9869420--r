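#' Fit ED/ES/MAP geometries and mechanics to a tracked sweep
#'
#' The single entry point of the analysis: runs segmentation (star--Kalman
#' ellipse tracking), cardiac timing (heart-frequency and end-diastole
#' detection from the lumen area--time signal), 4D geometry (3D centerline
#' from ED centres, polar grid, per-angle envelope detection, phase-contour
#' refit) and mechanics (local and global compliance, distensibility,
#' circumferential strain) on one sweep.
#'
#' @param sweep Either the output of [generate_sweep()] / a sweep-bundle list
#'   from [read_sweep_bundle()], or a list of frames.
#' @param pressures A `"pressure_measurement"` from
#'   [correct_brachial_pressure()], or a length-2 numeric
#'   `c(dia, sys)` brachial pair in mmHg.
#' @param init Initial [ellipse()] in the first frame. For a phantom sweep
#'   with ground truth it defaults to the first true contour's fit.
#' @param vessel_class `"healthy"` or `"aaa"` (sets the search-band width).
#' @param contours Optional precomputed list of per-frame ellipses, bypassing
#'   image segmentation (used to analyse ground-truth contours directly).
#' @param n_rays Star-ray count for segmentation.
#' @param n_angles Polar-grid angle count.
#' @param mask_spacing Pixel spacing for binary-mask areas, mm.
#' @param physio_range Physiological heart-frequency window, Hz.
#' @param ... Further arguments passed to [segment_sweep()].
#' @return An object of class `"aorta_fit"`; see [summary.aorta_fit()].
#' @export
fit_aorta_sweep <- function(sweep, pressures, init = NULL,
                            vessel_class = c("healthy", "aaa"),
                            contours = NULL, n_rays = 64, n_angles = 72,
                            mask_spacing = 0.1,
                            physio_range = c(40, 120) / 60, ...) {
  vessel_class <- match.arg(vessel_class)
  frames <- if (!is.null(sweep$frames)) sweep$frames else sweep
  if (is.numeric(pressures) && length(pressures) == 2)
    pressures <- correct_brachial_pressure(pressures[1], pressures[2])
  stopifnot(inherits(pressures, "pressure_measurement"))
  timestamps <- vapply(frames, `[[`, numeric(1), "timestamp")
  poses <- lapply(frames, `[[`, "pose")

  if (is.null(contours)) {
    if (is.null(init)) {
      if (is.null(sweep$truth))
        stop("init ellipse required when no ground truth is available")
      init <- fit_ellipse(sweep$truth$contours[[1]])
    }
    contours <- segment_sweep(frames, init, vessel_class,
                              n_rays = n_rays, ...)
  }

  signal <- lumen_area_series(contours, timestamps, pixel_spacing = mask_spacing)
  hf <- detect_heart_frequency(signal, physio_range)
  ed_frames <- detect_ed_frames(signal, hf)

  ed_centers <- t(vapply(ed_frames, function(k) {
    e <- contours[[k]]
    contour_to_world(cbind(e$cx, e$cy), poses[[k]])[1, ]
  }, numeric(3)))
  cl <- build_centerline(ed_centers)
  org <- frame_origins(cl, poses,
                       first_reference = contour_to_world(
                         cbind(contours[[1]]$cx, contours[[1]]$cy),
                         poses[[1]])[1, ])
  grid <- build_polar_grid(contours, org, timestamps, n_angles = n_angles)
  env <- envelope_radii(grid, hf)
  geoms <- refit_phase_contours(env, grid, poses)

  local <- lapply(seq_along(geoms$ED$frames), function(i) {
    local_mechanics(geoms$ED$ellipses[[i]], geoms$ES$ellipses[[i]],
                    pressures$pulse, pixel_spacing = mask_spacing)
  })
  local_df <- data.frame(
    frame = geoms$ED$frames,
    t = geoms$ED$t,
    s = geoms$ED$origins$s,
    a_ed = vapply(local, `[[`, numeric(1), "a_ed"),
    a_es = vapply(local, `[[`, numeric(1), "a_es"),
    c_local = vapply(local, `[[`, numeric(1), "c_local"),
    d_local = vapply(local, `[[`, numeric(1), "d_local"),
    strain = vapply(local, `[[`, numeric(1), "strain"),
    negative_distension = vapply(local, `[[`, logical(1), "negative_distension"))

  glob <- global_mechanics(geoms$ED, geoms$ES, pressures$pulse)

  structure(list(contours = contours, signal = signal, heart = hf,
                 ed_frames = ed_frames, centerline = cl, origins = org,
                 grid = grid, envelopes = env, geometry = geoms,
                 local = local_df, global = glob, pressures = pressures,
                 vessel_class = vessel_class,
                 n_angles = n_angles, mask_spacing = mask_spacing),
            class = "aorta_fit")
}

#' @export
print.aorta_fit <- function(x, ...) {
  cat(sprintf("aortic sweep fit (%s): %d frames, %d ED frames, heart %.2f Hz\n",
              x$vessel_class, nrow(x$signal), length(x$ed_frames),
              x$heart$f_peak))
  print(x$global)
  invisible(x)
}

#' Summary of a fitted sweep
#'
#' @param object An `"aorta_fit"`.
#' @param ... Unused.
#' @return A list with global mechanics, local mechanic summaries (mean +/-
#'   SD of distensibility and strain over stations), heart frequency and
#'   flags, printed on request.
#' @export
summary.aorta_fit <- function(object, ...) {
  loc <- object$local
  out <- list(
    n_frames = nrow(object$signal),
    heart = object$heart,
    ed_frames = object$ed_frames,
    global = object$global,
    d_local = cohort_summary(loc$d_local),
    strain = cohort_summary(loc$strain),
    negative_distension_frames = loc$frame[loc$negative_distension],
    degenerate_angles = sum(object$envelopes$degenerate))
  class(out) <- "summary.aorta_fit"
  out
}

#' @export
print.summary.aorta_fit <- function(x, ...) {
  cat(sprintf("frames: %d; heart %.2f Hz; ED frames: %d\n",
              x$n_frames, x$heart$f_peak, length(x$ed_frames)))
  print(x$global)
  cat(sprintf("local distensibility: %.1f +/- %.1f x10^-3 kPa^-1\n",
              1000 * x$d_local["mean"], 1000 * x$d_local["sd"]))
  cat(sprintf("circumferential strain: %.3f +/- %.3f\n",
              x$strain["mean"], x$strain["sd"]))
  if (length(x$negative_distension_frames))
    cat(sprintf("negative-distension frames: %s\n",
                paste(x$negative_distension_frames, collapse = ", ")))
  invisible(x)
}

#' @export
coef.aorta_fit <- function(object, ...) {
  c(v_ed_ml = object$global$v_ed, v_es_ml = object$global$v_es,
    c_global_ml_kpa = object$global$c_global,
    d_global_kpa = object$global$d_global,
    d_local_mean_kpa = mean(object$local$d_local),
    strain_mean = mean(object$local$strain),
    heart_hz = object$heart$f_peak)
}

#' Diagnostic plots for a fitted sweep
#'
#' Panel 1: lumen area--time signal with the detected ED frames. Panel 2: one
#' angle's radius--time signal with its ED/ES envelopes. Panel 3: local
#' distensibility along the vessel.
#'
#' @param x An `"aorta_fit"`.
#' @param angle Index of the polar angle shown in panel 2.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aorta_fit <- function(x, angle = 1, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$signal$t, x$signal$area, type = "l", xlab = "time (s)",
                 ylab = expression(area ~ (mm^2)), main = "lumen area-time", ...)
  graphics::abline(v = x$signal$t[x$ed_frames], col = "steelblue", lty = 3)
  graphics::plot(x$grid$t, x$grid$radii[angle, ], type = "l",
                 xlab = "time (s)", ylab = "radius (mm)",
                 main = sprintf("radius-time at angle %d with envelopes", angle))
  graphics::lines(x$grid$t, x$envelopes$r_es[angle, ], col = "purple")
  graphics::lines(x$grid$t, x$envelopes$r_ed[angle, ], col = "steelblue")
  graphics::plot(x$local$s, 1000 * x$local$d_local, type = "l",
                 xlab = "arclength (mm)",
                 ylab = expression(D[local] %*% 10^-3 ~ (kPa^-1)),
                 main = "local distensibility")
  invisible(x)
}
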