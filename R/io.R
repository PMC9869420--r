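#' Write a sweep bundle to disk
#'
#' The on-disk interchange format for a tracked sweep: grayscale frames as
#' `frames/NNNN.png` (8-bit grayscale, rescaled by the
#' recorded `intensity_scale`), per-frame poses in `poses.csv`
#' (`frame_index, t_s, x_mm, y_mm, z_mm, qw, qx, qy, qz`), acquisition
#' metadata in `meta.yaml`, and (when available) ground truth in
#' `truth.json`.
#'
#' @param sweep A [generate_sweep()] result (or a compatible list with
#'   `frames` and optional `truth`).
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sweep_bundle <- function(sweep, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  frames <- sweep$frames
  scale <- max(vapply(frames, function(f) max(f$image), numeric(1)), 1)
  for (f in frames) {
    png::writePNG(pmin(pmax(f$image / scale, 0), 1),
                  file.path(dir, "frames", sprintf("%04d.png", f$frame_index)))
  }
  poses <- do.call(rbind, lapply(frames, function(f) {
    data.frame(frame_index = f$frame_index, t_s = f$timestamp,
               x_mm = f$pose$translation[1], y_mm = f$pose$translation[2],
               z_mm = f$pose$translation[3],
               qw = f$pose$quaternion[1], qx = f$pose$quaternion[2],
               qy = f$pose$quaternion[3], qz = f$pose$quaternion[4])
  }))
  utils::write.csv(poses, file.path(dir, "poses.csv"), row.names = FALSE)
  meta <- list(pixel_spacing = frames[[1]]$pixel_spacing,
               image_size = nrow(frames[[1]]$image),
               n_frames = length(frames),
               intensity_scale = scale)
  if (!is.null(sweep$spec)) {
    sp <- sweep$spec
    meta$spec <- list(heart_rate = sp$heart_rate, waveform = sp$waveform,
                      probe_speed = sp$probe_speed,
                      sweep_duration = sp$sweep_duration,
                      sample_rate = sp$sample_rate,
                      speckle_sd = sp$speckle_sd, seed = sp$seed,
                      ed_pressure = sp$ed_pressure,
                      es_pressure = sp$es_pressure)
  }
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(sweep$truth)) {
    tr <- sweep$truth
    jsonlite::write_json(list(
      radius = tr$radius, base_radius = tr$base_radius, eps = tr$eps,
      arclength = tr$arclength, v_ed_ml = tr$v_ed_ml, v_es_ml = tr$v_es_ml,
      heart_frequency = tr$heart_frequency, ed_frames = tr$ed_frames,
      pulse_pressure = tr$pulse_pressure, timestamps = tr$timestamps,
      contours = lapply(tr$contours, unname)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a sweep bundle from disk
#'
#' @param dir Directory written by [write_sweep_bundle()].
#' @return A list with `frames` (image, pose, timestamp, frame_index,
#'   pixel_spacing), `meta` and, if present, `truth`.
#' @export
read_sweep_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  poses <- utils::read.csv(file.path(dir, "poses.csv"))
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  frames <- lapply(seq_len(nrow(poses)), function(i) {
    r <- poses[i, ]
    img <- png::readPNG(file.path(dir, "frames",
                                  sprintf("%04d.png", r$frame_index))) * scale
    list(image = img,
         pose = list(translation = c(r$x_mm, r$y_mm, r$z_mm),
                     quaternion = c(r$qw, r$qx, r$qy, r$qz),
                     timestamp = r$t_s),
         timestamp = r$t_s, frame_index = r$frame_index,
         pixel_spacing = meta$pixel_spacing)
  })
  out <- list(frames = frames, meta = meta)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    tr$contours <- lapply(tr$contours, as.matrix)
    out$truth <- tr
  }
  out
}

#' Write a phase geometry as an ASCII PLY mesh
#'
#' Ruled triangulation between consecutive contours with fan caps at both
#' ends (the same mesh [closed_mesh_volume()] integrates over).
#'
#' @param geometry A `"phase_geometry"`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(geometry, path) {
  contours <- geometry$contours
  n <- nrow(contours[[1]]); m <- length(contours)
  verts <- do.call(rbind, contours)
  ctr1 <- colMeans(contours[[1]]); ctr2 <- colMeans(contours[[m]])
  verts <- rbind(verts, ctr1, ctr2)
  i_c1 <- n * m; i_c2 <- n * m + 1          # 0-based centroid indices
  nxt <- c(2:n, 1)
  faces <- list()
  for (k in seq_len(m - 1)) {
    a <- (k - 1) * n + (1:n) - 1
    b <- k * n + (1:n) - 1
    an <- (k - 1) * n + nxt - 1
    bn <- k * n + nxt - 1
    faces[[length(faces) + 1]] <- cbind(a, an, b)
    faces[[length(faces) + 1]] <- cbind(an, bn, b)
  }
  a <- (1:n) - 1; an <- nxt - 1
  faces[[length(faces) + 1]] <- cbind(an, a, i_c1)
  a <- (m - 1) * n + (1:n) - 1; an <- (m - 1) * n + nxt - 1
  faces[[length(faces) + 1]] <- cbind(a, an, i_c2)
  fmat <- do.call(rbind, faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(fmat)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]), con)
  writeLines(sprintf("3 %d %d %d", fmat[, 1], fmat[, 2], fmat[, 3]), con)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Emits `contours.csv` (per-frame segmented ellipses), one
#' `geometry_<PHASE>.ply` and `contours_<PHASE>.csv` per phase,
#' `mechanics_local.csv`, `mechanics_global.json` and a `run.json` sidecar
#' with the resolved settings, so a rerun with the same inputs is
#' bit-identical.
#'
#' @param fit An `"aorta_fit"`.
#' @param dir Output directory.
#' @param seed Seed echoed into the sidecar (the analysis itself is
#'   deterministic).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- do.call(rbind, lapply(seq_along(fit$contours), function(k) {
    e <- fit$contours[[k]]
    data.frame(frame_index = k, t_s = fit$signal$t[k], cx_mm = e$cx,
               cy_mm = e$cy, a_mm = e$a, b_mm = e$b, phi_rad = e$phi)
  }))
  utils::write.csv(seg, file.path(dir, "contours.csv"), row.names = FALSE)
  for (ph in names(fit$geometry)) {
    g <- fit$geometry[[ph]]
    write_ply(g, file.path(dir, sprintf("geometry_%s.ply", ph)))
    cc <- do.call(rbind, lapply(seq_along(g$contours), function(i)
      data.frame(frame = g$frames[i], angle_index = seq_along(g$theta),
                 x_mm = g$contours[[i]][, 1], y_mm = g$contours[[i]][, 2],
                 z_mm = g$contours[[i]][, 3])))
    utils::write.csv(cc, file.path(dir, sprintf("contours_%s.csv", ph)),
                     row.names = FALSE)
  }
  utils::write.csv(fit$local, file.path(dir, "mechanics_local.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(fit$global),
                       file.path(dir, "mechanics_global.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("aortasweep")),
    seed = seed, vessel_class = fit$vessel_class,
    n_angles = fit$n_angles, mask_spacing = fit$mask_spacing,
    heart_hz = fit$heart$f_peak,
    pressure_variant = fit$pressures$variant),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
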