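# shared fixtures, built in code at test time

# direct (already-corrected) pulse pressure in kPa, for phantom analyses
direct_pressure <- function(pulse_kpa) {
  structure(list(pulse = pulse_kpa, variant = "direct"),
            class = "pressure_measurement")
}

# small clean aneurysm phantom used by several modules; slow probe so that
# ~4 cardiac cycles fall in every 10 mm of vessel
clean_aaa_spec <- function(seed = 7) {
  phantom_spec(base_radius = aneurysm_profile(8, 10, 21, 8),
               distension = 0.1, heart_rate = 72, probe_speed = 3,
               sweep_duration = 14, image_size = 96, pixel_spacing = 0.5,
               ed_pressure = 10.6, es_pressure = 16.0, seed = seed)
}

# analytic tube geometry: radius profile r(y) along the y axis
tube_geometry <- function(rfun, n_contours = 60, length_mm = 50, n_theta = 72,
                          phase = "MAP") {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  cs <- lapply(seq(0, length_mm, length.out = n_contours), function(y) {
    r <- rfun(y)
    cbind(r * cos(th), y, r * sin(th))
  })
  structure(list(phase = phase, contours = cs, theta = th),
            class = "phase_geometry")
}

rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
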