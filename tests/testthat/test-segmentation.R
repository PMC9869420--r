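test_that("curvature-flow despeckling obeys its basic laws", {
  const <- matrix(5, 32, 32)
  expect_equal(esf_despeckle(const, 20), const)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(esf_despeckle(img, 0), img)
  out <- esf_despeckle(img, 15, 0.2)
  expect_gte(min(out), min(img) - 1e-6)  # maximum principle
  expect_lte(max(out), max(img) + 1e-6)
  expect_error(esf_despeckle(matrix(c(1, NA, 1, 1), 2)), "finite")
  expect_error(esf_despeckle(img, 5, dt = 0.4), "dt")
})

test_that("curve shortening does not grow a disk boundary", {
  n <- 64
  g <- seq(-1, 1, length.out = n)
  rr <- sqrt(outer(g^2, g^2, "+"))
  disk <- (rr < 0.6) * 1.0
  # perimeter of the 0.5-level set, estimated from the contour lines
  perim <- function(img) {
    cl <- grDevices::contourLines(g, g, img, levels = 0.5)[[1]]
    sum(sqrt(diff(cl$x)^2 + diff(cl$y)^2))
  }
  p0 <- perim(disk)
  p1 <- perim(esf_despeckle(disk, 20, 0.2))
  expect_lte(p1, p0 + 1e-6)
})

test_that("3x3 Gaussian smoothing preserves mass and shrinks noise", {
  const <- matrix(2, 16, 16)
  expect_equal(gaussian_smooth3(const), const)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- gaussian_smooth3(imp)
  expect_equal(out[4:6, 4:6],
               matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3))
  expect_equal(sum(out), 1, tolerance = 1e-6)
  set.seed(1)
  wn <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(var(as.vector(gaussian_smooth3(wn))), var(as.vector(wn)))
  expect_equal(sum(gaussian_smooth3(wn)), sum(wn), tolerance = 1e-6 * sum(abs(wn)))
})

test_that("star edge detection finds a clean ring within the band", {
  spec <- phantom_spec(base_radius = 10, distension = 0, image_size = 96,
                       pixel_spacing = 0.5, sweep_duration = 1, seed = 2)
  sw <- generate_sweep(spec)
  img <- gaussian_smooth3(esf_despeckle(sw$frames[[1]]$image, 8, 0.2))
  band <- search_band(ellipse(0, 0, 10, 10), "healthy", thickness = 4)
  cand <- star_edge_candidates(img, band, 0.5)
  expect_equal(nrow(cand), 64)
  r <- sqrt(cand$x^2 + cand$y^2)
  expect_lt(max(abs(r - 10)), 0.5)
})

test_that("a gradient-free band yields no candidates", {
  flat <- matrix(0.5, 96, 96)
  band <- search_band(ellipse(0, 0, 10, 10), "healthy", thickness = 4)
  cand <- star_edge_candidates(flat, band, 0.5)
  expect_equal(nrow(cand), 0)
})

test_that("attenuated lateral sectors yield no candidates while others do", {
  spec <- phantom_spec(base_radius = 10, distension = 0, image_size = 96,
                       pixel_spacing = 0.5, sweep_duration = 1,
                       lateral_attenuation = 0.02, seed = 2)
  sw <- generate_sweep(spec)
  img <- gaussian_smooth3(esf_despeckle(sw$frames[[1]]$image, 8, 0.2))
  band <- search_band(ellipse(0, 0, 10, 10), "healthy", thickness = 4)
  cand <- star_edge_candidates(img, band, 0.5)
  lateral <- abs(cos(cand$theta)) > cos(pi / 12)
  vertical <- abs(sin(cand$theta)) > cos(pi / 12)
  expect_equal(sum(lateral), 0)        # attenuated sectors rejected
  expect_gt(sum(vertical), 3)          # top/bottom rays detected
})

test_that("star edge recovery stays accurate under speckle", {
  spec <- phantom_spec(base_radius = 10, distension = 0, image_size = 96,
                       pixel_spacing = 0.5, sweep_duration = 1,
                       speckle_sd = 0.3, seed = 4)
  sw <- generate_sweep(spec)
  img <- gaussian_smooth3(esf_despeckle(sw$frames[[1]]$image, 8, 0.2))
  band <- search_band(ellipse(0, 0, 10.5, 10.5), "healthy", thickness = 4)
  cand <- star_edge_candidates(img, band, 0.5)
  r <- sqrt(cand$x^2 + cand$y^2)
  expect_lt(mean(abs(r - 10)), 0.5)
})

test_that("the search band reflects the vessel class", {
  b1 <- search_band(ellipse(0, 0, 10, 10), "healthy")
  b2 <- search_band(ellipse(0, 0, 25, 25), "aaa")
  expect_equal(b1$inward + b1$outward, 2.5)
  expect_equal(b2$inward + b2$outward, 7)
})

test_that("Kalman update interpolates between prediction and measurement", {
  st <- c(list(ellipse = ellipse(0, 0, 10, 8, 0.2)), kalman_defaults())
  # measurement equal to the prediction leaves the state unchanged
  out <- kalman_step(st, st$ellipse)
  expect_equal(out$ellipse, st$ellipse, tolerance = 1e-12)
  expect_lt(max(diag(out$P)), max(diag(st$P + st$Q)))
  # vanishing measurement noise: posterior equals the measurement
  st0 <- st; st0$R <- diag(5) * 1e-18
  meas <- ellipse(1, -1, 11, 7, 0.3)
  expect_equal(kalman_step(st0, meas)$ellipse, meas, tolerance = 1e-6)
  # componentwise convex combination for diagonal covariances
  out2 <- kalman_step(st, meas)
  expect_true(out2$ellipse$cx > 0 && out2$ellipse$cx < 1)
  expect_true(out2$ellipse$a > 10 && out2$ellipse$a < 11)
  expect_error(kalman_step(c(list(ellipse = st$ellipse),
                             list(P = matrix(-1, 5, 5), Q = st$Q, R = st$R)),
                           meas), "positive semi-definite")
})

test_that("Kalman filtering reduces measurement jitter on a static ellipse", {
  set.seed(10)
  true_e <- ellipse(0, 0, 10, 8, 0.5)
  # measurement noise much larger than the assumed process noise
  kd <- kalman_defaults(process_sd_mm = 0.05, meas_sd_mm = 0.8)
  st <- c(list(ellipse = true_e), kd)
  raw <- filt <- numeric(200)
  for (k in 1:200) {
    meas <- ellipse(rnorm(1, 0, 0.8), rnorm(1, 0, 0.8),
                    10 + rnorm(1, 0, 0.8), 8 + rnorm(1, 0, 0.8), 0.5)
    st <- kalman_step(st, meas)
    raw[k] <- meas$a
    filt[k] <- st$ellipse$a
  }
  expect_lt(var(filt[50:200]), var(raw[50:200]) / 4)
})

test_that("segment_sweep tracks a clean phantom to within 2% area error", {
  spec <- phantom_spec(base_radius = 9, distension = 0.08, sweep_duration = 4,
                       probe_speed = 3, image_size = 96, pixel_spacing = 0.5,
                       seed = 6)
  sw <- generate_sweep(spec)
  init <- fit_ellipse(sw$truth$contours[[1]])
  seg <- segment_sweep(sw$frames, init, "healthy")
  a_true <- pi * sw$truth$radius^2
  a_fit <- vapply(seg, ellipse_area, numeric(1))
  expect_lt(max(abs(a_fit - a_true) / a_true), 0.02)
  expect_length(attr(seg, "failures"), 0)
})

test_that("an offset initialisation converges back onto the vessel", {
  spec <- phantom_spec(base_radius = 9, distension = 0, sweep_duration = 2,
                       probe_speed = 1, image_size = 96, pixel_spacing = 0.5,
                       seed = 8)
  sw <- generate_sweep(spec)
  init <- ellipse(3, 0, 9, 9)  # centre deliberately offset by 3 mm
  seg <- segment_sweep(sw$frames, init, "aaa")  # wide band to recapture
  centres <- vapply(seg, function(e) sqrt(e$cx^2 + e$cy^2), numeric(1))
  expect_lt(centres[10], 0.5)  # recentred within 10 frames
  expect_lt(abs(ellipse_area(seg[[10]]) - pi * 81) / (pi * 81), 0.05)
})

test_that("a single frame returns the fit at the initialisation", {
  spec <- phantom_spec(base_radius = 10, distension = 0, sweep_duration = 1,
                       image_size = 96, pixel_spacing = 0.5, seed = 2)
  sw <- generate_sweep(spec)
  seg <- segment_sweep(sw$frames[1], ellipse(0, 0, 10, 10), "healthy",
                       pixel_spacing = 0.5)
  expect_length(seg, 1)
  expect_equal(ellipse_area(seg[[1]]), pi * 100, tolerance = 0.02)
})

test_that("persistent fit failure aborts with a lost track", {
  flat <- matrix(0.5, 64, 64)
  frames <- replicate(13, list(image = flat, pixel_spacing = 0.5),
                      simplify = FALSE)
  expect_error(
    suppressWarnings(segment_sweep(frames, ellipse(0, 0, 8, 8), "healthy",
                                   max_failures = 5)),
    "track lost")
})
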