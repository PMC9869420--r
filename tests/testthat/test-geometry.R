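pose_at <- function(translation, quaternion = c(1, 0, 0, 0))
  list(translation = translation, quaternion = quaternion)

quat_to_rotmat_test <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

test_that("contours map rigidly into world coordinates", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  # identity pose embeds at z = 0
  w <- contour_to_world(sq, pose_at(c(0, 0, 0)))
  expect_equal(w, cbind(sq, 0), ignore_attr = TRUE)
  # pure translation preserves shape
  w2 <- contour_to_world(sq, pose_at(c(0, 0, 50)))
  expect_equal(w2[, 3], rep(50, 4))
  expect_equal(as.vector(dist(w2)), as.vector(dist(cbind(sq, 0))),
               tolerance = 1e-12)
  # 90 degrees about x then translation: (x, y, 0) -> (x, 0, y) + T
  qx90 <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  w3 <- contour_to_world(rbind(c(1, 0), c(0, 1), c(2, 3)),
                         pose_at(c(10, 20, 30), qx90))
  expect_equal(w3, rbind(c(11, 20, 30), c(10, 20, 31), c(12, 20, 33)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(contour_to_world(sq, pose_at(c(0, 0, 0), c(1, 1, 0, 0))),
               "unit norm")
})

test_that("centerline interpolation respects straight and curved truths", {
  # collinear centres stay on their line
  p <- cbind(seq(0, 30, length.out = 6), 0, 0)
  cl <- build_centerline(p)
  expect_lt(max(abs(cl$points[, 2:3])), 1e-6)
  expect_true(all(diff(cl$arclength) > 0))
  # helical centres: dense smoothed line stays near the analytic helix
  tt <- seq(0, 4 * pi, length.out = 24)
  hel <- cbind(20 * cos(tt), 20 * sin(tt), 8 * tt)
  cl2 <- build_centerline(hel)
  d <- abs(sqrt(cl2$points[, 1]^2 + cl2$points[, 2]^2) - 20)
  expect_lt(stats::median(d), 0.5)
  expect_error(build_centerline(hel[1:3, ]), "too few cardiac cycles")
})

test_that("frame origins follow plane-centerline intersections", {
  p <- cbind(0, 0, seq(0, 50, by = 0.5))
  cl <- structure(list(points = p,
                       arclength = seq(0, 50, by = 0.5)),
                  class = "centerline3d")
  # orthogonal planes: origins equal the sampled centerline points
  poses <- lapply(c(5, 20, 42.3), function(z) pose_at(c(0, 0, z)))
  org <- frame_origins(cl, poses)
  expect_equal(org$z, c(5, 20, 42.3), tolerance = 1e-9)
  expect_equal(org$u, rep(0, 3), tolerance = 1e-9)
  expect_false(any(org$fallback))
  # plane tilted 30 degrees about x against the straight line:
  # line x=y=0 meets the plane through (0,0,20) with normal R*(0,0,1) at z=20
  q30 <- c(cos(pi / 12), sin(pi / 12), 0, 0)
  org2 <- frame_origins(cl, list(pose_at(c(0, 3, 20), q30)))
  nrm <- quat_to_rotmat_test(q30)[, 3]
  z_exp <- 20 + 3 * nrm[2] / nrm[3]   # closed-form line-plane intersection
  expect_equal(org2$z, z_exp, tolerance = 1e-6)
})

test_that("multiple plane crossings pick the continuity-preserving one", {
  # S-shaped centerline whose z oscillates: crosses the plane z = 10 at
  # x = 0, 3*pi and 6*pi
  s <- seq(-pi / 2, 2.5 * pi, length.out = 301)
  pts <- cbind(3 * s, 0, 10 + 5 * sin(s))
  cl <- structure(list(points = pts,
                       arclength = c(0, cumsum(sqrt(rowSums(diff(pts)^2))))),
                  class = "centerline3d")
  pose <- pose_at(c(0, 0, 10))
  org <- frame_origins(cl, list(pose), first_reference = c(8, 0, 10))
  expect_equal(org$z, 10, tolerance = 1e-6)
  # among the three crossings, the one nearest the reference is returned
  expect_lt(abs(org$x - 3 * pi), 0.5)
  expect_false(org$fallback)
  # a plane the centerline never reaches falls back to a projection, flagged
  org2 <- frame_origins(cl, list(pose_at(c(0, 0, 40))))
  expect_true(org2$fallback)
})

test_that("polar resampling matches closed forms", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(10 * cos(th), 10 * sin(th))
  r1 <- polar_resample(circle, c(0, 0), 36)
  expect_equal(r1, rep(10, 36), tolerance = 1e-9)
  # origin offset to (-3, 0): limacon closed form r(t) = 3 cos t + sqrt(100 - 9 sin^2 t)
  r2 <- polar_resample(circle, c(-3, 0), 72)
  tq <- seq(0, 2 * pi, length.out = 73)[-73]
  expect_equal(r2, 3 * cos(tq) + sqrt(100 - 9 * sin(tq)^2), tolerance = 1e-3)
  expect_error(polar_resample(circle, c(11, 0), 36), "origin outside lumen")
})

test_that("envelopes bound a sinusoidal radius signal", {
  t <- seq(0, 10, by = 1 / 25)
  r <- 10 + sin(2 * pi * 1 * t)
  grid <- structure(list(radii = rbind(r, r), theta = c(0, pi),
                         t = t, origins = NULL), class = "polar_grid")
  hf <- structure(list(f_peak = 1, f_low = 0.8, f_high = 1.2,
                       period_range = c(1 / 1.2, 1 / 0.8)),
                  class = "heart_frequency_range")
  env <- envelope_radii(grid, hf)
  # away from the boundary cycles the envelopes sit on the extremes
  mid <- t > 1 & t < 9
  expect_lt(max(abs(env$r_es[1, mid] - 11)), 0.02)
  expect_lt(max(abs(env$r_ed[1, mid] - 9)), 0.02)
  expect_true(all(env$r_ed <= env$r_es))
  expect_false(any(env$degenerate))
})

test_that("a constant radius degenerates to coincident envelopes", {
  t <- seq(0, 5, by = 1 / 25)
  grid <- structure(list(radii = matrix(10, 3, length(t)),
                         theta = c(0, 2, 4), t = t, origins = NULL),
                    class = "polar_grid")
  hf <- structure(list(f_peak = 1, f_low = 0.8, f_high = 1.2,
                       period_range = c(1 / 1.2, 1 / 0.8)),
                  class = "heart_frequency_range")
  env <- envelope_radii(grid, hf)
  expect_true(all(env$degenerate))
  expect_equal(env$r_es[2, ], rep(10, length(t)))
  expect_equal(env$r_ed[2, ], rep(10, length(t)))
})

test_that("envelopes track an axial radius trend under pulsation", {
  t <- seq(0, 12, by = 1 / 25)
  base <- 10 + 5 * t / 12            # 10 -> 15 mm along the sweep
  r <- base * (1 + 0.05 * (0.5 - 0.5 * cos(2 * pi * t)))
  grid <- structure(list(radii = rbind(r), theta = 0, t = t, origins = NULL),
                    class = "polar_grid")
  hf <- structure(list(f_peak = 1, f_low = 0.8, f_high = 1.2,
                       period_range = c(1 / 1.2, 1 / 0.8)),
                  class = "heart_frequency_range")
  env <- envelope_radii(grid, hf)
  mid <- t > 1 & t < 11
  ratio <- env$r_es[1, mid] / env$r_ed[1, mid]
  expect_lt(max(abs(ratio - 1.05)), 0.01 * 1.05)
})

test_that("the MAP radius is the ED/ES midpoint", {
  expect_equal(map_radius(10, 12), 11)
  expect_equal(map_radius(8, 8), 8)
  expect_equal(map_radius(5, 9), 7)
  expect_error(map_radius(10, 9), "envelope inversion")
  # vectorised midpoint identity
  r_ed <- runif(50, 5, 10); r_es <- r_ed + runif(50, 0, 2)
  expect_lt(max(abs(map_radius(r_ed, r_es) - (r_ed + r_es) / 2)), 1e-9)
})

test_that("phase refit reproduces elliptical truth and stays planar", {
  # pulsating elliptical vessel, all frames in z-stacked parallel planes
  t <- seq(0, 6, by = 1 / 25)
  w <- 0.5 - 0.5 * cos(2 * pi * t)
  poses <- lapply(seq_along(t), function(k)
    list(translation = c(0, 0, 2 * t[k]), quaternion = c(1, 0, 0, 0)))
  n_ang <- 72
  theta <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  radii <- sapply(seq_along(t), function(k) {
    e <- ellipse(0, 0, 10 * (1 + 0.1 * w[k]), 7 * (1 + 0.1 * w[k]), 0.3)
    ellipse_radius(e, theta)
  })
  org <- data.frame(u = rep(0, length(t)), v = 0, s = 2 * t, fallback = FALSE)
  grid <- structure(list(radii = radii, theta = theta, t = t, origins = org),
                    class = "polar_grid")
  hf <- structure(list(f_peak = 1, f_low = 0.8, f_high = 1.2,
                       period_range = c(1 / 1.2, 1 / 0.8)),
                  class = "heart_frequency_range")
  env <- envelope_radii(grid, hf)
  geoms <- refit_phase_contours(env, grid, poses)
  expect_named(geoms, c("ED", "ES", "MAP"))
  mid <- which(grid$t > 1 & grid$t < 5)
  for (k in mid[seq(1, length(mid), by = 20)]) {
    e_ed <- geoms$ED$ellipses[[k]]
    expect_equal(e_ed$a, 10, tolerance = 1e-3)
    expect_equal(e_ed$b, 7, tolerance = 1e-3)
    e_es <- geoms$ES$ellipses[[k]]
    expect_equal(e_es$a, 11, tolerance = 2e-3)
    # planarity: all contour points in the source frame's plane
    expect_lt(max(abs(geoms$MAP$contours[[k]][, 3] - 2 * grid$t[k])), 1e-6)
  }
  # volume ordering across phases
  v <- vapply(geoms, closed_mesh_volume, numeric(1))
  expect_true(v[["ED"]] <= v[["MAP"]] && v[["MAP"]] <= v[["ES"]])
})

test_that("without pulsation all three phase geometries coincide", {
  t <- seq(0, 4, by = 1 / 25)
  poses <- lapply(seq_along(t), function(k)
    list(translation = c(0, 0, 3 * t[k]), quaternion = c(1, 0, 0, 0)))
  n_ang <- 36
  theta <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  org <- data.frame(u = rep(0, length(t)), v = 0, s = 3 * t, fallback = FALSE)
  grid <- structure(list(radii = matrix(9, n_ang, length(t)), theta = theta,
                         t = t, origins = org), class = "polar_grid")
  hf <- structure(list(f_peak = 1, f_low = 0.8, f_high = 1.2,
                       period_range = c(1 / 1.2, 1 / 0.8)),
                  class = "heart_frequency_range")
  env <- envelope_radii(grid, hf)
  geoms <- refit_phase_contours(env, grid, poses)
  for (k in c(1, 50, 101)) {
    expect_equal(geoms$ED$contours[[k]], geoms$ES$contours[[k]],
                 tolerance = 1e-6)
    expect_equal(geoms$ED$contours[[k]], geoms$MAP$contours[[k]],
                 tolerance = 1e-6)
  }
})
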