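test_that("brachial correction reproduces the reference pulse pressures", {
  # volunteer V1: (68, 115) mmHg
  p1 <- correct_brachial_pressure(68, 115)
  expect_equal(p1$corrected_dia, 0.88 * 68 * 0.1333224, tolerance = 1e-12)
  expect_equal(p1$corrected_sys, 1.05 * 115 * 0.1333224, tolerance = 1e-12)
  expect_equal(p1$pulse, 8.121, tolerance = 1e-3)
  # patient B1: (96, 152) mmHg -> (159.6 - 84.48) mmHg = 10.02 kPa
  p2 <- correct_brachial_pressure(96, 152)
  expect_equal(p2$pulse, 10.02, tolerance = 1e-3)
  expect_error(correct_brachial_pressure(100, 100), "non-physiological")
  expect_error(correct_brachial_pressure(-5, 100), "non-physiological")
  # the division variant raises both pressures, narrowing the pulse slightly
  p3 <- correct_brachial_pressure(68, 115, variant = "division")
  expect_gt(p3$corrected_dia, p1$corrected_dia)
  expect_lt(p3$pulse, p1$pulse)
})

test_that("local mechanics follow the circle closed forms", {
  m <- local_mechanics(ellipse(0, 0, 10, 10), ellipse(0, 0, 11, 11), 8,
                       pixel_spacing = 0.02)
  expect_equal(m$strain, 0.1, tolerance = 1e-6)
  expect_equal(m$d_local, 0.02625, tolerance = 1e-3)
  expect_equal(m$d_local, m$c_local / m$a_ed)
  expect_false(m$negative_distension)
  # identical contours: all-zero response
  m0 <- local_mechanics(ellipse(0, 0, 10, 10), ellipse(0, 0, 10, 10), 8)
  expect_equal(m0$c_local, 0)
  expect_equal(m0$d_local, 0)
  expect_equal(m0$strain, 0)
  # elliptical case: (20,10) -> (21,10.5) at 8 kPa
  m2 <- local_mechanics(ellipse(0, 0, 20, 10), ellipse(0, 0, 21, 10.5), 8)
  expect_equal(m2$strain, 0.05, tolerance = 1e-6)
  expect_equal(m2$d_local, ((21 * 10.5 - 200) * pi) / (200 * pi * 8),
               tolerance = 5e-3)
  # shrinking area flags negative distension but keeps the value
  m3 <- local_mechanics(ellipse(0, 0, 10, 10), ellipse(0, 0, 9.5, 9.5), 8)
  expect_true(m3$negative_distension)
  expect_lt(m3$c_local, 0)
})

test_that("analytic and mask perimeters agree to a fraction of a percent", {
  e1 <- ellipse(0, 0, 10, 10); e2 <- ellipse(0, 0, 20, 10)
  for (e in list(e1, e2)) {
    ma <- local_mechanics(e, e, 8, perimeter = "analytic")
    mm <- local_mechanics(e, e, 8, perimeter = "mask")
    expect_equal(ma$l_ed, mm$l_ed, tolerance = 1e-3)
  }
})

test_that("circular sections obey D = ((1 + strain)^2 - 1) / dP exactly", {
  for (eps in c(0.02, 0.1, 0.18)) {
    r <- 8
    # analytic areas: the identity is exact for circles
    a_ed <- pi * r^2; a_es <- pi * (r * (1 + eps))^2
    d <- ((a_es - a_ed) / a_ed) / 5.4
    expect_equal(d, ((1 + eps)^2 - 1) / 5.4, tolerance = 1e-9)
    # and the pipeline's mask-based version agrees to raster precision
    m <- local_mechanics(ellipse(0, 0, r, r), ellipse(0, 0, r * (1 + eps),
                                                      r * (1 + eps)), 5.4,
                         pixel_spacing = 0.02)
    expect_equal(m$d_local, d, tolerance = 0.01)
    expect_equal(m$strain, eps, tolerance = 1e-9)
  }
})

test_that("strain and distensibility are invariant to uniform rescaling", {
  m1 <- local_mechanics(ellipse(0, 0, 8, 6, 0.2), ellipse(0, 0, 8.8, 6.6, 0.2),
                        6, pixel_spacing = 0.02)
  m2 <- local_mechanics(ellipse(0, 0, 16, 12, 0.2),
                        ellipse(0, 0, 17.6, 13.2, 0.2), 6, pixel_spacing = 0.02)
  expect_equal(m1$strain, m2$strain, tolerance = 1e-9)
  expect_equal(m1$d_local, m2$d_local, tolerance = 5e-3)
  # units audit via the closed forms: C in mm^2/kPa
  expect_equal(m1$c_local * 6, m1$dA, tolerance = 1e-12)
})

test_that("closed-mesh volumes match cylinder and frustum closed forms", {
  cyl <- tube_geometry(function(y) 10, n_contours = 100, length_mm = 50)
  expect_equal(closed_mesh_volume(cyl), pi * 100 * 50 / 1000,
               tolerance = 0.005)
  fr <- tube_geometry(function(y) 10 + 10 * y / 30, n_contours = 100,
                      length_mm = 30)
  expect_equal(closed_mesh_volume(fr), pi * 30 / 3 * (100 + 200 + 400) / 1000,
               tolerance = 0.005)
  expect_error(closed_mesh_volume(list(cyl$contours[[1]])), "at least 2")
})

test_that("an aneurysm bulge volume matches numeric quadrature", {
  r0 <- aneurysm_profile(8, 14, 25, 6)
  g <- tube_geometry(r0, n_contours = 200, length_mm = 50)
  sq <- seq(0, 50, length.out = 5001)
  v_true <- sum(pi * r0(sq)^2) * (sq[2] - sq[1]) / 1000
  expect_equal(closed_mesh_volume(g), v_true, tolerance = 0.01)
})

test_that("global mechanics reproduce reference subjects from volumes", {
  # volunteer V1
  g1 <- global_mechanics(3.65, 5.51, correct_brachial_pressure(68, 115)$pulse)
  expect_equal(round(g1$c_global, 2), 0.23)
  expect_equal(round(1000 * g1$d_global), 63)
  # patient B9
  g2 <- global_mechanics(95, 122, correct_brachial_pressure(94, 180)$pulse)
  expect_equal(round(g2$c_global, 1), 1.9)
  expect_equal(round(1000 * g2$d_global), 20)
  # no volume change: identically zero
  g3 <- global_mechanics(50, 50, 8)
  expect_equal(g3$c_global, 0)
  expect_equal(g3$d_global, 0)
  expect_equal(g2$d_global, g2$c_global / g2$v_ed)
})

test_that("the exact rank-sum enumeration matches closed forms and wilcox.test", {
  # complete separation at n1 = n2 = 3: p = 2 / choose(6, 3)
  rs <- rank_sum_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(rs$p, 0.1)
  expect_identical(rs$method, "exact")
  expect_false(rs$ties)
  # all-tied groups are uninformative
  rs2 <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(rs2$p, 1)
  expect_true(rs2$ties)
  # tie-free case agrees with the reference implementation
  set.seed(2)
  x <- rnorm(6); y <- rnorm(7) + 0.5
  expect_equal(rank_sum_test(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), y), "at least 2")
})

test_that("cohort summary is the mean and n-1 standard deviation", {
  expect_equal(cohort_summary(c(5, 5, 5)), c(mean = 5, sd = 0))
  x <- c(63, 64, 103, 69, 102, 90, 73, 82, 70, 79)
  s <- cohort_summary(x)
  expect_equal(unname(s["mean"]), mean(x))
  expect_equal(unname(s["sd"]), sd(x))
  expect_error(cohort_summary(5), "at least 2")
})
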