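MMHG_TO_KPA <- 0.1333224

#' Correct brachial cuff pressures to aortic pressures
#'
#' Brachial cuff measurements overestimate diastolic pressure by 12% and
#' underestimate systolic pressure by 5% relative to intra-aortic pressure,
#' so the cuff pair is corrected multiplicatively (diastolic x 0.88,
#' systolic x 1.05) and converted to kPa. A division variant
#' (diastolic / 1.12, systolic / 0.95) is available; the multiplicative form
#' is the default used throughout.
#'
#' @param dia,sys Brachial cuff diastolic and systolic pressure, mmHg
#'   (`0 < dia < sys`).
#' @param variant `"multiplicative"` (default) or `"division"`.
#' @return A list of class `"pressure_measurement"`: `brachial_dia`,
#'   `brachial_sys` (mmHg), `corrected_dia`, `corrected_sys`, `pulse` (kPa).
#' @export
#' @examples
#' correct_brachial_pressure(68, 115)
correct_brachial_pressure <- function(dia, sys,
                                      variant = c("multiplicative", "division")) {
  variant <- match.arg(variant)
  if (!is.finite(dia) || !is.finite(sys) || dia <= 0 || sys <= dia)
    stop("non-physiological blood pressure: need 0 < diastolic < systolic")
  if (variant == "multiplicative") {
    cd <- 0.88 * dia; cs <- 1.05 * sys
  } else {
    cd <- dia / 1.12; cs <- sys / 0.95
  }
  structure(list(brachial_dia = dia, brachial_sys = sys,
                 corrected_dia = cd * MMHG_TO_KPA,
                 corrected_sys = cs * MMHG_TO_KPA,
                 pulse = (cs - cd) * MMHG_TO_KPA,
                 variant = variant),
            class = "pressure_measurement")
}

#' @export
print.pressure_measurement <- function(x, ...) {
  cat(sprintf("brachial %g/%g mmHg -> aortic %.3f/%.3f kPa (pulse %.3f kPa)\n",
              x$brachial_sys, x$brachial_dia, x$corrected_sys,
              x$corrected_dia, x$pulse))
  invisible(x)
}

#' Local (cross-sectional) compliance, distensibility and strain
#'
#' From the ED and ES contours of one station: areas come from rasterised
#' binary masks of the ellipses (same convention as the lumen area--time
#' signal), circumferences from the analytic ellipse perimeter. Then
#' `C_local = dA / dP` (mm^2/kPa), `D_local = C_local / A_ED` (1/kPa) and
#' `eps_circ = (l_ES - l_ED) / l_ED`.
#'
#' @param contour_ed,contour_es [ellipse()] objects at ED and ES.
#' @param pulse_kpa Pulse pressure, kPa (> 0).
#' @param pixel_spacing Mask pixel spacing, mm.
#' @param perimeter `"analytic"` (Ramanujan, default) or `"mask"`
#'   (polygonal arc length of the raster-resolution contour).
#' @return A list of class `"slice_mechanics"`: `a_ed`, `a_es`, `dA`,
#'   `c_local`, `d_local`, `l_ed`, `l_es`, `strain`, and
#'   `negative_distension` (TRUE when `A_ES < A_ED`, a segmentation-error
#'   signature; values are retained).
#' @export
local_mechanics <- function(contour_ed, contour_es, pulse_kpa,
                            pixel_spacing = 0.1,
                            perimeter = c("analytic", "mask")) {
  perimeter <- match.arg(perimeter)
  stopifnot(pulse_kpa > 0)
  a_ed <- ellipse_mask_area(contour_ed, pixel_spacing)
  a_es <- ellipse_mask_area(contour_es, pixel_spacing)
  per <- function(e) {
    if (perimeter == "analytic") return(ellipse_perimeter(e))
    p <- ellipse_points(e, seq(0, 2 * pi, length.out = 1 + ceiling(
      ellipse_perimeter(e) / pixel_spacing)))
    sum(sqrt(rowSums((p - rbind(p[-1, ], p[1, ]))^2)))
  }
  l_ed <- per(contour_ed); l_es <- per(contour_es)
  dA <- a_es - a_ed
  c_local <- dA / pulse_kpa
  structure(list(a_ed = a_ed, a_es = a_es, dA = dA,
                 c_local = c_local, d_local = c_local / a_ed,
                 l_ed = l_ed, l_es = l_es,
                 strain = (l_es - l_ed) / l_ed,
                 negative_distension = dA < 0),
            class = "slice_mechanics")
}

#' Volume of a contour-stack geometry as a closed solid
#'
#' Builds a ruled triangulation between consecutive contours (matched-angle
#' vertices), caps both ends with triangle fans to the end-contour centroids,
#' and evaluates the signed volume with the divergence theorem. The absolute
#' value is returned in millilitres, independent of orientation.
#'
#' @param geometry A `"phase_geometry"`, or a list of n x 3 contour matrices
#'   with matched angular sampling.
#' @return Volume, ml.
#' @export
closed_mesh_volume <- function(geometry) {
  contours <- if (inherits(geometry, "phase_geometry")) geometry$contours else geometry
  if (length(contours) < 2) stop("need at least 2 contours to close a solid")
  n <- nrow(contours[[1]])
  if (any(vapply(contours, nrow, integer(1)) != n))
    stop("contours must share the angular sampling")
  vol6 <- 0
  tri_vol <- function(v1, v2, v3) {
    # scalar triple products, rowwise
    v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  }
  nxt <- c(2:n, 1)
  for (k in seq_len(length(contours) - 1)) {
    a <- contours[[k]]; b <- contours[[k + 1]]
    vol6 <- vol6 + sum(tri_vol(a, a[nxt, , drop = FALSE], b)) +
      sum(tri_vol(a[nxt, , drop = FALSE], b[nxt, , drop = FALSE], b))
  }
  cap <- function(cc, flip) {
    ctr <- matrix(colMeans(cc), n, 3, byrow = TRUE)
    s <- sum(tri_vol(cc, cc[nxt, , drop = FALSE], ctr))
    if (flip) -s else s
  }
  vol6 <- vol6 + cap(contours[[1]], flip = TRUE) +
    cap(contours[[length(contours)]], flip = FALSE)
  abs(vol6) / 6 / 1000
}

#' Global (volume-based) compliance and distensibility
#'
#' `C_global = (V_ES - V_ED) / dP` (ml/kPa) and
#' `D_global = C_global / V_ED` (1/kPa), with volumes from
#' [closed_mesh_volume()] when geometries are supplied.
#'
#' @param geom_ed,geom_es `"phase_geometry"` objects (or numeric volumes
#'   in ml).
#' @param pulse_kpa Pulse pressure, kPa.
#' @return A list of class `"global_mechanics"`: `v_ed`, `v_es`, `dV`,
#'   `c_global`, `d_global`.
#' @export
global_mechanics <- function(geom_ed, geom_es, pulse_kpa) {
  stopifnot(pulse_kpa > 0)
  v_ed <- if (is.numeric(geom_ed)) geom_ed else closed_mesh_volume(geom_ed)
  v_es <- if (is.numeric(geom_es)) geom_es else closed_mesh_volume(geom_es)
  c_global <- (v_es - v_ed) / pulse_kpa
  structure(list(v_ed = v_ed, v_es = v_es, dV = v_es - v_ed,
                 c_global = c_global, d_global = c_global / v_ed),
            class = "global_mechanics")
}

#' @export
print.global_mechanics <- function(x, ...) {
  cat(sprintf("V_ED %.2f ml, V_ES %.2f ml, C_global %.3f ml/kPa, D_global %.1f x 10^-3 kPa^-1\n",
              x$v_ed, x$v_es, x$c_global, 1000 * x$d_global))
  invisible(x)
}

#' Exact two-sided rank-sum test (Mann--Whitney / Wilcoxon)
#'
#' Computes the two-sided p-value of the rank-sum statistic by full
#' enumeration of the group labellings (mid-ranks when ties are present, with
#' the tie flag set). When the number of labellings exceeds `max_enum` the
#' normal approximation with tie correction is used instead and flagged.
#'
#' @param group1,group2 Numeric vectors (each of length >= 2).
#' @param max_enum Enumeration cap on `choose(n1 + n2, n1)`.
#' @return A list of class `"rank_sum_test"`: `p`, `statistic` (rank sum of
#'   group 1), `ties`, `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(group1, group2, max_enum = 2e6) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("both groups need at least 2 values")
  x <- c(group1, group2)
  n1 <- length(group1); n <- length(x)
  rk <- rank(x)                       # mid-ranks under ties
  ties <- any(duplicated(x))
  w_obs <- sum(rk[seq_len(n1)])
  if (choose(n, n1) <= max_enum) {
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(rk[combs], nrow = n1))
    tol <- 1e-9
    p <- 2 * min(mean(ws <= w_obs + tol), mean(ws >= w_obs - tol))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(x)
    sig2 <- n1 * (n - n1) / 12 * ((n + 1) -
      sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (w_obs - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(p = min(p, 1), statistic = w_obs, ties = ties,
                 method = method), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("rank-sum test: W = %g, two-sided p = %.3g (%s%s)\n",
              x$statistic, x$p, x$method,
              if (x$ties) ", ties present" else ""))
  invisible(x)
}

#' Cohort mean and sample standard deviation
#'
#' @param values Per-subject scalars (>= 2).
#' @return Named vector `c(mean, sd)` with the n-1 sample SD.
#' @export
cohort_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}
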