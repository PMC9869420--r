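#' Rigid iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence with the least-squares rigid
#' alignment (SVD / Kabsch) for a fixed number of iterations or until the RMS
#' correspondence distance stops changing. Correspondence is single nearest
#' neighbour without outlier trimming. The RMS distance is non-increasing
#' across iterations.
#'
#' @param source n x 3 point cloud to move, mm.
#' @param target m x 3 reference point cloud, mm.
#' @param n_iter Iteration cap (default 30).
#' @param tol Stop when the RMS change falls below this, mm.
#' @param max_points Clouds larger than this are deterministically thinned
#'   (regular subsampling) before matching, to bound the cost of the
#'   brute-force nearest-neighbour search.
#' @return A list of class `"rigid_transform"` with `rotation` (3x3, det +1),
#'   `translation` (length 3), `rms` (final RMS distance) and `rms_trace`.
#' @export
icp_register <- function(source, target, n_iter = 30, tol = 1e-6,
                         max_points = 2000) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    stop("degenerate point cloud: need at least 3 points")
  if (qr(sweep(source, 2, colMeans(source)))$rank < 2 ||
      qr(sweep(target, 2, colMeans(target)))$rank < 2)
    stop("degenerate point cloud: points are collinear")
  thin <- function(p) {
    if (nrow(p) <= max_points) return(p)
    p[round(seq(1, nrow(p), length.out = max_points)), , drop = FALSE]
  }
  src0 <- thin(source); tgt <- thin(target)
  R_tot <- diag(3); t_tot <- c(0, 0, 0)
  src <- src0
  rms_trace <- numeric(0)
  prev_rms <- Inf
  for (it in seq_len(n_iter)) {
    nn <- nearest_neighbours(src, tgt)
    matched <- tgt[nn$idx, , drop = FALSE]
    rms <- sqrt(mean(nn$dist2))
    rms_trace <- c(rms_trace, rms)
    if (abs(prev_rms - rms) < tol) break
    prev_rms <- rms
    fit <- kabsch(src, matched)
    src <- sweep(src %*% t(fit$R), 2, fit$t, "+")
    R_tot <- fit$R %*% R_tot
    t_tot <- as.vector(fit$R %*% t_tot) + fit$t
  }
  structure(list(rotation = R_tot, translation = t_tot,
                 rms = rms_trace[length(rms_trace)], rms_trace = rms_trace),
            class = "rigid_transform")
}

nearest_neighbours <- function(a, b) {
  # chunked brute force: for each row of a, nearest row of b
  nb <- rowSums(b^2)
  idx <- integer(nrow(a)); d2 <- numeric(nrow(a))
  chunk <- max(1L, floor(2e6 / nrow(b)))
  for (st in seq(1, nrow(a), by = chunk)) {
    en <- min(st + chunk - 1, nrow(a))
    blk <- a[st:en, , drop = FALSE]
    D <- outer(rowSums(blk^2), nb, "+") - 2 * blk %*% t(b)
    j <- max.col(-D, ties.method = "first")
    idx[st:en] <- j
    d2[st:en] <- pmax(D[cbind(seq_len(nrow(blk)), j)], 0)
  }
  list(idx = idx, dist2 = d2)
}

# least-squares rigid transform mapping a onto b (paired points)
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.vector(cb - R %*% ca))
}

#' Apply a rigid transform to points
#' @param transform A `"rigid_transform"` from [icp_register()].
#' @param points n x 3 matrix, mm.
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(transform, points) {
  sweep(as.matrix(points) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("rigid transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm, final RMS %.4g mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3], x$rms))
  invisible(x)
}

#' Resample two geometries to matched equidistant slices
#'
#' Both geometries are cut into planar contours at equidistant stations along
#' the vessel-length axis (default `y`, spacing circa 0.2 mm), interpolating
#' matched-angle contour points linearly between the two bracketing contours
#' of each geometry. Only stations inside both geometries' extents are kept.
#'
#' @param geomA,geomB `"phase_geometry"` objects in a common (registered)
#'   coordinate frame.
#' @param spacing Slice spacing, mm.
#' @param axis Index of the length axis (1 = x, 2 = y, 3 = z); default 2.
#' @return A list of class `"slice_stack"`: `stations` (axis coordinates) and
#'   `A`, `B` (lists of planar contours, n_angles x 3, one per station).
#' @export
resample_slices <- function(geomA, geomB, spacing = 0.2, axis = 2) {
  levA <- contour_levels(geomA, axis)
  levB <- contour_levels(geomB, axis)
  lo <- max(min(levA$y), min(levB$y))
  hi <- min(max(levA$y), max(levB$y))
  if (hi <= lo) stop("registration failed or disjoint extents: no axis overlap")
  stations <- seq(lo, hi, by = spacing)
  list_A <- lapply(stations, slice_at, lev = levA, axis = axis)
  list_B <- lapply(stations, slice_at, lev = levB, axis = axis)
  structure(list(stations = stations, A = list_A, B = list_B, axis = axis,
                 spacing = spacing), class = "slice_stack")
}

# order a geometry's contours along the axis and drop non-monotone duplicates
contour_levels <- function(geom, axis) {
  y <- vapply(geom$contours, function(cc) mean(cc[, axis]), numeric(1))
  ord <- order(y)
  list(y = y[ord], contours = geom$contours[ord])
}

slice_at <- function(y0, lev, axis) {
  y <- lev$y
  i <- findInterval(y0, y, all.inside = TRUE)
  y1 <- y[i]; y2 <- y[i + 1]
  f <- if (y2 - y1 < 1e-12) 0 else (y0 - y1) / (y2 - y1)
  f <- min(max(f, 0), 1)
  cc <- (1 - f) * lev$contours[[i]] + f * lev$contours[[i + 1]]
  cc[, axis] <- y0
  cc
}

#' Similarity index (Dice coefficient) of two binary masks
#'
#' `SI = 2 |A intersect B| / (|A| + |B|)`: spatial overlap of the two pixel
#' sets, 1 for identical regions, 0 for disjoint ones.
#'
#' @param maskA,maskB Logical (or 0/1) matrices on the same grid.
#' @return The similarity index in `[0, 1]`.
#' @export
similarity_index <- function(maskA, maskB) {
  stopifnot(all(dim(maskA) == dim(maskB)))
  a <- sum(maskA != 0); b <- sum(maskB != 0)
  if (a + b == 0) stop("empty slice: both masks are empty")
  2 * sum(maskA != 0 & maskB != 0) / (a + b)
}

#' Hausdorff distance between two point sets
#'
#' `d(A,B) = max( max_a min_b |b - a|, max_b min_a |a - b| )`: the worst-case
#' boundary disagreement between two contours, mm.
#'
#' @param A,B Point matrices (n x d), same dimensionality.
#' @return The Hausdorff distance.
#' @export
hausdorff_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty point set")
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D2 <- pmax(D2, 0)
  max(sqrt(max(apply(D2, 1, min))), sqrt(max(apply(D2, 2, min))))
}

# rasterise a star-shaped planar slice contour into a mask on a given grid
slice_mask <- function(contour, axis, grid_u, grid_v) {
  keep <- setdiff(1:3, axis)
  u <- contour[, keep[1]]; v <- contour[, keep[2]]
  cu <- mean(u); cv <- mean(v)
  th <- atan2(v - cv, u - cu)
  ord <- order(th)
  th_s <- th[ord]
  rr <- sqrt((u - cu)^2 + (v - cv)^2)[ord]
  uu <- matrix(grid_u, length(grid_u), length(grid_v))
  vv <- matrix(grid_v, length(grid_u), length(grid_v), byrow = TRUE)
  pa <- atan2(vv - cv, uu - cu)
  pr <- sqrt((uu - cu)^2 + (vv - cv)^2)
  rb <- stats::approx(c(th_s - 2 * pi, th_s, th_s + 2 * pi), rep(rr, 3),
                      xout = as.vector(pa), rule = 2)$y
  matrix(as.vector(pr) <= rb, length(grid_u), length(grid_v))
}

#' Register and compare two geometries slice by slice
#'
#' Registers the first geometry onto the second with [icp_register()] (the
#' MAP-state geometry is the usual choice of input), resamples both to
#' matched equidistant slices along the vessel axis, rasterises each slice
#' pair on a shared pixel grid for the similarity index, computes the
#' per-slice Hausdorff distance on the contour points, and summarises with
#' medians and interquartile ranges (linear-interpolation quartiles).
#'
#' @param geomUS The sweep-derived `"phase_geometry"`.
#' @param geomRef The reference geometry (e.g. from CT), same class.
#' @param spacing Slice spacing, mm.
#' @param pixel_mm Rasterisation pixel size for the similarity index, mm.
#' @param axis Vessel-length axis (default 2, the y-direction).
#' @param register Set `FALSE` if the geometries are already aligned.
#' @return A list of class `"comparison_report"`: per-slice `si` and `hd`,
#'   `median_si`, `iqr_si`, `median_hd`, `iqr_hd`, and the `transform` used.
#' @export
compare_geometries <- function(geomUS, geomRef, spacing = 0.2, pixel_mm = 0.2,
                               axis = 2, register = TRUE) {
  tr <- NULL
  if (register) {
    src <- do.call(rbind, geomUS$contours)
    tgt <- do.call(rbind, geomRef$contours)
    tr <- icp_register(src, tgt)
    geomUS$contours <- lapply(geomUS$contours, function(cc) apply_rigid(tr, cc))
  }
  st <- resample_slices(geomUS, geomRef, spacing = spacing, axis = axis)
  keep <- setdiff(1:3, axis)
  si <- hd <- numeric(length(st$stations))
  for (i in seq_along(st$stations)) {
    a <- st$A[[i]]; b <- st$B[[i]]
    lims_u <- range(a[, keep[1]], b[, keep[1]]) + c(-2, 2) * pixel_mm
    lims_v <- range(a[, keep[2]], b[, keep[2]]) + c(-2, 2) * pixel_mm
    gu <- seq(lims_u[1], lims_u[2], by = pixel_mm)
    gv <- seq(lims_v[1], lims_v[2], by = pixel_mm)
    si[i] <- similarity_index(slice_mask(a, axis, gu, gv),
                              slice_mask(b, axis, gu, gv))
    hd[i] <- hausdorff_distance(a[, keep], b[, keep])
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q_si <- qs(si); q_hd <- qs(hd)
  structure(list(si = si, hd = hd, stations = st$stations,
                 median_si = q_si[2], iqr_si = q_si[c(1, 3)],
                 median_hd = q_hd[2], iqr_hd = q_hd[c(1, 3)],
                 transform = tr),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("geometry comparison over %d slices\n", length(x$si)))
  cat(sprintf("  similarity index: median %.3f [%.3f-%.3f]\n",
              x$median_si, x$iqr_si[1], x$iqr_si[2]))
  cat(sprintf("  Hausdorff distance: median %.2f [%.2f-%.2f] mm\n",
              x$median_hd, x$iqr_hd[1], x$iqr_hd[2]))
  invisible(x)
}
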