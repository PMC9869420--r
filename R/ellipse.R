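#' Ellipse constructor
#'
#' A 5-parameter ellipse describing the lumen--wall (or thrombus--wall)
#' interface in one cross-sectional frame. Coordinates and semi-axes are in
#' millimetres; the rotation is normalised to `[0, pi)` and the semi-axes are
#' ordered so that `a >= b`.
#'
#' @param cx,cy Centre, mm (image or in-plane coordinates).
#' @param a,b Semi-major and semi-minor axis, mm. Swapped internally if
#'   given in the wrong order.
#' @param phi Rotation of the major axis, radians.
#' @return An object of class `"us_ellipse"`: a list with fields
#'   `cx`, `cy`, `a`, `b`, `phi`.
#' @export
#' @examples
#' e <- ellipse(0, 0, 12, 8, 0.3)
#' ellipse_area(e)
ellipse <- function(cx, cy, a, b, phi = 0) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(a), is.finite(b),
            is.finite(phi))
  if (a < b) {
    tmp <- a; a <- b; b <- tmp
    phi <- phi + pi / 2
  }
  if (b <= 0) stop("ellipse semi-axes must be positive")
  phi <- phi %% pi
  structure(list(cx = cx, cy = cy, a = a, b = b, phi = phi),
            class = "us_ellipse")
}

#' @export
print.us_ellipse <- function(x, ...) {
  cat(sprintf(
    "ellipse: centre (%.3f, %.3f) mm, a = %.3f mm, b = %.3f mm, phi = %.4f rad\n",
    x$cx, x$cy, x$a, x$b, x$phi))
  invisible(x)
}

#' Ellipse area
#' @param e An ellipse from [ellipse()].
#' @return Area `pi * a * b`, mm^2.
#' @export
ellipse_area <- function(e) pi * e$a * e$b

#' Analytic ellipse perimeter
#'
#' Ramanujan's second approximation, accurate to well below 0.1% for the
#' aspect ratios seen in aortic cross-sections.
#'
#' @param e An ellipse from [ellipse()].
#' @return Circumference, mm.
#' @export
ellipse_perimeter <- function(e) {
  h <- ((e$a - e$b) / (e$a + e$b))^2
  pi * (e$a + e$b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Radius of an ellipse along a ray from its centre
#'
#' @param e An ellipse from [ellipse()].
#' @param theta Ray angles, radians (vectorised), measured in the frame's
#'   coordinate system.
#' @return Distances from the centre to the ellipse boundary along each ray, mm.
#' @export
ellipse_radius <- function(e, theta) {
  t_rel <- theta - e$phi
  e$a * e$b / sqrt((e$b * cos(t_rel))^2 + (e$a * sin(t_rel))^2)
}

#' Sample points on an ellipse boundary
#'
#' @param e An ellipse from [ellipse()].
#' @param theta Ray angles from the centre (default 64 equiangular rays).
#'   Points are taken where each ray meets the boundary, so matched angles
#'   across contours correspond geometrically.
#' @return A matrix with columns `x`, `y` (mm).
#' @export
ellipse_points <- function(e, theta = seq(0, 2 * pi, length.out = 65)[-65]) {
  r <- ellipse_radius(e, theta)
  cbind(x = e$cx + r * cos(theta), y = e$cy + r * sin(theta))
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse through a set of 2D points
#' (numerically stable partitioned formulation of the direct ellipse-specific
#' least-squares fit), then converts the conic to geometric parameters.
#' Points sampled exactly from an ellipse are recovered to machine precision.
#'
#' @param points A numeric matrix or data.frame with two columns (x, y), mm.
#'   At least 5 points in non-degenerate position are required.
#' @return An [ellipse()].
#' @export
#' @examples
#' e0 <- ellipse(3, -2, 20, 12, 0.4)
#' p <- ellipse_points(e0, seq(0, 2 * pi, length.out = 13)[-13])
#' fit_ellipse(p)
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2)
    stop("points must be a numeric matrix with two columns")
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 5)
    stop("insufficient edge support: at least 5 points are required")
  # centre/scale for conditioning
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx; y <- points[, 2] - my
  sc <- mean(sqrt(x^2 + y^2))
  if (sc < .Machine$double.eps)
    stop("insufficient edge support: degenerate point configuration")
  x <- x / sc; y <- y / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("insufficient edge support: degenerate point configuration"))
  M <- S1 + S2 %*% T1
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("insufficient edge support: no ellipse satisfies the fit")
  a1 <- evec[, ok[1]]
  a2 <- as.vector(T1 %*% a1)
  con <- c(a1, a2)  # A, B, C, D, E, F in scaled frame
  geo <- conic_to_ellipse(con)
  # undo scaling
  ellipse(geo$cx * sc + mx, geo$cy * sc + my, geo$a * sc, geo$b * sc, geo$phi)
}

# conic (A,B,C,D,E,F) with Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0 -> geometry
conic_to_ellipse <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # value of the quadratic form at the centre
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  m <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(m, symmetric = TRUE)
  lam <- ev$values           # decreasing
  axes2 <- -Fc / lam         # squared semi-axes per eigen direction
  if (any(axes2 <= 0)) stop("conic is not a real ellipse")
  # smaller eigenvalue -> larger axis
  a <- sqrt(axes2[2]); b <- sqrt(axes2[1])
  v <- ev$vectors[, 2]       # direction of the major axis
  phi <- atan2(v[2], v[1])
  ellipse(cx, cy, a, b, phi)
}

#' Rasterised ellipse area
#'
#' Pixel-centre counting on a grid centred on the ellipse, mirroring how lumen
#' areas are extracted from binary masks of the segmented contours. When the
#' minor semi-axis spans fewer than two pixels the rasterisation is
#' unreliable and the analytic area is returned with a warning.
#'
#' @param e An [ellipse()].
#' @param spacing Pixel spacing, mm/pixel.
#' @return Area, mm^2.
#' @export
ellipse_mask_area <- function(e, spacing) {
  stopifnot(spacing > 0)
  if (e$b < 2 * spacing) {
    warning("ellipse radius below 2 pixels at this spacing; using analytic area")
    return(ellipse_area(e))
  }
  half <- ceiling(e$a / spacing) + 1L
  g <- seq(-half, half) * spacing
  xs <- rep(g, times = length(g))
  ys <- rep(g, each = length(g))
  cphi <- cos(e$phi); sphi <- sin(e$phi)
  u <- (xs * cphi + ys * sphi) / e$a
  v <- (-xs * sphi + ys * cphi) / e$b
  # inclusive boundary with a tiny tolerance so lattice points exactly on the
  # contour are not dropped by floating-point rounding
  sum(u * u + v * v <= 1 + 1e-9) * spacing^2
}
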