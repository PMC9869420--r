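#' Lumen area--time signal from segmented contours
#'
#' Converts each segmented ellipse into a binary mask at the stated pixel
#' spacing and counts interior pixels, mirroring how lumen areas are extracted
#' from the binary masks of the contours. For radii of at least ten pixels the
#' count agrees with the analytic `pi*a*b` to within a couple of pixel areas.
#'
#' @param contours List of [ellipse()] objects, one per frame.
#' @param timestamps Frame timestamps, s (strictly increasing).
#' @param pixel_spacing Mask pixel spacing, mm/pixel (default 0.1 mm).
#' @return A data.frame of class `"area_time_signal"` with columns
#'   `frame`, `t`, `area` (mm^2).
#' @export
lumen_area_series <- function(contours, timestamps = NULL, pixel_spacing = 0.1) {
  stopifnot(length(contours) >= 1)
  if (is.null(timestamps)) timestamps <- seq_along(contours) - 1
  if (length(timestamps) != length(contours))
    stop("timestamps and contours lengths differ")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  area <- vapply(contours, ellipse_mask_area, numeric(1),
                 spacing = pixel_spacing)
  structure(data.frame(frame = seq_along(contours), t = timestamps,
                       area = area),
            class = c("area_time_signal", "data.frame"))
}

# resample a possibly non-equidistant signal to equidistant steps at the
# median sampling interval (linear interpolation)
resample_equidistant <- function(t, x) {
  dt <- stats::median(diff(t))
  tt <- seq(t[1], t[length(t)], by = dt)
  list(t = tt, x = stats::approx(t, x, xout = tt)$y, dt = dt)
}

#' Detect the heart-frequency range from an area--time signal
#'
#' Resamples the signal to equidistant time steps, removes the mean, and takes
#' the power-density spectrum (Hann-windowed periodogram). The heart frequency
#' is the highest spectral peak inside the physiological range; the returned
#' range spans +/- 0.2 Hz around it, allowing a +/- 12 beats/min drift over
#' the acquisition.
#'
#' @param signal An `area_time_signal` from [lumen_area_series()], or any
#'   data.frame with columns `t` and `area`.
#' @param physio_range Physiological frequency window, Hz
#'   (default 40--120 beats/min).
#' @return A list of class `"heart_frequency_range"` with `f_peak`, `f_low`,
#'   `f_high` (Hz) and `period_range` (s).
#' @export
detect_heart_frequency <- function(signal, physio_range = c(40, 120) / 60) {
  t <- signal$t; x <- signal$area
  if ((t[length(t)] - t[1]) < 2 / physio_range[1])
    stop("sweep too short: fewer than two cardiac cycles observable")
  rs <- resample_equidistant(t, x)
  x <- rs$x - mean(rs$x)
  n <- length(x)
  if (stats::sd(x) < 1e-12) stop("no cardiac signal: area signal is constant")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hann
  X <- stats::fft(x * w)
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * rs$dt)
  pow <- Mod(X[2:(nf + 1)])^2
  inb <- which(freq >= physio_range[1] & freq <= physio_range[2])
  if (length(inb) == 0) stop("no cardiac signal: no spectrum inside the physiological range")
  pk <- inb[which.max(pow[inb])]
  # require the in-band peak to stand above the overall noise floor
  if (pow[pk] < 5 * stats::median(pow))
    stop("no cardiac signal: no spectral peak above the noise floor")
  f_peak <- freq[pk]
  f_low <- max(f_peak - 0.2, 1e-6)
  f_high <- f_peak + 0.2
  structure(list(f_peak = f_peak, f_low = f_low, f_high = f_high,
                 period_range = c(1 / f_high, 1 / f_low)),
            class = "heart_frequency_range")
}

#' @export
print.heart_frequency_range <- function(x, ...) {
  cat(sprintf("heart frequency %.3f Hz (range %.3f-%.3f Hz, period %.3f-%.3f s)\n",
              x$f_peak, x$f_low, x$f_high, x$period_range[1], x$period_range[2]))
  invisible(x)
}

# local minima of x with minimum index separation min_sep and prominence
# >= prom, greedily keeping the deepest minima first
local_minima <- function(x, min_sep, prom = 0) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  # boundary samples count as minima when strictly below their neighbour
  if (n >= 2 && x[1] < x[2]) cand <- c(1L, cand)
  if (n >= 2 && x[n] < x[n - 1]) cand <- c(cand, n)
  if (prom > 0 && length(cand) > 0)
    cand <- cand[max(x) - x[cand] >= prom]
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(x[cand])]
  kept <- integer(0)
  for (i in ord)
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

#' Detect end-diastolic frames
#'
#' Finds the local minima of the equidistantly resampled area--time signal,
#' constrained so that consecutive minima are separated by at least the
#' minimal period of the detected heart-frequency range, then maps each
#' minimum back to the nearest original frame. End diastole is the phase of
#' smallest lumen calibre, so these frames carry the ED contours.
#'
#' @param signal An `area_time_signal` (columns `frame`, `t`, `area`).
#' @param hf A [detect_heart_frequency()] result.
#' @param prominence_frac Minima must dip at least this fraction of the
#'   signal's peak-to-peak range below the maximum (noise rejection).
#' @return Strictly increasing original frame indices.
#' @export
detect_ed_frames <- function(signal, hf, prominence_frac = 0.1) {
  stopifnot(inherits(hf, "heart_frequency_range"))
  rs <- resample_equidistant(signal$t, signal$area)
  min_sep <- (1 / hf$f_high) / rs$dt
  prom <- prominence_frac * diff(range(rs$x))
  idx <- local_minima(rs$x, min_sep, prom)
  if (length(idx) < 2) stop("sweep too short: fewer than two end-diastolic minima found")
  tmins <- rs$t[idx]
  frames <- vapply(tmins, function(tt) signal$frame[which.min(abs(signal$t - tt))],
                   signal$frame[1])
  unique(frames)
}
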