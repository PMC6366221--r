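# Preprocessing chain applied to every spectrum before stress indexes are
# computed: quality test (signal-to-noise), rubberband baseline correction,
# vector normalization. Atmospheric CO2/water-vapour compensation is a
# deliberate no-op stage: it is instrument-software specific and synthetic
# spectra contain no atmospheric bands.

# Lower convex hull of (x, y) with x strictly ascending (monotone chain).
# Returns indices of hull vertices, always including both end points.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  idx <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- idx[k - 1L]; a <- idx[k]
      # pop while the turn o -> a -> i is clockwise or collinear
      if ((x[a] - x[o]) * (y[i] - y[o]) -
          (y[a] - y[o]) * (x[i] - x[o]) <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    idx[k] <- i
  }
  idx[seq_len(k)]
}

# Reduce a hull vertex chain to at most n_points vertices, keeping both end
# points. Interior vertices are removed greedily by smallest added area
# (area of the triangle closed by skipping the vertex), so the reduced
# baseline stays as close as possible to the full hull.
reduce_hull_vertices <- function(x, y, idx, n_points) {
  while (length(idx) > n_points) {
    m <- length(idx)
    xi <- x[idx]; yi <- y[idx]
    area <- abs((xi[2:(m - 1)] - xi[1:(m - 2)]) * (yi[3:m] - yi[1:(m - 2)]) -
                (yi[2:(m - 1)] - yi[1:(m - 2)]) * (xi[3:m] - xi[1:(m - 2)])) / 2
    idx <- idx[-(which.min(area) + 1L)]
  }
  idx
}

#' Rubberband baseline correction
#'
#' Subtracts the lower convex hull of the spectrum ("stretched rubber
#' band"), evaluated by linear interpolation between hull vertices. The
#' number of baseline support points is limited to `n_points` in the
#' instrument-software convention; whenever the hull has no more than
#' `n_points` vertices (the usual case for smooth biological spectra) the
#' result is the exact lower convex hull, and the corrected spectrum is
#' non-negative and touches zero in at least two points.
#'
#' @param s An [ftir_spectrum()] with at least 3 points.
#' @param n_points Maximum number of baseline support points (default 64).
#' @return A list with elements `baseline` and `corrected`, both
#'   [ftir_spectrum()] objects on the grid of `s`.
#' @export
rubberband_baseline <- function(s, n_points = 64L) {
  stopifnot(inherits(s, "ftir_spectrum"))
  n <- length(s$wavenumbers)
  if (n < 3L) stop("rubberband baseline needs at least 3 points", call. = FALSE)
  # work on ascending x
  x <- rev(s$wavenumbers); y <- rev(s$intensities)
  idx <- lower_hull_indices(x, y)
  if (length(idx) > n_points) idx <- reduce_hull_vertices(x, y, idx, n_points)
  bl <- stats::approx(x[idx], y[idx], xout = x, method = "linear",
                      ties = "ordered")$y
  mk <- function(v) ftir_spectrum(s$wavenumbers, rev(v), strain = s$strain,
                                  condition = s$condition,
                                  replicate = s$replicate)
  list(baseline = mk(bl), corrected = mk(y - bl))
}

#' Vector normalization
#'
#' Mean-centres the intensities and scales them to unit Euclidean norm
#' (the common instrument-software meaning of "vector normalization");
#' `method = "l2"` skips the centring and applies plain unit-norm scaling.
#'
#' @param s An [ftir_spectrum()].
#' @param method `"center"` (default) or `"l2"`.
#' @return An [ftir_spectrum()] with mean 0 (for `"center"`) and Euclidean
#'   norm 1.
#' @export
vector_normalize <- function(s, method = c("center", "l2")) {
  stopifnot(inherits(s, "ftir_spectrum"))
  method <- match.arg(method)
  y <- s$intensities
  if (method == "center") y <- y - mean(y)
  nrm <- sqrt(sum(y^2))
  if (nrm < .Machine$double.eps * length(y))
    stop("zero variance spectrum", call. = FALSE)
  ftir_spectrum(s$wavenumbers, y / nrm, strain = s$strain,
                condition = s$condition, replicate = s$replicate)
}

#' Spectral signal-to-noise ratio
#'
#' SNR is the full-spectrum peak-to-peak signal divided by the RMS residual
#' after linear detrending of the intensities inside a band-free noise
#' window (2100-1900 cm^-1 by default). A noise-free window returns `Inf`,
#' which passes any finite threshold.
#'
#' @param s An [ftir_spectrum()].
#' @param noise_window Length-2 wavenumber interval used to estimate noise.
#' @return A scalar SNR (possibly `Inf`).
#' @export
quality_snr <- function(s, noise_window = c(1900, 2100)) {
  stopifnot(inherits(s, "ftir_spectrum"))
  lo <- min(noise_window); hi <- max(noise_window)
  inw <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (sum(inw) < 8L)
    stop("noise window not covered by spectrum (need >= 8 points)",
         call. = FALSE)
  x <- s$wavenumbers[inw]; y <- s$intensities[inw]
  res <- stats::lm.fit(cbind(1, x), y)$residuals
  rms <- sqrt(mean(res^2))
  ptp <- diff(range(s$intensities))
  if (rms <= .Machine$double.eps * max(1, ptp)) return(Inf)
  ptp / rms
}

#' Preprocess one spectrum
#'
#' Applies the full chain: rubberband baseline correction then vector
#' normalization. The signal-to-noise quality test is applied separately at
#' the set level (see [preprocess_set()]) so failing spectra can be
#' excluded rather than aborting.
#'
#' @param s An [ftir_spectrum()].
#' @param n_points Rubberband support points, see [rubberband_baseline()].
#' @param normalize Normalization method, see [vector_normalize()].
#' @return A preprocessed [ftir_spectrum()].
#' @export
preprocess_spectrum <- function(s, n_points = 64L,
                                normalize = c("center", "l2")) {
  vector_normalize(rubberband_baseline(s, n_points = n_points)$corrected,
                   method = match.arg(normalize))
}

#' Preprocess a spectrum set with quality control
#'
#' Runs [quality_snr()] on every raw spectrum, excludes (with a warning)
#' those below `snr_threshold`, and preprocesses the rest.
#'
#' @param set An [ftir_set()].
#' @param snr_threshold Minimum acceptable SNR (default 4000).
#' @param noise_window Noise window passed to [quality_snr()].
#' @param n_points,normalize Passed to [preprocess_spectrum()].
#' @return A list with `set` (the preprocessed [ftir_set()]), `snr`
#'   (numeric vector of per-spectrum SNR values) and `excluded`
#'   (manifest rows of excluded spectra).
#' @export
preprocess_set <- function(set, snr_threshold = 4000,
                           noise_window = c(1900, 2100), n_points = 64L,
                           normalize = "center") {
  stopifnot(inherits(set, "ftir_set"))
  snr <- vapply(set$spectra, quality_snr, numeric(1),
                noise_window = noise_window)
  keep <- snr >= snr_threshold
  man <- set_manifest(set)
  man$snr <- snr
  if (!all(keep)) {
    warning(sprintf("%d spectra excluded by the SNR quality test (< %g)",
                    sum(!keep), snr_threshold), call. = FALSE)
  }
  if (!any(keep)) stop("all spectra failed the quality test", call. = FALSE)
  proc <- lapply(set$spectra[keep], preprocess_spectrum,
                 n_points = n_points, normalize = normalize)
  list(set = ftir_set(proc, grid = set$grid), snr = snr,
       excluded = man[!keep, , drop = FALSE])
}
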