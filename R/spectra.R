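# 1 nm = 1e6 fm
.fm_per_nm <- 1e6

#' Construct a sweep spectrum
#'
#' @param wavelength_nm Strictly increasing, uniform wavelength grid (nm).
#' @param transmission Dimensionless transmission (baseline near 1 with a dip).
#' @return A data frame of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, transmission) {
  stopifnot(length(wavelength_nm) == length(transmission))
  if (length(wavelength_nm) < 16L)
    stop_param("a spectrum needs at least 16 samples")
  d <- diff(wavelength_nm)
  if (any(d <= 0) || max(d) - min(d) > 1e-6 * max(d))
    stop_param("wavelength grid must be strictly increasing and uniform")
  if (any(!is.finite(transmission)))
    stop_param("transmission must be finite")
  structure(data.frame(wavelength_nm = wavelength_nm,
                       transmission = transmission),
            class = c("spectrum", "data.frame"))
}

#' Lorentzian transmission dip model
#'
#' Renders `T(lambda) = 1 - depth * (kappa/2)^2 / ((lambda - lambda0)^2 +
#' (kappa/2)^2)` on a wavelength grid. `T(lambda0) = 1 - depth` and the dip
#' reaches half depth at `lambda0 +/- kappa/2`.
#'
#' @param lambda0 Resonance wavelength (nm).
#' @param kappa Full width at half maximum of the dip (fm).
#' @param depth On-resonance dip depth, in (0, 1].
#' @param grid Wavelength grid (nm).
#' @return A [spectrum()].
#' @export
#' @examples
#' g <- seq(780 - 2e-3, 780 + 2e-3, length.out = 201)
#' s <- lorentzian_model(780, kappa = 400, depth = 0.8, grid = g)
lorentzian_model <- function(lambda0, kappa, depth, grid) {
  check_positive(lambda0, "lambda0")
  check_positive(kappa, "kappa")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0 || depth > 1)
    stop_param("`depth` must be in (0, 1]")
  hw <- (kappa / .fm_per_nm) / 2    # half width in nm
  tr <- 1 - depth * hw^2 / ((grid - lambda0)^2 + hw^2)
  spectrum(grid, tr)
}

# Numerical FWHM of the dip 1 - T by linear interpolation at half depth.
# Returns NA when either half-depth crossing is missing.
numerical_fwhm_nm <- function(wavelength_nm, dip) {
  imax <- which.max(dip)
  half <- dip[imax] / 2
  left <- NA_real_
  right <- NA_real_
  if (imax > 1L) {
    below <- which(dip[seq_len(imax - 1L)] < half)
    if (length(below)) {
      i <- max(below)
      left <- wavelength_nm[i] + (half - dip[i]) *
        (wavelength_nm[i + 1L] - wavelength_nm[i]) / (dip[i + 1L] - dip[i])
    }
  }
  if (imax < length(dip)) {
    below <- which(dip > half)
    i <- max(below)
    if (i < length(dip)) {
      right <- wavelength_nm[i] + (half - dip[i]) *
        (wavelength_nm[i + 1L] - wavelength_nm[i]) / (dip[i + 1L] - dip[i])
    }
  }
  right - left
}

#' Centroid estimate of the resonance position
#'
#' Intensity-weighted centroid of the dip `1 - T`, restricted to grid points
#' where the dip exceeds `threshold_fraction` times its maximum. Thresholding
#' suppresses baseline noise far from the resonance.
#'
#' @param s A [spectrum()].
#' @param threshold_fraction Fraction of the maximum dip depth a point must
#'   exceed to enter the centroid (default 0.5, a half-depth centroid).
#' @return Centroid wavelength (nm).
#' @export
centroid_position <- function(s, threshold_fraction = 0.5) {
  if (!inherits(s, "spectrum")) stop_param("`s` must be a `spectrum`")
  check_fraction(threshold_fraction, "threshold_fraction")
  dip <- 1 - s$transmission
  m <- max(dip)
  if (m <= 0) stop_param("no dip in spectrum: nothing passes the threshold")
  keep <- dip >= threshold_fraction * m
  if (!any(keep)) stop_param("no point passes the centroid threshold")
  sum(s$wavelength_nm[keep] * dip[keep]) / sum(dip[keep])
}

#' Fit a Lorentzian dip to a spectrum
#'
#' Nonlinear least squares of [lorentzian_model()], initialized from the
#' centroid position, the numerical half width and the observed dip depth.
#' On non-convergence the initializer values are returned with
#' `converged = FALSE`.
#'
#' @param s A [spectrum()].
#' @return A list of class `lorentzian_fit` with elements `lambda0_nm`,
#'   `kappa_fm`, `depth`, `se` (named standard errors: `lambda0_fm`,
#'   `kappa_fm`, `depth`) and `converged`.
#' @export
#' @examples
#' g <- seq(780 - 2e-3, 780 + 2e-3, length.out = 201)
#' f <- fit_lorentzian(lorentzian_model(780, 400, 0.8, g))
#' f$kappa_fm
fit_lorentzian <- function(s) {
  if (!inherits(s, "spectrum")) stop_param("`s` must be a `spectrum`")
  dip <- 1 - s$transmission
  depth0 <- max(dip)
  if (depth0 <= 0) stop_param("no dip in spectrum")
  l0 <- centroid_position(s, 0.5)
  w0 <- numerical_fwhm_nm(s$wavelength_nm, dip)
  if (!is.finite(w0) || w0 <= 0)
    w0 <- diff(range(s$wavelength_nm)) / 10
  dat <- data.frame(wl = s$wavelength_nm, tr = s$transmission)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      tr ~ 1 - depth * (hw^2) / ((wl - l0f)^2 + hw^2),
      data = dat,
      start = list(depth = min(depth0, 1), hw = w0 / 2, l0f = l0),
      lower = c(depth = 0, hw = .Machine$double.eps, l0f = min(dat$wl)),
      upper = c(depth = 1.5, hw = diff(range(dat$wl)), l0f = max(dat$wl)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(lambda0_nm = l0, kappa_fm = w0 * .fm_per_nm,
                          depth = depth0,
                          se = c(lambda0_fm = NA_real_, kappa_fm = NA_real_,
                                 depth = NA_real_),
                          converged = FALSE),
                     class = "lorentzian_fit"))
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(lambda0_nm = unname(cf["l0f"]),
                 kappa_fm = unname(cf["hw"]) * 2 * .fm_per_nm,
                 depth = unname(cf["depth"]),
                 se = c(lambda0_fm = unname(se["l0f"]) * .fm_per_nm,
                        kappa_fm = unname(se["hw"]) * 2 * .fm_per_nm,
                        depth = unname(se["depth"])),
                 converged = TRUE),
            class = "lorentzian_fit")
}

#' Track resonance position (and linewidth) across a series of spectra
#'
#' Estimates the per-frame resonance position by centroid or Lorentzian
#' fitting and returns the shift relative to the first frame, in fm. Frames
#' without a discernible dip are marked as gaps and linearly interpolated when
#' at most `max_gap` consecutive frames are missing.
#'
#' @param spectra List of [spectrum()] objects sharing one wavelength grid.
#' @param method `"centroid"` (default) or `"lorentzian"`; the Lorentzian
#'   method also reports the per-frame FWHM.
#' @param threshold_fraction Centroid threshold, see [centroid_position()].
#' @param frame_interval Time between frames (s).
#' @param min_depth Minimum dip depth below which a frame is declared a gap.
#' @param max_gap Maximum number of consecutive gap frames interpolated over.
#' @return A [resonance_trace()]; `dlambda_fm` is zero at the first frame.
#' @export
track <- function(spectra, method = c("centroid", "lorentzian"),
                  threshold_fraction = 0.5, frame_interval = 0.02,
                  min_depth = 0.05, max_gap = 2) {
  method <- match.arg(method)
  if (!length(spectra)) stop_param("`spectra` must be a non-empty list")
  grid <- spectra[[1L]]$wavelength_nm
  for (s in spectra) {
    if (!inherits(s, "spectrum")) stop_param("all frames must be `spectrum`s")
    if (length(s$wavelength_nm) != length(grid) ||
        max(abs(s$wavelength_nm - grid)) > 1e-9)
      stop_param("all frames must share one wavelength grid")
  }
  n <- length(spectra)
  pos <- rep(NA_real_, n)
  fw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dip <- 1 - spectra[[i]]$transmission
    if (max(dip) < min_depth) next  # gap
    if (method == "centroid") {
      pos[i] <- tryCatch(centroid_position(spectra[[i]], threshold_fraction),
                         error = function(e) NA_real_)
    } else {
      f <- fit_lorentzian(spectra[[i]])
      pos[i] <- f$lambda0_nm
      fw[i] <- f$kappa_fm
    }
  }
  pos <- fill_gaps(pos, max_gap)
  if (method == "lorentzian") fw <- fill_gaps(fw, max_gap)
  time <- (seq_len(n) - 1L) * frame_interval
  resonance_trace(time, (pos - pos[1L]) * .fm_per_nm,
                  fwhm_fm = if (method == "lorentzian") fw else NULL)
}

# Linear interpolation over interior NA runs of length <= max_gap; errors on
# longer runs or NA at either end.
fill_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(x)
  if (is.na(x[1L]) || is.na(x[length(x)]))
    stop_param("trace starts or ends in a gap; cannot interpolate")
  r <- rle(is.na(x))
  if (any(r$values & r$lengths > max_gap))
    stop_param(sprintf("gap longer than %d consecutive frames", max_gap))
  idx <- seq_along(x)
  ok <- !is.na(x)
  approx(idx[ok], x[ok], xout = idx)$y
}
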