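# Temporal preprocessing of ROI time series: framewise displacement,
# censoring with interpolation, detrending, nuisance regression, band-pass.

#' Compute framewise displacement from rigid-body motion parameters
#'
#' FD at frame t is the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius_mm` times the sum of absolute
#' backward differences of the three rotations (radians converted to arc
#' length on a sphere of that radius). The first frame has FD 0. The default
#' 50 mm radius is the human convention; 30 mm is a reasonable canine value
#' for a Labrador-sized head.
#'
#' @param motion a [motion_trace()].
#' @param head_radius_mm rotation-to-arc conversion radius (mm).
#' @param threshold_mm censoring threshold carried on the result.
#' @return An [fd_series()].
#' @export
compute_fd <- function(motion, head_radius_mm = 50, threshold_mm = 0.2) {
  stopifnot(inherits(motion, "motion_trace"), nrow(motion$translations) >= 2,
            head_radius_mm > 0)
  dt <- abs(diff(motion$translations))
  dr <- abs(diff(motion$rotations))
  fd <- c(0, rowSums(dt) + head_radius_mm * rowSums(dr))
  fd_series(fd, threshold_mm)
}

#' Censor high-motion frames and interpolate their samples
#'
#' Frames whose FD exceeds the threshold are marked FALSE in the censor mask
#' and their samples replaced by linear interpolation between the nearest
#' retained neighbours (edge frames held constant), so that filtering sees a
#' complete series. The mask is carried forward so that correlations can
#' exclude the interpolated frames again.
#'
#' @param ts a [roi_timeseries()].
#' @param fd an [fd_series()] of matching length.
#' @return The censored-and-interpolated [roi_timeseries()].
#' @export
censor_and_interpolate <- function(ts, fd) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(fd, "fd_series"),
            length(fd$fd) == nrow(ts$samples))
  keep <- fd$fd <= fd$threshold_mm
  if (mean(!keep) > 0.5) {
    stop("censor_and_interpolate: more than 50% of frames exceed the FD ",
         "threshold; run rejected as unusable")
  }
  samples <- ts$samples
  if (any(!keep)) {
    t_idx <- seq_len(nrow(samples))
    for (col in seq_len(ncol(samples))) {
      samples[!keep, col] <- approx(t_idx[keep], samples[keep, col],
                                    xout = t_idx[!keep], rule = 2)$y
    }
  }
  roi_timeseries(samples, ts$region_labels, ts$tr_seconds,
                 censor_mask = ts$censor_mask & keep)
}

#' Remove the linear trend from every region's series
#'
#' Least-squares projection onto the orthogonal complement of \{1, t\}.
#'
#' @param ts a [roi_timeseries()].
#' @return The detrended [roi_timeseries()].
#' @export
detrend <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  T_ <- nrow(ts$samples)
  D <- cbind(1, seq_len(T_))
  res <- ts$samples - D %*% qr.coef(qr(D), ts$samples)
  roi_timeseries(res, ts$region_labels, ts$tr_seconds, ts$censor_mask)
}

#' Regress nuisance signals out of every region's series
#'
#' Returns the least-squares residuals after projecting out the confound
#' columns (an intercept is always added), leaving residuals orthogonal to
#' every confound. Rank-deficient confound sets are handled by the
#' pivoted-QR pseudo-inverse with a warning.
#'
#' @param ts a [roi_timeseries()].
#' @param confounds numeric T x K matrix of nuisance regressors.
#' @return The residual [roi_timeseries()].
#' @export
regress_nuisance <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  confounds <- as.matrix(confounds)
  stopifnot(nrow(confounds) == nrow(ts$samples))
  if (!all(is.finite(confounds))) stop("regress_nuisance: non-finite confounds")
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("regress_nuisance: rank-deficient confounds; using pseudo-inverse")
  }
  beta <- qr.coef(qx, ts$samples)
  beta[is.na(beta)] <- 0
  res <- ts$samples - X %*% beta
  roi_timeseries(res, ts$region_labels, ts$tr_seconds, ts$censor_mask)
}

# Orthonormal basis of the in-band Fourier bins with the linear-trend
# direction removed: an exact orthogonal projection, so applying the filter
# twice is a no-op and out-of-band bin-aligned components are zeroed exactly.
# Cached per (T, tr, low, high).
bandpass_basis_cache <- new.env(parent = emptyenv())

bandpass_basis <- function(T_, tr_seconds, low_hz, high_hz) {
  key <- paste(T_, tr_seconds, low_hz, high_hz, sep = "|")
  hit <- bandpass_basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  freqs <- seq_len(floor(T_ / 2)) / (T_ * tr_seconds)
  ks <- which(freqs >= low_hz - 1e-12 & freqs <= high_hz + 1e-12)
  if (!length(ks)) stop("detrend_bandpass: no Fourier bins inside the band")
  t0 <- seq_len(T_) - 1
  cols <- lapply(ks, function(k) {
    ang <- 2 * pi * k * t0 / T_
    if (2 * k == T_) cbind(cos(ang)) else cbind(cos(ang), sin(ang))
  })
  C <- do.call(cbind, cols)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  # Remove the component of the (centered) time index inside the passband.
  tt <- t0 - mean(t0)
  v <- drop(crossprod(C, tt))
  nv <- sqrt(sum(v^2))
  Q <- if (nv > 1e-12) {
    v <- v / nv
    qr.Q(qr(C - (C %*% v) %*% t(v)))[, seq_len(ncol(C) - 1), drop = FALSE]
  } else C
  bandpass_basis_cache[[key]] <- Q
  Q
}

#' Detrend and ideal band-pass filter
#'
#' Projects every region's series onto the span of the Fourier bins whose
#' frequency lies in `[low_hz, high_hz]`, with the linear-trend direction
#' removed from the passband (an ideal rectangular filter realised as an
#' exact orthogonal projection). The output therefore has zero mean and no
#' linear trend, bin-aligned out-of-band sinusoids are annihilated exactly,
#' and applying the filter twice changes nothing. A Butterworth alternative
#' (forward-backward, via the `signal` package) is available for users who
#' prefer a smooth transition band.
#'
#' @param ts a [roi_timeseries()].
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param filter `"ideal"` (default) or `"butterworth"`.
#' @param order Butterworth order (ignored for the ideal filter).
#' @return The filtered [roi_timeseries()].
#' @export
detrend_bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1,
                             filter = c("ideal", "butterworth"), order = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  filter <- match.arg(filter)
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop("detrend_bandpass: band must satisfy 0 < low < high < Nyquist")
  }
  if (filter == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("the Butterworth option requires the 'signal' package")
    }
    dts <- detrend(ts)
    bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
    out <- apply(dts$samples, 2, function(y) signal::filtfilt(bf, y))
    return(roi_timeseries(out, ts$region_labels, ts$tr_seconds, ts$censor_mask))
  }
  Q <- bandpass_basis(nrow(ts$samples), ts$tr_seconds, low_hz, high_hz)
  out <- Q %*% crossprod(Q, ts$samples)
  roi_timeseries(out, ts$region_labels, ts$tr_seconds, ts$censor_mask)
}

#' Full temporal preprocessing chain for one run
#'
#' Order: FD computation, censoring with interpolation, detrending, nuisance
#' regression (the six motion parameters, detrended and band-limited with
#' the same projection so the chain is an exact projection overall), ideal
#' band-pass. Censored frames stay flagged in the censor mask for the
#' correlation stage.
#'
#' @param ts a [roi_timeseries()].
#' @param motion the paired [motion_trace()]; NULL skips FD censoring and
#'   motion regression.
#' @param fd_threshold_mm censoring threshold (mm).
#' @param head_radius_mm rotation-to-arc radius (mm).
#' @param band two-element passband in Hz.
#' @param filter filter kind, see [detrend_bandpass()].
#' @param extra_confounds optional additional T x K nuisance matrix (e.g.
#'   tissue signals), filtered like the motion parameters.
#' @return The preprocessed [roi_timeseries()].
#' @export
preprocess_run <- function(ts, motion = NULL, fd_threshold_mm = 0.2,
                           head_radius_mm = 50, band = c(0.01, 0.1),
                           filter = "ideal", extra_confounds = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  confounds <- NULL
  if (!is.null(motion)) {
    fd <- compute_fd(motion, head_radius_mm, fd_threshold_mm)
    ts <- censor_and_interpolate(ts, fd)
    confounds <- cbind(motion$translations, motion$rotations)
  }
  if (!is.null(extra_confounds)) confounds <- cbind(confounds, extra_confounds)
  ts <- detrend(ts)
  if (!is.null(confounds)) {
    Q <- bandpass_basis(nrow(ts$samples), ts$tr_seconds, band[1], band[2])
    filt_conf <- Q %*% crossprod(Q, unname(as.matrix(confounds)))
    ts <- regress_nuisance(ts, filt_conf)
  }
  detrend_bandpass(ts, band[1], band[2], filter = filter)
}
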