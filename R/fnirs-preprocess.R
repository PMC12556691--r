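#' Partial pathlength factor
#'
#' Scaling applied in the modified Beer-Lambert conversion: the
#' differential pathlength factor divided by the partial volume correction.
#' With the defaults (DPF = 6, PVC = 60) the factor is 0.1.
#'
#' @param dpf Differential pathlength factor.
#' @param pvc Partial volume correction (> 0).
#' @return `dpf / pvc`.
#' @export
partial_pathlength_factor <- function(dpf = 6, pvc = 60) {
  if (pvc == 0) stop("`pvc` must be non-zero", call. = FALSE)
  if (pvc < 0) stop("`pvc` must be positive", call. = FALSE)
  dpf / pvc
}

#' @rdname partial_pathlength_factor
#' @return `ppf_params()` returns a list with `dpf`, `pvc` and `ppf`.
#' @export
ppf_params <- function(dpf = 6, pvc = 60) {
  structure(
    list(dpf = dpf, pvc = pvc, ppf = partial_pathlength_factor(dpf, pvc)),
    class = "ppf_params"
  )
}

# natural-log extinction matrix (2 wavelengths x 2 chromophores),
# cm^-1 per (mol/L); decadic table entries scaled by ln 10
extinction_matrix_ln <- function() {
  ext <- extinction_coefficients()
  ext <- ext[order(ext$wavelength_nm), ]
  m <- log(10) * as.matrix(ext[c("hbo", "hbr")])
  rownames(m) <- as.character(ext$wavelength_nm)
  if (abs(det(m)) < 1e-12) {
    stop("extinction coefficient matrix is singular", call. = FALSE)
  }
  m
}

#' Modified Beer-Lambert conversions
#'
#' `haemo_to_od()` is the forward relation used by the simulator: given
#' HbO/HbR concentration changes (micromolar), it returns natural-log
#' optical density changes at 760 and 850 nm,
#' `OD_lambda = eps_lambda,HbO * C_HbO * L + eps_lambda,HbR * C_HbR * L`
#' with effective path `L = distance * ppf`. `od_to_haemo()` inverts the
#' 2x2 system per time point; the two are exact mutual inverses.
#'
#' @param chbo,chbr Concentration-change time series in micromolar.
#' @param od760,od850 Optical-density time series (natural log).
#' @param distance_mm Source-detector distance in mm.
#' @param ppf Partial pathlength factor (scalar or [ppf_params()]).
#' @return `haemo_to_od()`: list `od760`, `od850`; `od_to_haemo()`: list
#'   `hbo`, `hbr` (micromolar).
#' @export
haemo_to_od <- function(chbo, chbr, distance_mm, ppf = ppf_params()) {
  if (inherits(ppf, "ppf_params")) ppf <- ppf$ppf
  E <- extinction_matrix_ln()
  L <- (distance_mm / 10) * ppf # cm
  conc_molar <- rbind(chbo, chbr) * 1e-6
  od <- (E %*% conc_molar) * L
  list(od760 = as.numeric(od[1, ]), od850 = as.numeric(od[2, ]))
}

#' @rdname haemo_to_od
#' @export
od_to_haemo <- function(od760, od850, distance_mm, ppf = ppf_params()) {
  if (inherits(ppf, "ppf_params")) ppf <- ppf$ppf
  if (length(od760) != length(od850)) {
    stop("both wavelengths must have the same length", call. = FALSE)
  }
  E <- extinction_matrix_ln()
  L <- (distance_mm / 10) * ppf
  conc_molar <- solve(E, rbind(od760, od850)) / L
  list(
    hbo = as.numeric(conc_molar[1, ]) * 1e6,
    hbr = as.numeric(conc_molar[2, ]) * 1e6
  )
}

#' Convert raw intensities to optical density
#'
#' `OD(t) = -ln(I(t) / mean_t I)` per channel/wavelength column, using the
#' whole-recording mean intensity as the baseline.
#'
#' @param intensity Matrix (time x channel-wavelength columns) of strictly
#'   positive intensities, or a `fnirs_recording`.
#' @return Matrix of the same shape.
#' @export
intensity_to_od <- function(intensity) {
  if (inherits(intensity, "fnirs_recording")) intensity <- intensity$intensity
  intensity <- as.matrix(intensity)
  bad <- colSums(intensity <= 0) > 0
  if (any(bad)) {
    stop(
      "non-positive intensity in channel(s): ",
      paste(colnames(intensity)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  -log(sweep(intensity, 2, colMeans(intensity), "/"))
}

#' Scalp coupling index
#'
#' Pearson correlation between a channel's two wavelengths after band-pass
#' filtering to the cardiac band (0.7-1.5 Hz; the upper edge is clipped
#' just below the Nyquist frequency when the sampling rate is too low to
#' cover it). High values indicate good optode-scalp contact. Reported as
#' a quality measure only — no channels are excluded by default.
#'
#' @param rec A `fnirs_recording` (or list with `intensity`, `channels`,
#'   `sampling_rate`).
#' @param band Cardiac band in Hz.
#' @return Tibble with `channel` and `sci` in `[-1, 1]`.
#' @export
scalp_coupling_index <- function(rec, band = c(0.7, 1.5)) {
  n_time <- nrow(rec$intensity)
  if (n_time / rec$sampling_rate < 30) {
    stop("recording must be at least 30 s long for the SCI", call. = FALSE)
  }
  nyq <- rec$sampling_rate / 2
  hi <- min(band[2], 0.98 * nyq)
  lo <- min(band[1], 0.8 * hi)
  bf <- signal::butter(3, c(lo, hi) / nyq, type = "pass")
  od <- intensity_to_od(rec$intensity)
  purrr::map_dfr(rec$channels$channel, function(ch) {
    x <- signal::filtfilt(bf, od[, paste0(ch, "_760")])
    y <- signal::filtfilt(bf, od[, paste0(ch, "_850")])
    sci <- if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14) {
      NA_real_ # no cardiac-band signal at all (e.g. a silent channel)
    } else {
      stats::cor(x, y)
    }
    tibble::tibble(channel = ch, sci = sci)
  })
}

#' Temporal derivative distribution repair
#'
#' Robust motion-artifact correction. Each signal is split into a
#' low-frequency baseline and a residual; the residual's temporal
#' derivative is iteratively re-weighted with Tukey's biweight (tuning
#' constant 4.685 times a MAD-based robust SD) until the weights converge,
#' re-integrated, and recombined with the baseline. The baseline is
#' estimated with a running median whose window matches a 0.5 Hz passband
#' (`sampling_rate / 0.5` samples): unlike a linear low-pass filter, the
#' median does not absorb any share of a spike into the baseline, so
#' spikes are confined to the residual where the biweight removes them,
#' while smooth haemodynamic signal passes through unchanged.
#'
#' @param od Matrix (time x columns) of optical-density signals, or a
#'   single numeric vector.
#' @param sampling_rate Hz.
#' @param split_hz Passband edge of the baseline smoother (default 0.5).
#' @param tol Convergence tolerance on the maximum weight change.
#' @param max_iter Iteration cap.
#' @return Corrected signal of the same shape.
#' @export
tddr_correct <- function(od, sampling_rate, split_hz = 0.5, tol = 1e-6,
                         max_iter = 50) {
  vec_in <- is.null(dim(od))
  od <- as.matrix(od)
  if (!all(is.finite(od))) stop("signal must be finite", call. = FALSE)
  k <- round(sampling_rate / split_hz)
  if (k %% 2 == 0) k <- k + 1
  out <- apply(od, 2, function(x) {
    if (k >= length(x)) {
      low <- rep(stats::median(x), length(x))
    } else {
      low <- as.numeric(stats::runmed(x, k, endrule = "median"))
    }
    resid <- x - low
    d <- diff(resid)
    if (length(d) == 0) {
      return(x)
    }
    w <- rep(1, length(d))
    for (i in seq_len(max_iter)) {
      mu <- sum(w * d) / sum(w)
      dev <- d - mu
      sigma <- 1.4826 * stats::median(abs(dev))
      if (sigma < .Machine$double.eps^0.5 * max(1, stats::sd(x))) {
        w <- rep(1, length(d))
        break
      }
      r <- dev / (4.685 * sigma)
      w_new <- ifelse(abs(r) < 1, (1 - r^2)^2, 0)
      delta <- max(abs(w_new - w))
      w <- w_new
      if (delta < tol) break
    }
    mu <- sum(w * d) / sum(w)
    resid_new <- cumsum(c(0, w * (d - mu)))
    low + resid_new
  })
  if (vec_in) as.numeric(out) else out
}
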