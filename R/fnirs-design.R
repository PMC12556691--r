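#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with response peak around 6 s,
#' undershoot around 16 s and a peak/undershoot ratio of 1/6 — the
#' canonical HRF used both to forward-model simulated recordings and to
#' build GLM regressors.
#'
#' @param t Time in seconds (>= 0).
#' @param peak Shape of the response gamma (s).
#' @param undershoot Shape of the undershoot gamma (s).
#' @param ratio Undershoot amplitude relative to the response.
#' @return HRF values (arbitrary scale; regressors are re-scaled to unit
#'   peak downstream).
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h
}

# per-condition regressors: a `duration_s` boxcar at each onset convolved
# with the canonical HRF, scaled so a single event peaks at 1. Shared by the
# simulator's forward model and the GLM design matrix.
condition_regressors <- function(events, sampling_rate, n_time,
                                 duration_s = 16) {
  stopifnot(nrow(events) > 0)
  dt <- 1 / sampling_rate
  t_kernel <- seq(0, 40 + duration_s, by = dt)
  hrf <- hrf_double_gamma(t_kernel)
  boxcar <- rep(1, max(1, round(duration_s * sampling_rate)))
  kernel <- stats::convolve(hrf, rev(boxcar), type = "open") * dt
  kernel <- kernel / max(kernel) # unit peak per event
  conds <- sort(unique(events$condition))
  out <- matrix(0, n_time, length(conds), dimnames = list(NULL, conds))
  for (i in seq_len(nrow(events))) {
    start <- round(events$onset[i] * sampling_rate) + 1
    idx <- start:min(n_time, start + length(kernel) - 1)
    if (start > n_time) next
    out[idx, events$condition[i]] <- out[idx, events$condition[i]] +
      kernel[seq_along(idx)]
  }
  out
}

#' Build the fNIRS GLM design matrix
#'
#' Columns: one regressor per condition (16-s boxcar at each event onset
#' convolved with the canonical double-gamma HRF, unit event peak), a
#' discrete-cosine drift basis covering frequencies up to
#' `drift_highpass_hz`, the leading principal components of the
#' short-channel signals (enough to reach `pc_var` cumulative variance, or
#' exactly `pc_n` if given), and a constant term.
#'
#' @param events Tibble with `onset` (s) and `condition`; an empty table is
#'   an error and events with identical onset and condition raise a
#'   warning.
#' @param sampling_rate Hz.
#' @param n_time Number of samples in the recording.
#' @param duration_s Event (boxcar) duration, default 16 s.
#' @param drift_highpass_hz Highest drift frequency modelled (default
#'   0.01 Hz).
#' @param short_channel_signals Optional matrix (time x signals) of
#'   short-channel haemoglobin time courses.
#' @param pc_var Cumulative-variance threshold for retained short-channel
#'   PCs (default 0.95).
#' @param pc_n Optional integer overriding `pc_var`.
#' @return A `fnirs_design`: list with `matrix` (n_time x p), `column_type`
#'   (condition/drift/short_pc/constant), and `n_short_pcs`.
#' @export
build_design_matrix <- function(events, sampling_rate, n_time,
                                duration_s = 16, drift_highpass_hz = 0.01,
                                short_channel_signals = NULL,
                                pc_var = 0.95, pc_n = NULL) {
  if (is.null(events) || nrow(events) == 0) {
    stop("no events supplied; cannot build a design matrix", call. = FALSE)
  }
  if (anyDuplicated(events[c("onset", "condition")])) {
    warning("duplicated identical events in design", call. = FALSE)
  }
  cond <- condition_regressors(events, sampling_rate, n_time, duration_s)
  t_sec <- n_time / sampling_rate
  n_drift <- floor(2 * t_sec * drift_highpass_hz)
  drift <- NULL
  if (n_drift > 0) {
    n_idx <- seq_len(n_time) - 1
    drift <- sapply(seq_len(n_drift), function(k) {
      cos(pi * (2 * n_idx + 1) * k / (2 * n_time))
    })
    colnames(drift) <- paste0("drift_", seq_len(n_drift))
  }
  pcs <- NULL
  n_pcs <- 0
  if (!is.null(short_channel_signals) && ncol(short_channel_signals) > 0 &&
    sum(apply(short_channel_signals, 2, stats::var)) > 1e-20) {
    pca <- stats::prcomp(short_channel_signals, center = TRUE, scale. = FALSE)
    cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    n_pcs <- if (!is.null(pc_n)) {
      min(pc_n, ncol(pca$x))
    } else {
      which(cumvar >= pc_var)[1]
    }
    pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("short_pc_", seq_len(n_pcs))
  }
  X <- cbind(cond, drift, pcs, constant = 1)
  column_type <- c(
    rep("condition", ncol(cond)),
    rep("drift", if (is.null(drift)) 0 else ncol(drift)),
    rep("short_pc", n_pcs),
    "constant"
  )
  structure(
    list(matrix = X, column_type = column_type, n_short_pcs = n_pcs),
    class = "fnirs_design"
  )
}
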