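#' Default per-ROI response amplitudes
#'
#' Ground-truth evoked HbO amplitudes per ROI and condition for the fNIRS
#' simulator, with the canonical polarity HbR = -HbO / 3.
#'
#' @param rois ROI labels.
#' @param hbo_performed,hbo_unknown Peak HbO amplitudes in micromolar.
#' @return Tibble with `roi`, `condition`, `hbo`, `hbr`.
#' @export
default_amplitudes <- function(rois = aon_rois, hbo_performed = 1,
                               hbo_unknown = 0.6) {
  amp <- tidyr::expand_grid(
    roi = rois,
    condition = c("performed", "unknown")
  )
  amp$hbo <- ifelse(amp$condition == "performed", hbo_performed, hbo_unknown)
  amp$hbr <- -amp$hbo / 3
  amp
}

#' Configuration for the fNIRS forward simulator
#'
#' Parameters of the forward model that turns an experiment schedule into
#' a two-wavelength intensity recording: evoked HbO/HbR responses (16-s
#' boxcar convolved with the canonical HRF, scaled by per-ROI amplitudes)
#' are converted to optical density by the Beer-Lambert relation (same
#' extinction table and pathlength factor as the inverse step), a
#' superficial haemodynamic component shared across channels with
#' channel-specific gains is added, plus linear drift, white noise and
#' optional artifacts; intensities are `I0 * exp(-OD)`.
#'
#' Defaults: 2.6 Hz sampling, the full 78 long / 8 short montage, 1.0 /
#' 0.6 micromolar evoked HbO (performed / unknown), a 0.3-micromolar
#' superficial component, 5e-4 OD white noise and 1e-6 OD/s drift —
#' magnitudes representative of a cooperative adult recording.
#'
#' @param sampling_rate Hz (> 0), default 2.6.
#' @param n_long_channels,n_short_channels Channel counts (> 0).
#' @param amplitudes Tibble from [default_amplitudes()] (columns `roi`,
#'   `condition`, `hbo`, `hbr`; `hbr` defaults to `-hbo/3` if absent).
#' @param superficial_sd SD of the shared superficial HbO component
#'   (micromolar; its HbR counterpart is -1/3 of it).
#' @param white_noise_sd SD of white noise added to optical density.
#' @param drift_slope Linear drift in OD per second (randomly signed and
#'   scaled per channel).
#' @param artifact_spec Optional tibble with `time_s`, `magnitude`, `type`
#'   ("spike" or "shift") describing motion artifacts added to the OD of
#'   every channel.
#' @param ppf [ppf_params()] used in the forward conversion.
#' @param isi_s Inter-stimulus interval between observation events (s).
#' @param lead_in_s Baseline before the first event (s).
#' @param duration_s Event duration (s), default the 16-s video length.
#' @param seed Integer seed.
#' @return A `fnirs_sim_config` list.
#' @export
fnirs_sim_config <- function(sampling_rate = 2.6, n_long_channels = 78,
                             n_short_channels = 8,
                             amplitudes = default_amplitudes(),
                             superficial_sd = 0.3, white_noise_sd = 5e-4,
                             drift_slope = 1e-6, artifact_spec = NULL,
                             ppf = ppf_params(), isi_s = 10, lead_in_s = 15,
                             duration_s = 16, seed = 1) {
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  if (n_long_channels <= 0 || n_short_channels <= 0) {
    stop("channel counts must be positive", call. = FALSE)
  }
  if (!("hbr" %in% names(amplitudes))) amplitudes$hbr <- -amplitudes$hbo / 3
  structure(
    list(
      sampling_rate = sampling_rate,
      n_long_channels = as.integer(n_long_channels),
      n_short_channels = as.integer(n_short_channels),
      amplitudes = amplitudes,
      superficial_sd = superficial_sd, white_noise_sd = white_noise_sd,
      drift_slope = drift_slope, artifact_spec = artifact_spec,
      ppf = ppf, isi_s = isi_s, lead_in_s = lead_in_s,
      duration_s = duration_s, seed = as.integer(seed)
    ),
    class = "fnirs_sim_config"
  )
}

#' Generate a synthetic fNIRS recording
#'
#' Forward-models a two-wavelength intensity recording for one participant
#' from an experiment schedule (observation trials become events) and a
#' [fnirs_sim_config()]. Ground-truth amplitudes and the generating config
#' are stored in the result, so the inverse pipeline
#' ([process_fnirs()]) can be validated against them.
#'
#' @param schedule An [generate_schedule()] result, or a tibble of events
#'   (`onset`, `condition`).
#' @param config A [fnirs_sim_config()].
#' @param montage Optional montage tibble (defaults to [make_montage()]
#'   with the configured channel counts).
#' @return A `fnirs_recording`: list with `intensity` (time x
#'   channel-wavelength matrix, columns `<channel>_<wavelength>`),
#'   `channels` (montage), `events`, `sampling_rate`, and `truth`.
#' @export
generate_fnirs_recording <- function(schedule, config = fnirs_sim_config(),
                                     montage = NULL) {
  stopifnot(inherits(config, "fnirs_sim_config"))
  if (is.null(montage)) {
    montage <- make_montage(config$n_long_channels, config$n_short_channels)
  }
  validate_montage(montage)
  long <- montage[montage$type == "long", ]
  bad_roi <- setdiff(long$roi, unique(config$amplitudes$roi))
  if (length(bad_roi) > 0) {
    stop(
      "no amplitude specified for ROI(s): ",
      paste(bad_roi, collapse = ", "),
      call. = FALSE
    )
  }
  if (inherits(schedule, "experiment_schedule")) {
    obs <- schedule$trials[schedule$trials$phase == "observe", ]
    events <- tibble::tibble(
      onset = config$lead_in_s +
        (seq_len(nrow(obs)) - 1) * (config$duration_s + config$isi_s),
      condition = obs$condition
    )
  } else {
    events <- tibble::as_tibble(schedule)[c("onset", "condition")]
  }
  events$duration <- config$duration_s
  fs <- config$sampling_rate
  n_time <- ceiling((max(events$onset) + config$duration_s + 30) * fs)
  reg <- condition_regressors(events, fs, n_time, config$duration_s)
  t_s <- (seq_len(n_time) - 1) / fs
  nyq <- fs / 2

  withr::with_seed(config$seed, {
    # shared superficial haemodynamic component: low-pass filtered noise
    sup <- stats::rnorm(n_time)
    if (nyq > 0.25) {
      bf <- signal::butter(2, 0.25 / nyq, type = "low")
      sup <- signal::filtfilt(bf, sup)
    }
    if (stats::sd(sup) > 0) sup <- sup / stats::sd(sup) * config$superficial_sd
    gains <- stats::runif(nrow(montage), 0.5, 1.5)
    drift_scale <- stats::runif(nrow(montage), 0.5, 1.5) *
      sample(c(-1, 1), nrow(montage), replace = TRUE)
    i0 <- matrix(stats::runif(2 * nrow(montage), 500, 2000),
      ncol = 2
    )
    artifact_od <- rep(0, n_time)
    if (!is.null(config$artifact_spec) && nrow(config$artifact_spec) > 0) {
      for (i in seq_len(nrow(config$artifact_spec))) {
        a <- config$artifact_spec[i, ]
        if (a$type == "spike") {
          artifact_od <- artifact_od +
            a$magnitude * exp(-abs(t_s - a$time_s) / 0.4)
        } else {
          artifact_od <- artifact_od + a$magnitude * (t_s >= a$time_s)
        }
      }
    }
    intensity <- matrix(NA_real_, n_time, 2 * nrow(montage))
    colnames(intensity) <- as.vector(t(outer(
      montage$channel, c("760", "850"), paste,
      sep = "_"
    )))
    for (c_idx in seq_len(nrow(montage))) {
      ch <- montage[c_idx, ]
      if (ch$type == "long") {
        amp <- config$amplitudes[config$amplitudes$roi == ch$roi, ]
        amp <- amp[match(colnames(reg), amp$condition), ]
        chbo <- as.numeric(reg %*% amp$hbo)
        chbr <- as.numeric(reg %*% amp$hbr)
      } else {
        chbo <- rep(0, n_time)
        chbr <- rep(0, n_time)
      }
      chbo <- chbo + gains[c_idx] * sup
      chbr <- chbr - gains[c_idx] * sup / 3
      od <- haemo_to_od(chbo, chbr, ch$distance_mm, config$ppf)
      drift <- drift_scale[c_idx] * config$drift_slope * t_s
      for (w_idx in 1:2) {
        od_w <- (if (w_idx == 1) od$od760 else od$od850) + drift + artifact_od
        if (config$white_noise_sd > 0) {
          od_w <- od_w + stats::rnorm(n_time, 0, config$white_noise_sd)
        }
        intensity[, 2 * (c_idx - 1) + w_idx] <- i0[c_idx, w_idx] * exp(-od_w)
      }
    }
  })
  structure(
    list(
      intensity = intensity, channels = montage, events = events,
      sampling_rate = fs,
      truth = list(amplitudes = config$amplitudes, config = config)
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "<fnirs_recording: %d channels (%d long / %d short), %d samples @ %g Hz, %d events>\n",
    nrow(x$channels), sum(x$channels$type == "long"),
    sum(x$channels$type == "short"), nrow(x$intensity), x$sampling_rate,
    nrow(x$events)
  ))
  invisible(x)
}

#' Write / read a recording directory
#'
#' Serialises a `fnirs_recording` as plain-text files: `channels.csv`,
#' `intensities.csv` (time x channel-wavelength), `events.csv`,
#' `meta.json` (sampling rate) and `truth.json` (ground-truth amplitudes).
#'
#' @param rec A `fnirs_recording`.
#' @param dir Directory path (created if needed).
#' @return `write_fnirs_recording()` returns `dir` invisibly;
#'   `read_fnirs_recording()` returns a `fnirs_recording`.
#' @export
write_fnirs_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(rec$channels, file.path(dir, "channels.csv"))
  readr::write_csv(
    tibble::as_tibble(rec$intensity),
    file.path(dir, "intensities.csv")
  )
  readr::write_csv(rec$events, file.path(dir, "events.csv"))
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE
  )
  jsonlite::write_json(list(amplitudes = rec$truth$amplitudes),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_fnirs_recording
#' @export
read_fnirs_recording <- function(dir) {
  channels <- readr::read_csv(file.path(dir, "channels.csv"),
    show_col_types = FALSE
  )
  intensity <- as.matrix(readr::read_csv(file.path(dir, "intensities.csv"),
    show_col_types = FALSE
  ))
  events <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(amplitudes = tibble::as_tibble(tr$amplitudes))
  } else {
    NULL
  }
  structure(
    list(
      intensity = intensity, channels = channels, events = events,
      sampling_rate = meta$sampling_rate, truth = truth
    ),
    class = "fnirs_recording"
  )
}
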