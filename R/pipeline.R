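#' Pipeline configuration
#'
#' A fully serialisable bundle of every stage's parameters: simulation
#' sizes and noise levels, kinematic metric settings, sampler settings and
#' fNIRS settings. Its hash (recorded in the run manifest and every output
#' table) identifies a run; re-running with the same config reproduces all
#' outputs byte for byte.
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param n_videos Even number of stimulus videos.
#' @param n_participants Number of observers.
#' @param n_frames Frames per stimulus video.
#' @param fps Video frame rate.
#' @param follower_noise_range Range of follower coordinate-noise SDs
#'   across videos (uniformly spaced), giving a spread of true synchrony
#'   levels.
#' @param observer Named-list overrides for [observer_sim_config()].
#' @param fnirs Named-list overrides for [fnirs_sim_config()].
#' @param fnirs_participants Number of participants for whom fNIRS
#'   recordings are simulated and processed (capped at `n_participants`).
#' @param metric Named list: `window`, `polyorder`, `m`, `r_factor`,
#'   `presmooth`.
#' @param sampler A [sampler_config()].
#' @param fnirs_glm Named list: `tddr`, `short_channels`, `pc_var`, `pc_n`,
#'   `weighting`, `drift_highpass_hz`.
#' @return A `pipeline_config` list with a `hash` field.
#' @export
pipeline_config <- function(seed = 1, n_videos = 40, n_participants = 43,
                            n_frames = 400, fps = 25,
                            follower_noise_range = c(0, 20),
                            observer = list(), fnirs = list(),
                            fnirs_participants = n_participants,
                            metric = list(), sampler = sampler_config(seed = seed),
                            fnirs_glm = list()) {
  metric <- utils::modifyList(
    list(window = 13, polyorder = 2, m = 2, r_factor = 0.2, presmooth = TRUE),
    metric
  )
  fnirs_glm <- utils::modifyList(
    list(
      tddr = TRUE, short_channels = TRUE, pc_var = 0.95, pc_n = NULL,
      weighting = "inverse_variance", drift_highpass_hz = 0.01
    ),
    fnirs_glm
  )
  cfg <- list(
    seed = as.integer(seed), n_videos = as.integer(n_videos),
    n_participants = as.integer(n_participants),
    n_frames = as.integer(n_frames), fps = fps,
    follower_noise_range = follower_noise_range,
    observer = observer, fnirs = fnirs,
    fnirs_participants = as.integer(min(fnirs_participants, n_participants)),
    metric = metric, sampler = unclass(sampler), fnirs_glm = fnirs_glm
  )
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Reduced-size demonstration configuration
#'
#' A small but complete configuration (12 videos, 12 observers, 3 fNIRS
#' participants with a 24-long/4-short montage, short sampler runs) that
#' exercises every pipeline stage in about a minute. Use
#' [pipeline_config()] defaults for study-scale runs.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(
    seed = seed, n_videos = 12, n_participants = 12, n_frames = 200,
    fnirs_participants = 3,
    fnirs = list(n_long_channels = 24, n_short_channels = 4, isi_s = 6),
    sampler = sampler_config(
      chains = 2, warmup = 500, iter = 500, thin = 6, seed = seed,
      rhat_max = 1.05
    )
  )
}

# derived, deterministic stage seeds (kept below 2^31)
stage_seed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data with known ground truth:
#' (1) simulate dyads and score per-video synchrony and complexity;
#' (2) build the experiment schedule; (3) simulate observer trials;
#' (4) fit the trait and rating models of estimation error; (5) simulate
#' and process fNIRS recordings per participant; (6) fit the
#' brain-behaviour model. Writes five output tables
#' (`video_metrics.csv`, `trials.csv`, `behaviour_posteriors.csv`,
#' `roi_estimates.csv`, `brain_posteriors.csv`), the raw behaviour-model
#' posterior draws (`behaviour_draws.csv`) and `manifest.json`
#' recording the config, its hash and all file names. Deterministic for a
#' fixed config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("dyadsync_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sampler <- do.call(sampler_config, config$sampler[c("chains", "warmup", "iter", "thin", "seed", "rhat_max")])

  # 1. dyads + kinematic metrics
  noise_levels <- seq(config$follower_noise_range[1],
    config$follower_noise_range[2],
    length.out = config$n_videos
  )
  dyads <- lapply(seq_len(config$n_videos), function(v) {
    generate_dyad(dyad_sim_config(
      n_frames = config$n_frames, fps = config$fps,
      follower_noise_sd = noise_levels[v],
      seed = stage_seed(config$seed, 1L) + v
    ))
  })
  names(dyads) <- sprintf("v%02d", seq_len(config$n_videos))
  metrics <- score_dyads(dyads,
    presmooth = config$metric$presmooth, window = config$metric$window,
    polyorder = config$metric$polyorder, m = config$metric$m,
    r_factor = config$metric$r_factor
  )

  # 2. schedule
  schedule <- generate_schedule(config$n_videos, seed = stage_seed(config$seed, 2L))
  measured <- dplyr::inner_join(schedule$videos, metrics[c("video_id", "synchrony")],
    by = "video_id"
  )

  # 3. observer trials
  traits <- simulate_traits(config$n_participants, seed = stage_seed(config$seed, 3L))
  obs_cfg <- do.call(observer_sim_config, utils::modifyList(
    list(
      n_participants = config$n_participants,
      seed = stage_seed(config$seed, 4L)
    ),
    config$observer
  ))
  trials <- generate_observer_data(measured, traits, obs_cfg)

  # 4. behaviour models
  trait_fit <- fit_trait_model(trials, traits, sampler = sampler)
  trials_c <- dplyr::left_join(trials, metrics[c("video_id", "complexity")],
    by = "video_id"
  )
  rating_fit <- fit_rating_model(trials_c, sampler = sampler)
  behaviour_posteriors <- dplyr::bind_rows(
    dplyr::mutate(tidy(trait_fit), model = "trait", .before = 1),
    dplyr::mutate(tidy(rating_fit), model = "rating", .before = 1)
  )

  # 5. fNIRS per participant
  fnirs_ids <- traits$participant_id[seq_len(config$fnirs_participants)]
  roi_estimates <- purrr::map_dfr(seq_along(fnirs_ids), function(i) {
    fn_cfg <- do.call(fnirs_sim_config, utils::modifyList(
      list(seed = stage_seed(config$seed, 5L) + i),
      config$fnirs
    ))
    rec <- generate_fnirs_recording(schedule, fn_cfg)
    res <- process_fnirs(rec,
      tddr = config$fnirs_glm$tddr,
      short_channels = config$fnirs_glm$short_channels,
      pc_var = config$fnirs_glm$pc_var, pc_n = config$fnirs_glm$pc_n,
      drift_highpass_hz = config$fnirs_glm$drift_highpass_hz,
      weighting = config$fnirs_glm$weighting
    )
    dplyr::mutate(res$roi_estimates, participant_id = fnirs_ids[i], .before = 1)
  })

  # 6. brain-behaviour model
  records <- prepare_brain_records(
    roi_estimates,
    dplyr::filter(trials, .data$participant_id %in% fnirs_ids)
  )
  brain_fit <- fit_brain_model(records, sampler = sampler)
  brain_posteriors <- tidy(brain_fit)

  files <- c(
    video_metrics = "video_metrics.csv", trials = "trials.csv",
    behaviour_posteriors = "behaviour_posteriors.csv",
    roi_estimates = "roi_estimates.csv",
    brain_posteriors = "brain_posteriors.csv",
    behaviour_draws = "behaviour_draws.csv"
  )
  draws_tbl <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(posterior_draws(trait_fit)),
      model = "trait", .before = 1
    ),
    dplyr::mutate(tibble::as_tibble(posterior_draws(rating_fit)),
      model = "rating", .before = 1
    )
  )
  readr::write_csv(draws_tbl, file.path(outdir, files["behaviour_draws"]))
  stamp <- function(df) dplyr::mutate(df, config_hash = config$hash, seed = config$seed)
  readr::write_csv(stamp(metrics), file.path(outdir, files["video_metrics"]))
  readr::write_csv(stamp(trials), file.path(outdir, files["trials"]))
  readr::write_csv(stamp(behaviour_posteriors), file.path(outdir, files["behaviour_posteriors"]))
  readr::write_csv(stamp(roi_estimates), file.path(outdir, files["roi_estimates"]))
  readr::write_csv(stamp(brain_posteriors), file.path(outdir, files["brain_posteriors"]))

  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config), config_hash = config$hash,
    outdir = normalizePath(outdir), files = as.list(files),
    created = "run manifest; outputs reproducible from config + seed"
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
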