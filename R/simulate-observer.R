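#' Trait score names
#'
#' The six interindividual measures used as predictors of estimation error.
#' @format Character vector of length 6.
#' @export
trait_names <- c(
  "extraversion", "self_esteem", "body_perception",
  "body_competence", "empathy", "autistic_traits"
)

#' Configuration for the observer estimation simulator
#'
#' Generative model for observers' synchrony estimates. For participant i
#' and video v, the latent estimation error is
#' `D_iv = intercept[condition] + sum_k beta_k * z_ik + u_i + eps_iv`
#' with participant random intercepts `u_i ~ N(0, random_intercept_sd^2)`
#' and residuals `eps ~ N(0, residual_sd^2)`. The recorded estimate is
#' `E = clamp(100 * S - D, 0, 100)`. Enjoyment is linearly linked to -D
#' (accurate estimation co-occurring with higher enjoyment) plus noise, and
#' recognition responses are Bernoulli with a configurable hit rate.
#'
#' Default intercepts (14.4 performed / 19.1 unknown error units) and trait
#' coefficients mirror the magnitudes reported for the study sample, so
#' recovery studies run at realistic effect sizes.
#'
#' @param n_participants Number of observers (default 43, the study sample).
#' @param intercept_performed,intercept_unknown Mean estimation error per
#'   condition, 0-100 scale.
#' @param trait_coefficients Named numeric of length 6 (error units per
#'   z-unit of each trait; names in [trait_names]).
#' @param random_intercept_sd SD of participant intercepts (>= 0).
#' @param residual_sd Trial-level residual SD (>= 0).
#' @param enjoyment_link Slope of enjoyment on -D (enjoyment units per
#'   error unit).
#' @param enjoyment_sd Residual SD of enjoyment ratings.
#' @param recognition_hit_rate P(respond "recognised") for performed
#'   videos.
#' @param recognition_false_alarm_rate P(respond "recognised") for unknown
#'   videos.
#' @param seed Integer seed.
#' @return An `observer_sim_config` list.
#' @export
observer_sim_config <- function(n_participants = 43,
                                intercept_performed = 14.4,
                                intercept_unknown = 19.1,
                                trait_coefficients = c(
                                  extraversion = -0.10, self_esteem = 1.76,
                                  body_perception = 1.16, body_competence = -2.27,
                                  empathy = -2.25, autistic_traits = 1.66
                                ),
                                random_intercept_sd = 5,
                                residual_sd = 10,
                                enjoyment_link = 1,
                                enjoyment_sd = 10,
                                recognition_hit_rate = 0.7,
                                recognition_false_alarm_rate = 0.3,
                                seed = 1) {
  if (n_participants < 2) stop("`n_participants` must be >= 2", call. = FALSE)
  if (random_intercept_sd < 0 || residual_sd < 0 || enjoyment_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  tc <- rep(0, 6)
  names(tc) <- trait_names
  if (length(trait_coefficients) > 0) {
    bad <- setdiff(names(trait_coefficients), trait_names)
    if (length(bad) > 0) {
      stop("unknown trait coefficient(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    tc[names(trait_coefficients)] <- trait_coefficients
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      intercept_performed = intercept_performed,
      intercept_unknown = intercept_unknown,
      trait_coefficients = tc,
      random_intercept_sd = random_intercept_sd,
      residual_sd = residual_sd,
      enjoyment_link = enjoyment_link,
      enjoyment_sd = enjoyment_sd,
      recognition_hit_rate = recognition_hit_rate,
      recognition_false_alarm_rate = recognition_false_alarm_rate,
      seed = as.integer(seed)
    ),
    class = "observer_sim_config"
  )
}

#' Simulate participant trait scores
#'
#' Draws the six questionnaire scores from Gaussians with plausible
#' questionnaire-scale means and SDs, and appends z-scored versions
#' (columns `z_<trait>`, standardised across the simulated sample).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return Tibble with `participant_id`, the six raw scores and their
#'   z-scores.
#' @export
simulate_traits <- function(n_participants = 43, seed = 1) {
  # questionnaire-scale location/spread per measure
  mu <- c(3.2, 28, 3.1, 19, 60, 80)
  sd <- c(0.7, 5, 0.6, 4, 12, 25)
  withr::with_seed(as.integer(seed), {
    raw <- purrr::map2(mu, sd, ~ stats::rnorm(n_participants, .x, .y))
  })
  names(raw) <- trait_names
  out <- tibble::tibble(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    !!!raw
  )
  zs <- lapply(out[trait_names], zscore)
  names(zs) <- paste0("z_", trait_names)
  dplyr::bind_cols(out, tibble::as_tibble(zs))
}

#' Generate synthetic observer trial data
#'
#' Simulates one trial record per participant x video from the generative
#' model described in [observer_sim_config()]. Ground-truth latent errors
#' are attached as attribute `"truth"`.
#'
#' @param measured Tibble with columns `video_id`, `condition`
#'   (performed/unknown) and `synchrony` in `[0, 1]`.
#' @param traits Trait table from [simulate_traits()] (or same shape) with
#'   one row per participant; z-scored columns are used if present, else
#'   computed.
#' @param config An [observer_sim_config()]; `n_participants` must match
#'   `nrow(traits)`.
#' @return Tibble of trial records: `participant_id`, `video_id`,
#'   `condition`, `measured_synchrony`, `estimated_synchrony`, `enjoyment`,
#'   `recognized`.
#' @export
generate_observer_data <- function(measured, traits, config = observer_sim_config()) {
  stopifnot(inherits(config, "observer_sim_config"))
  if (any(measured$synchrony < 0 | measured$synchrony > 1)) {
    stop("measured synchrony must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(traits) != config$n_participants) {
    stop(sprintf(
      "trait table has %d participants but config expects %d",
      nrow(traits), config$n_participants
    ), call. = FALSE)
  }
  zcols <- paste0("z_", trait_names)
  if (!all(zcols %in% names(traits))) {
    zs <- lapply(traits[trait_names], zscore)
    names(zs) <- zcols
    traits <- dplyr::bind_cols(traits, tibble::as_tibble(zs))
  }
  zmat <- as.matrix(traits[zcols])
  trait_part <- as.numeric(zmat %*% config$trait_coefficients)
  np <- config$n_participants
  nv <- nrow(measured)
  withr::with_seed(config$seed, {
    u <- stats::rnorm(np, 0, config$random_intercept_sd)
    grid <- tidyr::expand_grid(
      participant_id = traits$participant_id,
      video_id = measured$video_id
    )
    grid <- dplyr::left_join(grid, measured, by = "video_id")
    pi_idx <- match(grid$participant_id, traits$participant_id)
    intercept <- ifelse(grid$condition == "performed",
      config$intercept_performed, config$intercept_unknown
    )
    d_latent <- intercept + trait_part[pi_idx] + u[pi_idx] +
      stats::rnorm(nrow(grid), 0, config$residual_sd)
    estimate <- pmin(pmax(100 * grid$synchrony - d_latent, 0), 100)
    enjoyment <- pmin(pmax(
      50 - config$enjoyment_link * d_latent +
        stats::rnorm(nrow(grid), 0, config$enjoyment_sd), 0
    ), 100)
    p_yes <- ifelse(grid$condition == "performed",
      config$recognition_hit_rate, config$recognition_false_alarm_rate
    )
    recognized <- stats::runif(nrow(grid)) < p_yes
  })
  out <- tibble::tibble(
    participant_id = grid$participant_id,
    video_id = grid$video_id,
    condition = grid$condition,
    measured_synchrony = grid$synchrony,
    estimated_synchrony = estimate,
    enjoyment = enjoyment,
    recognized = recognized
  )
  attr(out, "truth") <- list(
    config = config, random_intercepts = u, latent_error = d_latent
  )
  out
}
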