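# single-fit recovery checks at study scale; the replicated coverage and
# calibration studies live in test-acceptance.R

test_that("trait model recovers generating intercepts, slope and contrast", {
  measured <- measured_videos(40, seed = 31)
  traits <- simulate_traits(43, seed = 32)
  cfg <- observer_sim_config(
    intercept_performed = 14.4, intercept_unknown = 19.1,
    trait_coefficients = c(body_competence = -2.27),
    seed = 33
  )
  trials <- generate_observer_data(measured, traits, cfg)
  fit <- fit_trait_model(trials, traits, sampler = quick_sampler(seed = 33))
  tb <- tidy(fit)
  row <- function(p) tb[tb$parameter == p, ]
  covers <- function(p, value) {
    r <- row(p)
    r$hpd_low <= value && value <= r$hpd_high
  }
  expect_true(covers("mean_error_performed", 14.4))
  expect_true(covers("mean_error_unknown", 19.1))
  expect_true(covers("condition_contrast", 14.4 - 19.1))
  expect_true(covers("body_competence", -2.27))
  # underestimation in both conditions is detected as substantial
  expect_true(row("mean_error_performed")$substantial)
  expect_true(row("mean_error_unknown")$substantial)
})

test_that("condition contrast covers 0 when intercepts are equal", {
  measured <- measured_videos(40, seed = 41)
  traits <- simulate_traits(30, seed = 42)
  cfg <- observer_sim_config(
    n_participants = 30,
    intercept_performed = 12, intercept_unknown = 12,
    trait_coefficients = c(), seed = 43
  )
  trials <- generate_observer_data(measured, traits, cfg)
  fit <- fit_trait_model(trials, traits, sampler = quick_sampler(seed = 43))
  contrast <- tidy(fit) |> dplyr::filter(parameter == "condition_contrast")
  expect_lte(contrast$hpd_low, 0)
  expect_gte(contrast$hpd_high, 0)
})

test_that("trait model validates its inputs", {
  measured <- measured_videos(4)
  traits <- simulate_traits(4, seed = 1)
  trials <- generate_observer_data(
    measured, traits, observer_sim_config(n_participants = 4, seed = 2)
  )
  expect_error(
    fit_trait_model(dplyr::mutate(trials, participant_id = "p99"), traits),
    "trait table"
  )
})

test_that("rating model recovers an enjoyment slope and a null recognition effect", {
  measured <- measured_videos(40, seed = 51)
  traits <- simulate_traits(43, seed = 52)
  # build trials where error depends on enjoyment with slope -0.40:
  # simulate enjoyment independently, then construct estimates from it
  withr::with_seed(53, {
    grid <- tidyr::expand_grid(
      participant_id = traits$participant_id,
      video_id = measured$video_id
    ) |>
      dplyr::left_join(measured, by = "video_id")
    u <- rnorm(nrow(traits), 0, 3)
    names(u) <- traits$participant_id
    enjoyment <- runif(nrow(grid), 0, 100)
    complexity <- rep(runif(40, 0.05, 0.4), times = nrow(traits))
    d_latent <- 35 - 0.40 * enjoyment + u[grid$participant_id] +
      rnorm(nrow(grid), 0, 6)
    trials <- grid |>
      dplyr::mutate(
        measured_synchrony = synchrony,
        estimated_synchrony = pmin(pmax(100 * synchrony - d_latent, 0), 100),
        enjoyment = enjoyment,
        complexity = complexity,
        recognized = runif(nrow(grid)) < 0.5 # pure noise
      )
  })
  fit <- fit_rating_model(trials, sampler = quick_sampler(seed = 54))
  tb <- tidy(fit)
  enj <- tb[tb$parameter == "enjoyment", ]
  expect_true(enj$hpd_low <= -0.40 && -0.40 <= enj$hpd_high)
  expect_true(enj$substantial)
  recog <- tb[tb$parameter == "recognized", ]
  expect_true(recog$hpd_low <= 0 && 0 <= recog$hpd_high)
  # equal generating slopes in both conditions: contrast covers 0
  contrast <- tb[tb$parameter == "enjoyment_slope_contrast", ]
  expect_true(contrast$hpd_low <= 0 && 0 <= contrast$hpd_high)
})

test_that("rating model requires the merged complexity column", {
  measured <- measured_videos(4)
  traits <- simulate_traits(4, seed = 1)
  trials <- generate_observer_data(
    measured, traits, observer_sim_config(n_participants = 4, seed = 2)
  )
  expect_error(fit_rating_model(trials), "complexity")
})
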