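test_that("null observer model reproduces the measured synchrony exactly", {
  measured <- measured_videos(10)
  traits <- simulate_traits(4, seed = 1)
  cfg <- observer_sim_config(
    n_participants = 4,
    intercept_performed = 0, intercept_unknown = 0,
    trait_coefficients = c(), random_intercept_sd = 0, residual_sd = 0,
    seed = 1
  )
  trials <- generate_observer_data(measured, traits, cfg)
  expect_equal(trials$estimated_synchrony, 100 * trials$measured_synchrony)
  expect_equal(
    estimation_error(trials$measured_synchrony, trials$estimated_synchrony),
    rep(0, nrow(trials))
  )
})

test_that("estimates are clamped to the slider bounds", {
  measured <- tibble::tibble(
    video_id = c("v1", "v2"), condition = c("performed", "unknown"),
    synchrony = c(0.02, 0.99)
  )
  traits <- simulate_traits(2, seed = 2)
  cfg <- observer_sim_config(
    n_participants = 2,
    intercept_performed = 50, intercept_unknown = -60,
    trait_coefficients = c(), random_intercept_sd = 0, residual_sd = 0,
    seed = 1
  )
  trials <- generate_observer_data(measured, traits, cfg)
  perf <- trials[trials$condition == "performed", ]
  unk <- trials[trials$condition == "unknown", ]
  expect_equal(perf$estimated_synchrony, rep(0, nrow(perf))) # 2 - 50 -> 0
  expect_equal(unk$estimated_synchrony, rep(100, nrow(unk))) # 99 + 60 -> 100
})

test_that("simulated error converges to configured mean and SD", {
  # 10,000 trials; empirical moments within 3 Monte-Carlo SEs.
  # synchrony kept >= 0.55 so the [0, 100] clamp is essentially inactive
  measured <- withr::with_seed(8, tibble::tibble(
    video_id = sprintf("v%03d", 1:200),
    condition = rep(c("performed", "unknown"), 100),
    synchrony = runif(200, 0.55, 0.95)
  ))
  traits <- simulate_traits(50, seed = 9)
  cfg <- observer_sim_config(
    n_participants = 50,
    intercept_performed = 14.4, intercept_unknown = 19.1,
    trait_coefficients = c(), random_intercept_sd = 0, residual_sd = 10,
    seed = 10
  )
  trials <- generate_observer_data(measured, traits, cfg)
  # keep unclamped trials only (clamping truncates the error distribution)
  ok <- trials$estimated_synchrony > 0 & trials$estimated_synchrony < 100
  d <- estimation_error(
    trials$measured_synchrony[ok], trials$estimated_synchrony[ok]
  )
  cond <- trials$condition[ok]
  for (cc in c("performed", "unknown")) {
    mu <- if (cc == "performed") 14.4 else 19.1
    n <- sum(cond == cc)
    se <- 10 / sqrt(n)
    expect_lt(abs(mean(d[cond == cc]) - mu), 3 * se)
    expect_lt(abs(stats::sd(d[cond == cc]) - 10), 3 * 10 / sqrt(2 * n))
  }
})

test_that("intercept recovery at study scale via sample means", {
  measured <- withr::with_seed(3, tibble::tibble(
    video_id = sprintf("v%02d", 1:40),
    condition = rep(c("performed", "unknown"), 20),
    synchrony = runif(40, 0.55, 0.95)
  ))
  traits <- simulate_traits(43, seed = 4)
  cfg <- observer_sim_config(seed = 5, trait_coefficients = c())
  trials <- generate_observer_data(measured, traits, cfg)
  d <- estimation_error(trials$measured_synchrony, trials$estimated_synchrony)
  # 43 x 40 trials; random intercepts (sd 5) dominate the Monte-Carlo error
  for (cc in c("performed", "unknown")) {
    mu <- if (cc == "performed") 14.4 else 19.1
    se <- sqrt(5^2 / 43 + 10^2 / sum(trials$condition == cc))
    expect_lt(abs(mean(d[trials$condition == cc]) - mu), 3 * se)
  }
})

test_that("enjoyment tracks accuracy and recognition rates follow the config", {
  measured <- measured_videos(40, seed = 6)
  traits <- simulate_traits(30, seed = 6)
  cfg <- observer_sim_config(
    n_participants = 30, enjoyment_link = 1,
    recognition_hit_rate = 0.9, recognition_false_alarm_rate = 0.1, seed = 7
  )
  trials <- generate_observer_data(measured, traits, cfg)
  d <- estimation_error(trials$measured_synchrony, trials$estimated_synchrony)
  expect_lt(stats::cor(d, trials$enjoyment), -0.2)
  expect_gt(mean(trials$recognized[trials$condition == "performed"]), 0.8)
  expect_lt(mean(trials$recognized[trials$condition == "unknown"]), 0.2)
})

test_that("participant mismatches are rejected", {
  measured <- measured_videos(4)
  traits <- simulate_traits(3, seed = 1)
  expect_error(
    generate_observer_data(measured, traits, observer_sim_config(n_participants = 5)),
    "participants"
  )
})
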