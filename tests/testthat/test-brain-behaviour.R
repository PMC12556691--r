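# synthetic brain-behaviour records with configurable per-ROI error slopes
brain_records_sim <- function(seed = 1, n_participants = 20,
                              slopes_performed = stats::setNames(rep(0, 12), aon_rois),
                              slopes_unknown = stats::setNames(rep(0, 12), aon_rois),
                              resid_sd = 0.3, u_sd = 0.2) {
  withr::with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n_participants))
    err <- rnorm(2 * n_participants, 17, 8) # participant x condition mean error
    records <- tidyr::expand_grid(
      participant_id = ids, roi = aon_rois,
      condition = c("performed", "unknown")
    )
    err_tbl <- tidyr::expand_grid(
      participant_id = ids, condition = c("performed", "unknown")
    )
    err_tbl$mean_estimation_error <- err
    records <- dplyr::left_join(records,
      err_tbl,
      by = c("participant_id", "condition")
    )
    per_part <- tibble::tibble(
      participant_id = ids,
      recognition_rate = runif(n_participants, 0.4, 0.9),
      mean_enjoyment = runif(n_participants, 30, 80),
      body_competence_z = as.numeric(scale(rnorm(n_participants)))
    )
    records <- dplyr::left_join(records, per_part, by = "participant_id")
    u <- rnorm(n_participants, 0, u_sd)
    names(u) <- ids
    err_z <- (records$mean_estimation_error - mean(records$mean_estimation_error)) /
      stats::sd(records$mean_estimation_error)
    slope <- ifelse(records$condition == "performed",
      slopes_performed[records$roi], slopes_unknown[records$roi]
    )
    records$hbdiff <- 0.1 + slope * err_z + u[records$participant_id] +
      rnorm(nrow(records), 0, resid_sd)
  })
  records
}

test_that("brain records aggregate trials to participant x condition summaries", {
  measured <- measured_videos(8, seed = 61)
  traits <- simulate_traits(4, seed = 62)
  trials <- generate_observer_data(
    measured, traits, observer_sim_config(n_participants = 4, seed = 63)
  )
  roi_est <- tidyr::expand_grid(
    participant_id = traits$participant_id, roi = aon_rois,
    condition = c("performed", "unknown")
  )
  roi_est$hbdiff <- rnorm(nrow(roi_est))
  rec <- prepare_brain_records(roi_est, trials)
  expect_equal(nrow(rec), 4 * 12 * 2)
  one <- rec[rec$participant_id == "p01" & rec$roi == "LIFG" &
    rec$condition == "performed", ]
  tt <- trials[trials$participant_id == "p01" & trials$condition == "performed", ]
  expect_equal(
    one$mean_estimation_error,
    mean(estimation_error(tt$measured_synchrony, tt$estimated_synchrony))
  )
  # recognition rate: correct = "yes" for performed, "no" for unknown
  tt_all <- trials[trials$participant_id == "p01", ]
  expect_equal(
    one$recognition_rate,
    mean((tt_all$condition == "performed") == tt_all$recognized)
  )
})

test_that("contrast equals the draw-wise difference of condition slopes", {
  records <- brain_records_sim(seed = 71, n_participants = 10)
  fit <- fit_brain_model(records,
    sampler = quick_sampler(seed = 72, iter = 300, warmup = 300)
  )
  dr <- posterior_draws(fit)
  for (r in c("LIFG", "RMC", "RIPL")) {
    expect_equal(
      dr[, paste0("slope_", r, "_contrast")],
      dr[, paste0("slope_", r, "_performed")] - dr[, paste0("slope_", r, "_unknown")],
      tolerance = 1e-12
    )
    expect_equal(
      dr[, paste0("slope_", r, "_aggregated")],
      (dr[, paste0("slope_", r, "_performed")] +
        dr[, paste0("slope_", r, "_unknown")]) / 2,
      tolerance = 1e-12
    )
  }
})

test_that("a condition-specific ROI slope is recovered and flagged", {
  slopes_p <- stats::setNames(rep(0, 12), aon_rois)
  slopes_p["LIFG"] <- -0.21
  records <- brain_records_sim(
    seed = 73, n_participants = 30,
    slopes_performed = slopes_p, resid_sd = 0.1, u_sd = 0.1
  )
  fit <- fit_brain_model(records, sampler = quick_sampler(seed = 74))
  tb <- tidy(fit)
  sl <- tb[tb$parameter == "slope_LIFG_performed", ]
  expect_true(sl$hpd_low <= -0.21 && -0.21 <= sl$hpd_high)
  contrast <- tb[tb$parameter == "slope_LIFG_contrast", ]
  expect_true(contrast$substantial)
  # identical generating slopes elsewhere: contrast covers 0
  null_contrast <- tb[tb$parameter == "slope_RIPL_contrast", ]
  expect_true(null_contrast$hpd_low <= 0 && 0 <= null_contrast$hpd_high)
})

test_that("incomplete crossings are reported", {
  records <- brain_records_sim(seed = 75, n_participants = 5)
  expect_error(fit_brain_model(records[-1, ]), "incomplete")
})

test_that("body-competence moderation slopes obey their algebraic identities", {
  records <- brain_records_sim(seed = 81, n_participants = 15)
  fit <- body_competence_moderation(
    records,
    sampler = quick_sampler(seed = 82, iter = 300, warmup = 300)
  )
  dr <- posterior_draws(fit)
  # slope at +1 SD minus slope at -1 SD equals the reported pairwise diff
  expect_equal(
    dr[, "slope_diff_plus1_minus1"],
    dr[, "slope_at_bc_plus1"] - dr[, "slope_at_bc_minus1"],
    tolerance = 1e-12
  )
  # with no generating moderation, the three conditional slopes agree
  tb <- tidy(fit)
  for (p in c("slope_diff_plus1_minus1", "slope_diff_plus1_0", "slope_diff_0_minus1")) {
    r <- tb[tb$parameter == p, ]
    expect_true(r$hpd_low <= 0 && 0 <= r$hpd_high)
  }
})

test_that("positive moderation steepens the slope at high body competence", {
  withr::with_seed(91, {
    n <- 25
    ids <- sprintf("p%02d", seq_len(n))
    records <- brain_records_sim(seed = 92, n_participants = n, resid_sd = 0.05, u_sd = 0.05)
    # inject moderation: effective slope = base + 0.15 * bc_z
    err_z <- (records$mean_estimation_error - mean(records$mean_estimation_error)) /
      stats::sd(records$mean_estimation_error)
    records$hbdiff <- records$hbdiff +
      (-0.1 + 0.15 * records$body_competence_z) * err_z
  })
  fit <- body_competence_moderation(records, sampler = quick_sampler(seed = 93))
  dr <- posterior_draws(fit)
  expect_lt(
    mean(dr[, "slope_at_bc_minus1"]),
    mean(dr[, "slope_at_bc_plus1"])
  )
  tb <- tidy(fit)
  diff <- tb[tb$parameter == "slope_diff_plus1_minus1", ]
  expect_true(diff$hpd_low <= 0.30 && 0.30 <= diff$hpd_high) # 2 * 0.15
})

test_that("moderation requires the body-competence column", {
  records <- brain_records_sim(seed = 95, n_participants = 5)
  records$body_competence_z <- NULL
  expect_error(body_competence_moderation(records), "body_competence_z")
})
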