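#' Assemble brain-behaviour records
#'
#' Joins per-participant ROI response estimates with behavioural
#' summaries: the participant x condition mean estimation error, the
#' participant's recognition rate (proportion of correct
#' performed/unknown judgements), and the mean enjoyment rating. One row
#' per participant x ROI x condition.
#'
#' @param roi_estimates Tibble with `participant_id`, `roi`, `condition`,
#'   `hbdiff` (e.g. stacked [process_fnirs()] results).
#' @param trials Trial table with `participant_id`, `condition`,
#'   `measured_synchrony`, `estimated_synchrony`, `enjoyment`,
#'   `recognized`.
#' @return Tibble with `participant_id`, `roi`, `condition`, `hbdiff`,
#'   `mean_estimation_error`, `recognition_rate`, `mean_enjoyment`.
#' @export
prepare_brain_records <- function(roi_estimates, trials) {
  trials <- dplyr::mutate(trials,
    error = estimation_error(.data$measured_synchrony, .data$estimated_synchrony),
    correct = (.data$condition == "performed") == .data$recognized
  )
  per_cond <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(mean_estimation_error = mean(.data$error), .groups = "drop")
  per_part <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      recognition_rate = mean(.data$correct),
      mean_enjoyment = mean(.data$enjoyment),
      .groups = "drop"
    )
  roi_estimates |>
    dplyr::select(dplyr::all_of(c("participant_id", "roi", "condition", "hbdiff"))) |>
    dplyr::left_join(per_cond, by = c("participant_id", "condition")) |>
    dplyr::left_join(per_part, by = "participant_id")
}

# design + contrast machinery shared by the two brain models.
# Slope contrasts are obtained by finite differences of design rows, so
# every derived slope is an exact linear combination of coefficients.
brain_design <- function(records, moderation = FALSE) {
  stopifnot(all(c(
    "participant_id", "roi", "condition", "hbdiff",
    "mean_estimation_error", "recognition_rate", "mean_enjoyment"
  ) %in% names(records)))
  cells <- tidyr::expand_grid(
    participant_id = unique(records$participant_id),
    roi = unique(records$roi),
    condition = unique(records$condition)
  )
  missing_cells <- dplyr::anti_join(cells, records,
    by = c("participant_id", "roi", "condition")
  )
  if (nrow(missing_cells) > 0) {
    stop(
      "incomplete participant x ROI x condition crossing; missing e.g. ",
      paste(utils::head(
        paste(missing_cells$participant_id, missing_cells$roi,
          missing_cells$condition,
          sep = "/"
        ), 3
      ), collapse = ", "),
      call. = FALSE
    )
  }
  # standardise the behavioural predictors across the analysed records
  records$error_z <- zscore(records$mean_estimation_error)
  records$recognition_z <- zscore(records$recognition_rate)
  records$enjoyment_z <- zscore(records$mean_enjoyment)
  if (moderation && !("body_competence_z" %in% names(records))) {
    stop("records must contain `body_competence_z` for the moderation model",
      call. = FALSE
    )
  }
  records$cond_code <- ifelse(records$condition == "performed", -0.5, 0.5)
  records$roi <- factor(records$roi)
  form <- if (moderation) {
    ~ cond_code * roi * error_z + recognition_z + enjoyment_z +
      body_competence_z * error_z
  } else {
    ~ cond_code * roi * error_z + recognition_z + enjoyment_z
  }
  X <- stats::model.matrix(form, data = records)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  list(records = records, X = X, form = form)
}

# contrast vector for d mu / d error_z at a given ROI/condition (and body
# competence level), via finite differencing of the model matrix row
brain_slope_contrast <- function(form, X, roi_levels, roi, cond_code, bc_z = NULL) {
  base <- data.frame(
    cond_code = cond_code, roi = factor(roi, levels = roi_levels),
    error_z = 0, recognition_z = 0, enjoyment_z = 0
  )
  if (!is.null(bc_z)) base$body_competence_z <- bc_z
  hi <- base
  hi$error_z <- 1
  mm <- stats::model.matrix(form, rbind(hi, base))
  as.numeric(mm[1, ] - mm[2, ])
}

#' Fit the brain-behaviour model
#'
#' Hierarchical Gaussian model of per-ROI HbO-HbR response amplitudes:
#' `hbdiff ~ 1 + condition * ROI * mean estimation error +
#' recognition rate + mean enjoyment + (1 | participant)`, with all
#' behavioural predictors z-scored across the analysed records and
#' condition coded performed = -1/2, unknown = +1/2.
#'
#' Besides the raw coefficients, the fit reports, per ROI: the estimation
#' error slope in each condition (`slope_<ROI>_performed` /
#' `_unknown`), their average (`slope_<ROI>_aggregated`) and the
#' performed-minus-unknown difference (`slope_<ROI>_contrast`). All are
#' exact draw-wise linear combinations of the coefficients, so the
#' contrast posterior equals the difference of the condition-slope
#' posteriors draw by draw.
#'
#' @param records From [prepare_brain_records()].
#' @param sampler A [sampler_config()].
#' @param priors Prior overrides, see [fit_hier_gauss()].
#' @return A `bsync_fit`.
#' @export
fit_brain_model <- function(records, sampler = sampler_config(),
                            priors = list()) {
  bd <- brain_design(records, moderation = FALSE)
  roi_levels <- levels(bd$records$roi)
  contrasts <- list()
  for (r in roi_levels) {
    perf <- brain_slope_contrast(bd$form, bd$X, roi_levels, r, -0.5)
    unk <- brain_slope_contrast(bd$form, bd$X, roi_levels, r, 0.5)
    contrasts[[paste0("slope_", r, "_performed")]] <- perf
    contrasts[[paste0("slope_", r, "_unknown")]] <- unk
    contrasts[[paste0("slope_", r, "_aggregated")]] <- (perf + unk) / 2
    contrasts[[paste0("slope_", r, "_contrast")]] <- perf - unk
  }
  fit_hier_gauss(
    bd$records$hbdiff, bd$X, bd$records$participant_id,
    contrasts = contrasts, sampler = sampler, priors = priors
  )
}

#' Body-competence moderation of the brain-behaviour association
#'
#' Extends [fit_brain_model()] with a body-competence x estimation-error
#' interaction and reports the error-activation slope (averaged over ROIs
#' and conditions) evaluated at body competence one SD below the mean, at
#' the mean, and one SD above (`slope_at_bc_minus1/0/plus1`), plus the
#' pairwise slope differences. The slope at the mean equals the
#' main-effect slope by construction.
#'
#' @param records From [prepare_brain_records()], plus a
#'   `body_competence_z` column (participant-level z-scored body
#'   competence).
#' @param sampler A [sampler_config()].
#' @param priors Prior overrides.
#' @return A `bsync_fit`.
#' @export
body_competence_moderation <- function(records, sampler = sampler_config(),
                                       priors = list()) {
  bd <- brain_design(records, moderation = TRUE)
  roi_levels <- levels(bd$records$roi)
  slope_at <- function(z) {
    vs <- lapply(roi_levels, function(r) {
      (brain_slope_contrast(bd$form, bd$X, roi_levels, r, -0.5, bc_z = z) +
        brain_slope_contrast(bd$form, bd$X, roi_levels, r, 0.5, bc_z = z)) / 2
    })
    Reduce(`+`, vs) / length(vs)
  }
  s_m1 <- slope_at(-1)
  s_0 <- slope_at(0)
  s_p1 <- slope_at(1)
  contrasts <- list(
    slope_at_bc_minus1 = s_m1,
    slope_at_bc_0 = s_0,
    slope_at_bc_plus1 = s_p1,
    slope_diff_plus1_minus1 = s_p1 - s_m1,
    slope_diff_plus1_0 = s_p1 - s_0,
    slope_diff_0_minus1 = s_0 - s_m1
  )
  fit_hier_gauss(
    bd$records$hbdiff, bd$X, bd$records$participant_id,
    contrasts = contrasts, sampler = sampler, priors = priors
  )
}

#' Table of per-ROI slope estimates
#'
#' Reshapes a [fit_brain_model()] fit into the familiar two-block report:
#' per ROI, the aggregated (both conditions) error slope and the
#' performed-minus-unknown contrast, each with 95% HPD bounds and
#' substantial/trend flags.
#'
#' @param fit A `bsync_fit` from [fit_brain_model()].
#' @return Tibble with `roi`, `block` ("aggregated"/"contrast"),
#'   `estimate`, `hpd_low`, `hpd_high`, `substantial`, `trend`.
#' @export
brain_slope_table <- function(fit) {
  tbl <- fit$summary |>
    dplyr::filter(grepl("^slope_.*_(aggregated|contrast)$", .data$parameter)) |>
    dplyr::mutate(
      roi = sub("^slope_(.*)_(aggregated|contrast)$", "\\1", .data$parameter),
      block = sub("^slope_.*_(aggregated|contrast)$", "\\1", .data$parameter)
    )
  dplyr::select(
    tbl, "roi", "block", "estimate", "hpd_low", "hpd_high",
    "substantial", "trend"
  )
}
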