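#' GLM with lag-1 autoregressive noise
#'
#' Ordinary least squares followed by Cochrane-Orcutt prewhitening: the
#' AR(1) coefficient is estimated from the lag-1 autocorrelation of the
#' OLS residuals, response and design are quasi-differenced, and the model
#' is refit; standard errors come from the prewhitened fit. This accounts
#' for the strong serial correlation of haemodynamic signals.
#'
#' @param y Numeric response (haemoglobin time series).
#' @param X Design matrix or `fnirs_design`.
#' @return List with `coefficients` (tibble `term`, `estimate`, `se`) and
#'   `rho` (estimated AR(1) coefficient).
#' @export
fit_glm_ar1 <- function(y, X) {
  if (inherits(X, "fnirs_design")) X <- X$matrix
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  denom <- sum(r^2)
  rho <- if (denom < .Machine$double.eps * max(1, sum(y^2))) {
    0 # (near-)perfect fit: nothing to prewhiten
  } else {
    sum(r[-1] * r[-length(r)]) / denom
  }
  if (abs(rho) >= 1) {
    stop("estimated AR(1) coefficient |rho| >= 1; cannot prewhiten",
      call. = FALSE
    )
  }
  n <- length(y)
  ys <- y[-1] - rho * y[-n]
  Xs <- X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE]
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  dof <- max(1, nrow(Xs) - ncol(Xs))
  sigma2 <- rss / dof
  xtx_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = unname(fit$coefficients), se = se
    ),
    rho = rho
  )
}

#' Inverse-variance weighted ROI aggregation
#'
#' Combines per-channel GLM estimates into one estimate per ROI, weighted
#' by the per-channel standard errors: by default precision weighting
#' `w = 1/SE^2` (so `SE_ROI = sqrt(1 / sum(w))`), optionally `w = 1/SE`.
#'
#' @param estimates Tibble with `channel`, `roi`, grouping columns (any of
#'   `condition`, `chromophore`), `estimate`, `se`.
#' @param rois ROIs to aggregate (default: all present); an ROI with no
#'   channels is an error.
#' @param weighting `"inverse_variance"` (default) or `"inverse_se"`.
#' @return Tibble with one row per ROI x grouping combination: `estimate`,
#'   `se`, `n_channels`.
#' @export
aggregate_roi <- function(estimates, rois = NULL,
                          weighting = c("inverse_variance", "inverse_se")) {
  weighting <- match.arg(weighting)
  if (is.null(rois)) rois <- unique(estimates$roi)
  empty <- setdiff(rois, unique(estimates$roi))
  if (length(empty) > 0) {
    stop("no channels for ROI(s): ", paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  group_cols <- intersect(c("roi", "condition", "chromophore"), names(estimates))
  estimates |>
    dplyr::filter(.data$roi %in% rois) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      estimate = {
        w <- if (weighting == "inverse_variance") 1 / .data$se^2 else 1 / .data$se
        sum(w * .data$estimate) / sum(w)
      },
      se = {
        w <- if (weighting == "inverse_variance") 1 / .data$se^2 else 1 / .data$se
        if (weighting == "inverse_variance") {
          sqrt(1 / sum(w))
        } else {
          # weighted-mean SE under independence
          sqrt(sum((w / sum(w))^2 * .data$se^2))
        }
      },
      n_channels = dplyr::n(),
      .groups = "drop"
    )
}

#' HbO-HbR difference and response category
#'
#' `hbdiff = hbo - hbr`. The sign codes response orientation: canonical
#' (HbO up, HbR down), inverted (HbO down, HbR up; a negative-BOLD-like
#' response), or same-sign (both up or both down — possibly blood pressure
#' or extracerebral changes rather than cortical activation).
#'
#' @param hbo_beta,hbr_beta Estimated response amplitudes (vectorised).
#' @return Tibble with `hbo_beta`, `hbr_beta`, `hbdiff`, `category`.
#' @export
hbdiff <- function(hbo_beta, hbr_beta) {
  stopifnot(all(is.finite(hbo_beta)), all(is.finite(hbr_beta)))
  category <- dplyr::case_when(
    hbo_beta > 0 & hbr_beta < 0 ~ "canonical",
    hbo_beta < 0 & hbr_beta > 0 ~ "inverted",
    .default = "same_sign"
  )
  tibble::tibble(
    hbo_beta = hbo_beta, hbr_beta = hbr_beta,
    hbdiff = hbo_beta - hbr_beta, category = category
  )
}

#' Full fNIRS signal chain: intensities to per-ROI response estimates
#'
#' Runs the complete haemodynamic analysis on one recording:
#' intensity -> optical density -> (optional) motion-artifact repair
#' (TDDR) -> modified Beer-Lambert conversion to HbO/HbR -> GLM with
#' condition regressors, cosine drift basis, short-channel principal
#' components and AR(1) prewhitening -> inverse-variance ROI aggregation
#' -> HbO-HbR differences. The scalp coupling index is reported for every
#' channel but never used to exclude channels.
#'
#' @param rec A `fnirs_recording`.
#' @param ppf [ppf_params()] for the Beer-Lambert inversion.
#' @param tddr Apply [tddr_correct()] (default TRUE).
#' @param short_channels Include short-channel PC regressors (default
#'   TRUE).
#' @param pc_var,pc_n Short-channel PC retention rule (see
#'   [build_design_matrix()]).
#' @param drift_highpass_hz Drift basis cutoff.
#' @param duration_s Event duration for the condition regressors.
#' @param weighting ROI weighting rule, see [aggregate_roi()].
#' @return A `fnirs_glm_result`: list with `channel_betas` (per channel x
#'   condition x chromophore), `roi_estimates` (per ROI x condition:
#'   `hbo_beta`, `hbr_beta`, SEs, `hbdiff`, `category`), `sci`, and
#'   `n_short_pcs`.
#' @export
process_fnirs <- function(rec, ppf = ppf_params(), tddr = TRUE,
                          short_channels = TRUE, pc_var = 0.95, pc_n = NULL,
                          drift_highpass_hz = 0.01, duration_s = 16,
                          weighting = c("inverse_variance", "inverse_se")) {
  weighting <- match.arg(weighting)
  validate_montage(rec$channels)
  od <- intensity_to_od(rec$intensity)
  sci <- tryCatch(scalp_coupling_index(rec), error = function(e) NULL)
  if (tddr) od <- tddr_correct(od, rec$sampling_rate)
  # per-channel Beer-Lambert inversion
  haemo <- list()
  for (i in seq_len(nrow(rec$channels))) {
    ch <- rec$channels[i, ]
    conc <- od_to_haemo(
      od[, paste0(ch$channel, "_760")], od[, paste0(ch$channel, "_850")],
      ch$distance_mm, ppf
    )
    haemo[[ch$channel]] <- conc
  }
  short_ids <- rec$channels$channel[rec$channels$type == "short"]
  short_mat <- NULL
  if (short_channels && length(short_ids) > 0) {
    short_mat <- do.call(cbind, lapply(short_ids, function(ch) {
      cbind(haemo[[ch]]$hbo, haemo[[ch]]$hbr)
    }))
  }
  design <- build_design_matrix(
    rec$events, rec$sampling_rate, nrow(od),
    duration_s = duration_s, drift_highpass_hz = drift_highpass_hz,
    short_channel_signals = short_mat, pc_var = pc_var, pc_n = pc_n
  )
  cond_terms <- colnames(design$matrix)[design$column_type == "condition"]
  long <- rec$channels[rec$channels$type == "long", ]
  channel_betas <- purrr::map_dfr(seq_len(nrow(long)), function(i) {
    ch <- long[i, ]
    purrr::map_dfr(c("hbo", "hbr"), function(chrom) {
      fit <- fit_glm_ar1(haemo[[ch$channel]][[chrom]], design)
      out <- fit$coefficients[fit$coefficients$term %in% cond_terms, ]
      tibble::tibble(
        channel = ch$channel, roi = ch$roi, chromophore = chrom,
        condition = out$term, estimate = out$estimate, se = out$se,
        rho = fit$rho
      )
    })
  })
  roi_agg <- aggregate_roi(channel_betas, weighting = weighting)
  roi_wide <- tidyr::pivot_wider(roi_agg,
    id_cols = c("roi", "condition"),
    names_from = "chromophore", values_from = c("estimate", "se")
  )
  roi_estimates <- dplyr::bind_cols(
    roi_wide[c("roi", "condition")],
    hbdiff(roi_wide$estimate_hbo, roi_wide$estimate_hbr),
    tibble::tibble(
      hbo_se = roi_wide$se_hbo, hbr_se = roi_wide$se_hbr
    )
  )
  structure(
    list(
      channel_betas = channel_betas, roi_estimates = roi_estimates,
      sci = sci, n_short_pcs = design$n_short_pcs, weighting = weighting
    ),
    class = "fnirs_glm_result"
  )
}

#' @export
print.fnirs_glm_result <- function(x, ...) {
  cat(sprintf(
    "<fnirs_glm_result: %d channel-level estimates, %d ROI x condition cells, %d short-channel PCs>\n",
    nrow(x$channel_betas), nrow(x$roi_estimates), x$n_short_pcs
  ))
  print(x$roi_estimates, n = 10)
  invisible(x)
}

#' Plot per-ROI haemodynamic response estimates
#'
#' @param object A `fnirs_glm_result`.
#' @param ... Unused.
#' @return A ggplot object: HbO-HbR difference per ROI and condition.
#' @method autoplot fnirs_glm_result
#' @export
autoplot.fnirs_glm_result <- function(object, ...) {
  ggplot2::ggplot(
    object$roi_estimates,
    ggplot2::aes(.data$roi, .data$hbdiff, fill = .data$condition)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "HbO - HbR response amplitude (µM)",
      fill = "condition"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
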