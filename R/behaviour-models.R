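#' Fit the trait model of estimation error
#'
#' Hierarchical Gaussian regression of trial-level estimation error
#' (`100 * measured - estimated`) on the six interindividual traits, each
#' crossed with condition, with participant random intercepts:
#' `error ~ 1 + trait_k * condition (k = 1..6) + (1 | participant)`.
#' Traits are z-scored at the participant level across the analysed sample;
#' condition is coded performed = -1/2, unknown = +1/2, so the intercept is
#' the grand-mean error and trait main effects are cross-condition slopes.
#'
#' Derived quantities reported alongside the coefficients:
#' `mean_error_performed`, `mean_error_unknown` (per-condition intercept
#' means) and `condition_contrast` (performed minus unknown).
#'
#' @param trials Trial table with `participant_id`, `condition`,
#'   `measured_synchrony` (0-1), `estimated_synchrony` (0-100).
#' @param traits Trait table with `participant_id` and the six scores of
#'   [trait_names] (raw; z-scored internally).
#' @param sampler A [sampler_config()].
#' @param priors Prior overrides, see [fit_hier_gauss()].
#' @return A `bsync_fit`.
#' @export
fit_trait_model <- function(trials, traits, sampler = sampler_config(),
                            priors = list()) {
  if (!all(trials$participant_id %in% traits$participant_id)) {
    stop("every trial's participant must appear in the trait table",
      call. = FALSE
    )
  }
  if (length(unique(trials$participant_id)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  traits <- dplyr::mutate(
    traits,
    dplyr::across(dplyr::all_of(trait_names), zscore, .names = "z_{.col}")
  )
  dat <- dplyr::left_join(trials, traits, by = "participant_id")
  y <- estimation_error(dat$measured_synchrony, dat$estimated_synchrony)
  cond <- ifelse(dat$condition == "performed", -0.5, 0.5)
  zmat <- as.matrix(dat[paste0("z_", trait_names)])
  X <- cbind(
    intercept = 1, condition = cond, zmat, zmat * cond
  )
  colnames(X) <- c(
    "intercept", "condition", trait_names,
    paste0(trait_names, ":condition")
  )
  k <- ncol(X)
  unit <- function(nm) {
    v <- rep(0, k)
    v[match(nm, colnames(X))] <- 1
    v
  }
  contrasts <- list(
    mean_error_performed = unit("intercept") - 0.5 * unit("condition"),
    mean_error_unknown = unit("intercept") + 0.5 * unit("condition"),
    condition_contrast = -unit("condition") # performed - unknown
  )
  fit_hier_gauss(y, X, dat$participant_id,
    contrasts = contrasts,
    sampler = sampler, priors = priors
  )
}

#' Fit the rating model of estimation error
#'
#' Hierarchical Gaussian regression of trial-level estimation error on
#' enjoyment and movement complexity (each crossed with condition) and on
#' the recognition response, with participant random intercepts — the
#' replication model for the aesthetic/kinematic correlates of estimation
#' error. Enjoyment and complexity enter in raw units by default (error
#' units per rating point / per entropy unit); set `standardize` to
#' z-score them.
#'
#' Derived quantities: per-condition slopes for enjoyment and complexity
#' and their performed-minus-unknown differences.
#'
#' @param trials Trial table with `participant_id`, `condition`,
#'   `measured_synchrony`, `estimated_synchrony`, `enjoyment`, `recognized`
#'   and a per-video `complexity` column (merge from [score_dyads()]).
#' @param sampler A [sampler_config()].
#' @param standardize Character subset of `c("enjoyment", "complexity")` to
#'   z-score before fitting.
#' @param priors Prior overrides.
#' @return A `bsync_fit`.
#' @export
fit_rating_model <- function(trials, sampler = sampler_config(),
                             standardize = character(), priors = list()) {
  needed <- c(
    "participant_id", "condition", "measured_synchrony",
    "estimated_synchrony", "enjoyment", "recognized", "complexity"
  )
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  y <- estimation_error(trials$measured_synchrony, trials$estimated_synchrony)
  enj <- trials$enjoyment
  comp <- trials$complexity
  if ("enjoyment" %in% standardize) enj <- zscore(enj)
  if ("complexity" %in% standardize) comp <- zscore(comp)
  cond <- ifelse(trials$condition == "performed", -0.5, 0.5)
  X <- cbind(
    intercept = 1, condition = cond,
    enjoyment = enj, complexity = comp,
    recognized = as.numeric(trials$recognized),
    `enjoyment:condition` = enj * cond,
    `complexity:condition` = comp * cond
  )
  k <- ncol(X)
  unit <- function(nm) {
    v <- rep(0, k)
    v[match(nm, colnames(X))] <- 1
    v
  }
  contrasts <- list(
    enjoyment_slope_performed = unit("enjoyment") - 0.5 * unit("enjoyment:condition"),
    enjoyment_slope_unknown = unit("enjoyment") + 0.5 * unit("enjoyment:condition"),
    enjoyment_slope_contrast = -unit("enjoyment:condition"),
    complexity_slope_performed = unit("complexity") - 0.5 * unit("complexity:condition"),
    complexity_slope_unknown = unit("complexity") + 0.5 * unit("complexity:condition"),
    complexity_slope_contrast = -unit("complexity:condition")
  )
  fit_hier_gauss(y, X, trials$participant_id,
    contrasts = contrasts,
    sampler = sampler, priors = priors
  )
}
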