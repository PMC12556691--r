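#' Sampler configuration for hierarchical models
#'
#' Settings for the MCMC sampler behind all hierarchical Gaussian models.
#' Defaults follow common practice for this model class: 4 chains with
#' 1,000 post-warmup draws each. Reduce for quick exploratory fits.
#'
#' @param chains Number of chains.
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param iter Post-warmup draws kept per chain.
#' @param thin Thinning interval (the sampler runs `iter * thin` post-warmup
#'   iterations and keeps every `thin`-th); useful when the group-level SD
#'   mixes slowly with few groups.
#' @param seed Integer seed (chains are offset deterministically).
#' @param rhat_max Convergence threshold on the split-Rhat of every
#'   monitored parameter; exceeding it raises a diagnostic error naming the
#'   offending parameters. Set to `Inf` to disable.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                           seed = 1, rhat_max = 1.01) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 100, thin >= 1)
  structure(
    list(
      chains = as.integer(chains), warmup = as.integer(warmup),
      iter = as.integer(iter), thin = as.integer(thin),
      seed = as.integer(seed), rhat_max = rhat_max
    ),
    class = "sampler_config"
  )
}

# Weakly informative priors: Normal(0, 20^2) on the intercept,
# Normal(0, 10^2) on (standardised-predictor) slopes, half-Student-t(3, 0, 10)
# on both SD parameters. Wide enough to dominate nothing at the 0-100 error
# scale; exposed so users can override.
hier_gauss_model_string <- function(intercept_sd = 20, slope_sd = 10, sd_scale = 10) {
  sprintf("
model {
  mu <- X %%*%% beta
  for (n in 1:N) {
    y[n] ~ dnorm(mu[n] + u[g[n]], tau)
  }
  for (j in 1:J) {
    u[j] ~ dnorm(0, tau_u)
  }
  beta[1] ~ dnorm(0, %g)
  for (k in 2:K) {
    beta[k] ~ dnorm(0, %g)
  }
  sigma ~ dt(0, %g, 3) T(0,)
  sigma_u ~ dt(0, %g, 3) T(0,)
  tau <- 1 / (sigma * sigma)
  tau_u <- 1 / (sigma_u * sigma_u)
}", 1 / intercept_sd^2, 1 / slope_sd^2, 1 / sd_scale^2, 1 / sd_scale^2)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected as well as between-chain
#' disagreement.
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return Scalar Rhat.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[1:half, , drop = FALSE], draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  n2 <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  b <- n2 * stats::var(means)
  if (w == 0) {
    return(1)
  }
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

#' Fit a hierarchical Gaussian regression
#'
#' The shared engine for all the package's multilevel models: a Gaussian
#' likelihood with fixed-effect design matrix `X`, participant (group)
#' random intercepts, and weakly informative priors. Sampling is performed
#' with JAGS (conjugate block updating). Derived quantities — per-condition
#' means, slopes, contrasts — are supplied as linear combinations of the
#' coefficients and summarised draw-by-draw, so a contrast's posterior is
#' exactly the draw-wise combination of its parents.
#'
#' @param y Numeric response.
#' @param X Design matrix (first column the intercept); column names become
#'   parameter names.
#' @param group Factor/character grouping vector (random intercepts).
#' @param contrasts Optional named list of numeric vectors (length
#'   `ncol(X)`) defining derived quantities `c %*% beta`.
#' @param sampler A [sampler_config()].
#' @param priors Named list overriding `intercept_sd`, `slope_sd`,
#'   `sd_scale`.
#' @return A `bsync_fit` object; see [tidy.bsync_fit()].
#' @export
fit_hier_gauss <- function(y, X, group, contrasts = list(),
                           sampler = sampler_config(), priors = list()) {
  stopifnot(length(y) == nrow(X), length(group) == length(y))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  g <- as.integer(factor(group))
  pr <- utils::modifyList(
    list(intercept_sd = 20, slope_sd = 10, sd_scale = 10), priors
  )
  model_str <- hier_gauss_model_string(pr$intercept_sd, pr$slope_sd, pr$sd_scale)
  data_list <- list(y = y, X = X, g = g, N = length(y), J = max(g), K = ncol(X))
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = sampler$seed * 1000L + ch
    )
  })
  jm <- rjags::jags.model(textConnection(model_str),
    data = data_list, inits = inits,
    n.chains = sampler$chains, n.adapt = 100, quiet = TRUE
  )
  if (sampler$warmup > 0) {
    stats::update(jm, n.iter = sampler$warmup, progress.bar = "none")
  }
  thin <- if (is.null(sampler$thin)) 1L else sampler$thin
  samp <- rjags::coda.samples(jm, c("beta", "sigma", "sigma_u"),
    n.iter = sampler$iter * thin, thin = thin, progress.bar = "none"
  )
  par_names <- c(colnames(X), "sigma", "sigma_u")
  # draws: iterations x parameters per chain -> combined, plus rhat per param
  chain_mats <- lapply(samp, as.matrix)
  k <- ncol(X)
  rhat <- vapply(seq_len(k + 2), function(j) {
    split_rhat(sapply(chain_mats, function(mm) mm[, j]))
  }, numeric(1))
  names(rhat) <- par_names
  draws <- do.call(rbind, chain_mats)
  colnames(draws) <- par_names
  if (is.finite(sampler$rhat_max) && any(rhat > sampler$rhat_max)) {
    bad <- names(rhat)[rhat > sampler$rhat_max]
    stop(structure(
      class = c("bsync_convergence_error", "error", "condition"),
      list(
        message = paste0(
          "sampler did not converge (split-Rhat > ",
          sampler$rhat_max, ") for: ", paste(bad, collapse = ", ")
        ),
        call = NULL
      )
    ))
  }
  beta_draws <- draws[, seq_len(k), drop = FALSE]
  if (length(contrasts) > 0) {
    cmat <- do.call(cbind, lapply(contrasts, function(v) {
      stopifnot(length(v) == k)
      as.numeric(v)
    }))
    derived <- beta_draws %*% cmat
    colnames(derived) <- names(contrasts)
    draws <- cbind(draws, derived)
  }
  summary_tbl <- summarise_draws_tbl(draws)
  structure(
    list(
      summary = summary_tbl, draws = draws, rhat = rhat,
      contrast_names = names(contrasts),
      n_obs = length(y), n_groups = max(g), sampler = sampler, priors = pr
    ),
    class = "bsync_fit"
  )
}

# posterior mean, 95% HPD and the substantial/trend flags per column.
# substantial: HPD excludes 0. trend: HPD overlaps 0 but less than 10% of
# the posterior mass lies on the minority side of 0.
summarise_draws_tbl <- function(draws, mass = 0.95) {
  purrr::map_dfr(colnames(draws), function(p) {
    d <- draws[, p]
    h <- hpd_interval(d, mass)
    substantial <- h[1] > 0 || h[2] < 0
    p_min <- min(mean(d > 0), mean(d < 0))
    tibble::tibble(
      parameter = p, estimate = mean(d),
      hpd_low = unname(h[1]), hpd_high = unname(h[2]),
      substantial = substantial,
      trend = !substantial && p_min < 0.10
    )
  })
}

#' @export
print.bsync_fit <- function(x, ...) {
  cat(sprintf(
    "<bsync_fit: %d obs, %d groups, %d draws, max split-Rhat %.3f>\n",
    x$n_obs, x$n_groups, nrow(x$draws), max(x$rhat)
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a hierarchical model fit
#'
#' One row per fixed effect, variance component, and derived contrast, with
#' posterior mean, 95% HPD bounds, and the substantial (HPD excludes 0) and
#' trend (< 10% of posterior mass on the minority side of 0) flags.
#'
#' @param x A `bsync_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bsync_fit
#' @export
tidy.bsync_fit <- function(x, ...) {
  x$summary
}

#' One-line model summary
#'
#' @param x A `bsync_fit`.
#' @param ... Unused.
#' @return Tibble with sizes, draw count, worst split-Rhat, and posterior
#'   mean residual/group SDs.
#' @method glance bsync_fit
#' @export
glance.bsync_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_groups = x$n_groups, n_draws = nrow(x$draws),
    n_chains = x$sampler$chains, max_rhat = max(x$rhat),
    sigma = mean(x$draws[, "sigma"]), sigma_group = mean(x$draws[, "sigma_u"])
  )
}

#' Posterior draws of a fitted model
#'
#' @param x A `bsync_fit`.
#' @param parameters Optional character subset.
#' @return Matrix of draws (iterations x parameters, chains stacked).
#' @export
posterior_draws <- function(x, parameters = NULL) {
  stopifnot(inherits(x, "bsync_fit"))
  if (is.null(parameters)) {
    return(x$draws)
  }
  x$draws[, parameters, drop = FALSE]
}

#' Coefficient interval plot
#'
#' Posterior means with 95% HPD bars; substantial effects are highlighted.
#'
#' @param object A `bsync_fit`.
#' @param parameters Optional character subset (defaults to everything but
#'   the variance components).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsync_fit
#' @export
autoplot.bsync_fit <- function(object, parameters = NULL, ...) {
  tbl <- object$summary
  if (is.null(parameters)) {
    tbl <- dplyr::filter(tbl, !.data$parameter %in% c("sigma", "sigma_u"))
  } else {
    tbl <- dplyr::filter(tbl, .data$parameter %in% parameters)
  }
  tbl$parameter <- factor(tbl$parameter, levels = rev(tbl$parameter))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$estimate, .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        xmin = .data$hpd_low, xmax = .data$hpd_high,
        colour = .data$substantial
      )
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "posterior mean (95% HPD)", y = NULL,
      colour = "HPD excludes 0"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
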