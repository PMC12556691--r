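# shared fixtures: everything generated in code at test time

# short-but-converging sampler for test fits; convergence at the strict
# threshold is asserted separately in test-bayes.R
quick_sampler <- function(seed = 1, chains = 2, warmup = 500, iter = 1000,
                          thin = 2, rhat_max = 1.05) {
  sampler_config(
    chains = chains, warmup = warmup, iter = iter, thin = thin, seed = seed,
    rhat_max = rhat_max
  )
}

# tiny hand-buildable pose sequence: joints at chosen coordinates per frame
toy_pose <- function(coord_list, fps = 25) {
  df <- purrr::imap_dfr(coord_list, function(m, f) {
    tibble::tibble(
      frame = as.integer(f) - 1L, joint = pose_joints,
      x = m[, 1], y = m[, 2]
    )
  })
  as_pose_seq(df, fps = fps)
}

# a 7 x 2 coordinate layout with all pairwise distances distinct
toy_coords <- function(shift_x = 0, shift_y = 0, scale = 1) {
  m <- cbind(
    c(0, -2, 2, -3, 3.5, -4, 5),
    c(0, 1, 1, 3, 3.2, 6, 6.5)
  )
  scale * m + matrix(c(shift_x, shift_y), 7, 2, byrow = TRUE)
}

# per-video measured synchrony table for observer simulations
measured_videos <- function(n_videos = 40, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      video_id = sprintf("v%02d", seq_len(n_videos)),
      condition = rep(c("performed", "unknown"), n_videos / 2),
      synchrony = stats::runif(n_videos, 0.3, 0.95)
    )
  })
}

# small fNIRS scene: schedule + config + montage sized for fast processing.
# With fewer than 12 long channels the montage covers a subset of the ROIs.
small_fnirs_setup <- function(seed = 1, n_videos = 12, n_long = 24, n_short = 4,
                              ...) {
  schedule <- generate_schedule(n_videos, seed = seed)
  config <- fnirs_sim_config(
    n_long_channels = n_long, n_short_channels = n_short,
    isi_s = 8, seed = seed, ...
  )
  montage <- make_montage(n_long, n_short,
    rois = aon_rois[seq_len(min(n_long, length(aon_rois)))]
  )
  list(schedule = schedule, config = config, montage = montage)
}

# noise-free variant: evoked responses only
noise_free_fnirs <- function(seed = 1, ...) {
  small_fnirs_setup(
    seed = seed,
    superficial_sd = 0, white_noise_sd = 0, drift_slope = 0, ...
  )
}

# brute-force sample entropy: direct template counting (independent oracle)
sampen_brute <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (stats::sd(x) == 0) {
    return(0)
  }
  count <- function(mm) {
    nt <- n - m # same template range for both lengths
    hits <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          hits <- hits + 1
        }
      }
    }
    hits
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0 || A == 0) {
    return(Inf)
  }
  -log(A / B)
}

# brute-force shortest-window HPD (independent oracle)
hpd_brute <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + k - 1])
    }
  }
  best
}
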