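#' Configuration for simulated leader-follower dyads
#'
#' Parameters for the mirror-game style kinematic simulator: a leader whose
#' joints follow band-limited sinusoid mixtures and a follower that tracks
#' the leader with a fixed lag, an amplitude scaling, and additive Gaussian
#' coordinate noise. Lower noise yields higher objective synchrony, so the
#' mapping from coupling fidelity to the synchrony score can be tested.
#'
#' @param n_frames Number of frames (> `lag_frames`).
#' @param fps Frames per second (default 25, the stimulus frame rate).
#' @param lag_frames Follower lag in frames (>= 0).
#' @param follower_noise_sd SD of Gaussian coordinate noise added to the
#'   follower, in pixel-like units (>= 0).
#' @param amplitude_scale Multiplicative scaling of the follower's
#'   coordinates (> 0).
#' @param seed Integer seed; generators are pure functions of their config.
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(n_frames = 400, fps = 25, lag_frames = 0,
                            follower_noise_sd = 0, amplitude_scale = 1,
                            seed = 1) {
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 1) {
    stop("`n_frames` must be a positive integer", call. = FALSE)
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (lag_frames < 0) stop("`lag_frames` must be non-negative", call. = FALSE)
  if (n_frames <= lag_frames) {
    stop("`n_frames` must exceed `lag_frames`", call. = FALSE)
  }
  if (follower_noise_sd < 0) {
    stop("`follower_noise_sd` must be non-negative", call. = FALSE)
  }
  if (amplitude_scale <= 0) stop("`amplitude_scale` must be positive", call. = FALSE)
  structure(
    list(
      n_frames = as.integer(n_frames), fps = fps,
      lag_frames = as.integer(lag_frames),
      follower_noise_sd = follower_noise_sd,
      amplitude_scale = amplitude_scale, seed = as.integer(seed)
    ),
    class = "dyad_sim_config"
  )
}

# anatomical rest pose (pixel units, y grows downward as in image coords)
rest_pose <- function() {
  data.frame(
    joint = pose_joints,
    x = c(320, 260, 380, 230, 410, 210, 430),
    y = c(150, 175, 175, 260, 260, 340, 340)
  )
}

# per-joint movement amplitude (px): trunk near-stationary, arms mobile
joint_amplitude <- c(
  neck = 2, l_shoulder = 3, r_shoulder = 3,
  l_elbow = 18, r_elbow = 18, l_hand = 40, r_hand = 40
)

#' Generate a leader pose sequence
#'
#' Each joint coordinate is a fixed anatomical rest position plus a mixture
#' of 3-6 sinusoids with random phases and frequencies at or below 1 Hz, so
#' trajectories are smooth and band-limited like improvised mirror-game arm
#' movement. Shoulders and neck are near-stationary; elbows and hands carry
#' most of the motion. Deterministic for a given config (seed included).
#'
#' @param config A [dyad_sim_config()].
#' @return A `pose_seq` with `n_frames` frames; the rest pose is attached as
#'   attribute `"rest_pose"`.
#' @export
generate_leader <- function(config) {
  stopifnot(inherits(config, "dyad_sim_config"))
  rest <- rest_pose()
  t_s <- (seq_len(config$n_frames) - 1) / config$fps
  withr::with_seed(config$seed, {
    coord_mat <- matrix(0, nrow = config$n_frames, ncol = 2 * length(pose_joints))
    k <- 0
    for (j in pose_joints) {
      for (axis in c("x", "y")) {
        k <- k + 1
        n_sin <- sample(3:6, 1)
        amp <- joint_amplitude[[j]] * stats::runif(n_sin, 0.3, 1) / n_sin
        freq <- stats::runif(n_sin, 0.05, 1) # band-limited <= 1 Hz
        phase <- stats::runif(n_sin, 0, 2 * pi)
        coord_mat[, k] <- rest[[axis]][rest$joint == j] +
          colSums(amp * sin(2 * pi * outer(freq, t_s) + phase))
      }
    }
  })
  idx_x <- seq(1, by = 2, length.out = length(pose_joints))
  out <- pose_from_matrix(
    frame = seq_len(config$n_frames) - 1L,
    x = coord_mat[, idx_x, drop = FALSE],
    y = coord_mat[, idx_x + 1, drop = FALSE],
    fps = config$fps
  )
  attr(out, "rest_pose") <- rest
  out
}

#' Generate a follower tracking a leader
#'
#' The follower reproduces the leader's trajectory delayed by
#' `lag_frames`, scaled by `amplitude_scale`, with independent Gaussian
#' noise of SD `follower_noise_sd` added to every coordinate. The first
#' `lag_frames` frames hold the (scaled) rest pose. The noise stream is
#' seeded independently of the leader's stream (config seed + 1).
#'
#' @param leader A `pose_seq`, typically from [generate_leader()].
#' @param config A [dyad_sim_config()]; `lag_frames` must be smaller than
#'   the leader's frame count.
#' @return A `pose_seq` of the same length as `leader`.
#' @export
generate_follower <- function(leader, config) {
  stopifnot(inherits(config, "dyad_sim_config"))
  nf <- n_frames(leader)
  if (config$lag_frames >= nf) {
    stop("`lag_frames` must be smaller than the leader's frame count",
      call. = FALSE
    )
  }
  pm <- pose_matrix(leader)
  lag <- config$lag_frames
  rest <- attr(leader, "rest_pose")
  if (is.null(rest)) {
    rest <- data.frame(joint = pose_joints, x = pm$x[1, ], y = pm$y[1, ])
  }
  shift <- function(mat, rest_row) {
    out <- mat
    if (lag > 0) {
      out[seq_len(lag), ] <- matrix(rest_row, nrow = lag, ncol = ncol(mat), byrow = TRUE)
      out[(lag + 1):nf, ] <- mat[seq_len(nf - lag), ]
    }
    out * config$amplitude_scale
  }
  x <- shift(pm$x, rest$x[match(pose_joints, rest$joint)])
  y <- shift(pm$y, rest$y[match(pose_joints, rest$joint)])
  if (config$follower_noise_sd > 0) {
    withr::with_seed(config$seed + 1L, {
      x <- x + matrix(
        stats::rnorm(length(x), 0, config$follower_noise_sd),
        nrow = nrow(x)
      )
      y <- y + matrix(
        stats::rnorm(length(y), 0, config$follower_noise_sd),
        nrow = nrow(y)
      )
    })
  }
  out <- pose_from_matrix(pm$frame, x, y, fps = pose_fps(leader))
  rest_f <- rest
  rest_f$x <- rest_f$x * config$amplitude_scale
  rest_f$y <- rest_f$y * config$amplitude_scale
  attr(out, "rest_pose") <- rest_f
  out
}

#' Generate a full synthetic dyad
#'
#' Convenience wrapper: leader plus follower from one config.
#'
#' @param config A [dyad_sim_config()].
#' @return List with elements `leader` and `follower` (both `pose_seq`).
#' @export
generate_dyad <- function(config) {
  leader <- generate_leader(config)
  list(leader = leader, follower = generate_follower(leader, config))
}
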