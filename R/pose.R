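#' Upper-body joint set
#'
#' The seven tracked upper-body joints, in the fixed enumeration order used
#' throughout the package. All joint-pair orderings (e.g. the 21 pairwise
#' distances of [pose_distance_vector()]) are lexicographic in this order.
#'
#' @format Character vector of length 7.
#' @export
pose_joints <- c(
  "neck",
  "l_shoulder", "r_shoulder",
  "l_elbow", "r_elbow",
  "l_hand", "r_hand"
)

#' Construct a pose sequence
#'
#' A pose sequence is a tidy tibble with one row per frame x joint and
#' columns `frame`, `joint`, `x`, `y`, carrying the sampling rate as an
#' attribute. It is the substrate for all kinematic metrics.
#'
#' @param df Data frame with columns `frame`, `joint`, `x`, `y`; every frame
#'   must contain all seven joints of [pose_joints].
#' @param fps Sampling rate in frames per second (> 0).
#' @return A `pose_seq` tibble (rows ordered by frame, then joint order).
#' @export
as_pose_seq <- function(df, fps = 25) {
  stopifnot(is.data.frame(df))
  needed <- c("frame", "joint", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("pose data lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  bad <- setdiff(unique(df$joint), pose_joints)
  if (length(bad) > 0) {
    stop("unknown joint name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[needed])
  out$joint <- factor(out$joint, levels = pose_joints)
  counts <- table(out$frame)
  if (any(counts != length(pose_joints))) {
    stop("every frame must contain exactly the 7 joints", call. = FALSE)
  }
  if (anyNA(out$x) || anyNA(out$y) || !all(is.finite(out$x)) || !all(is.finite(out$y))) {
    stop("pose coordinates must be finite", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$frame, .data$joint)
  out$joint <- as.character(out$joint)
  attr(out, "fps") <- fps
  class(out) <- c("pose_seq", class(out))
  out
}

#' @export
print.pose_seq <- function(x, ...) {
  cat(sprintf(
    "<pose_seq: %d frames, 7 joints, %g fps>\n",
    n_frames(x), pose_fps(x)
  ))
  NextMethod()
}

#' Sampling rate of a pose sequence
#' @param seq A `pose_seq`.
#' @return Frames per second.
#' @export
pose_fps <- function(seq) {
  fps <- attr(seq, "fps")
  if (is.null(fps)) 25 else fps
}

#' Number of frames in a pose sequence
#' @param seq A `pose_seq`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  length(unique(seq$frame))
}

# frames x (2 * joints) coordinate matrix; columns x.<joint>, y.<joint>
# in the fixed joint order. Internal workhorse for vectorised metrics.
pose_matrix <- function(seq) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(seq, joint = factor(.data$joint, levels = pose_joints)),
    id_cols = "frame", names_from = "joint", values_from = c("x", "y"),
    names_sep = "."
  )
  wide <- dplyr::arrange(wide, .data$frame)
  xs <- as.matrix(wide[paste0("x.", pose_joints)])
  ys <- as.matrix(wide[paste0("y.", pose_joints)])
  list(frame = wide$frame, x = xs, y = ys)
}

# rebuild a pose_seq from pose_matrix() parts
pose_from_matrix <- function(frame, x, y, fps) {
  colnames(x) <- pose_joints
  colnames(y) <- pose_joints
  long_x <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(data.frame(frame = frame), x)),
    -"frame",
    names_to = "joint", values_to = "x"
  )
  long_y <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(data.frame(frame = frame), y)),
    -"frame",
    names_to = "joint", values_to = "y"
  )
  as_pose_seq(dplyr::inner_join(long_x, long_y, by = c("frame", "joint")), fps = fps)
}

#' Read / write pose tables
#'
#' Pose sequences are serialised as tab-separated tables with columns
#' `frame`, `joint`, `x`, `y`.
#'
#' @param path File path.
#' @param fps Sampling rate to attach on read.
#' @return `read_pose_tsv()` returns a `pose_seq`; `write_pose_tsv()` returns
#'   `path` invisibly.
#' @export
read_pose_tsv <- function(path, fps = 25) {
  as_pose_seq(readr::read_tsv(path, show_col_types = FALSE), fps = fps)
}

#' @rdname read_pose_tsv
#' @param seq A `pose_seq`.
#' @export
write_pose_tsv <- function(seq, path) {
  readr::write_tsv(as.data.frame(seq)[c("frame", "joint", "x", "y")], path)
  invisible(path)
}

#' Plot joint trajectories of a pose sequence
#'
#' @param seq A `pose_seq`.
#' @param coords Which coordinates to facet over (`"x"`, `"y"`, or both).
#' @return A ggplot object (time courses per joint).
#' @export
plot_pose_trajectories <- function(seq, coords = c("x", "y")) {
  coords <- match.arg(coords, several.ok = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::mutate(seq, time = .data$frame / pose_fps(seq)),
    dplyr::all_of(coords),
    names_to = "axis", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value, colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "coordinate (px)", colour = "joint")
}
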