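#' Savitzky-Golay smoothing of a pose sequence
#'
#' Smooths every joint coordinate time series with a Savitzky-Golay filter
#' (default window 13 frames, polynomial order 2 — i.e. half a second at
#' 25 fps), the standard pre-processing step for keypoint trajectories.
#'
#' @param seq A `pose_seq`.
#' @param window Odd filter window length in frames.
#' @param polyorder Polynomial order (< `window`).
#' @return A smoothed `pose_seq` of identical length.
#' @export
smooth_pose <- function(seq, window = 13, polyorder = 2) {
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  if (polyorder >= window) stop("`polyorder` must be < `window`", call. = FALSE)
  nf <- n_frames(seq)
  if (nf < window) {
    stop(sprintf(
      "pose sequence has %d frames; Savitzky-Golay smoothing needs at least %d",
      nf, window
    ), call. = FALSE)
  }
  pm <- pose_matrix(seq)
  sg <- function(mat) apply(mat, 2, signal::sgolayfilt, p = polyorder, n = window)
  out <- pose_from_matrix(pm$frame, sg(pm$x), sg(pm$y), fps = pose_fps(seq))
  attr(out, "rest_pose") <- attr(seq, "rest_pose")
  out
}

# joint-pair table in fixed lexicographic order of the joint enumeration
joint_pairs <- function() {
  idx <- utils::combn(seq_along(pose_joints), 2)
  data.frame(a = pose_joints[idx[1, ]], b = pose_joints[idx[2, ]])
}

# frames x 21 matrix of L1-normalised pairwise joint distances.
# Degenerate frames (all joints coincident) get the uniform vector.
pose_distance_frames <- function(seq) {
  pm <- pose_matrix(seq)
  idx <- utils::combn(seq_along(pose_joints), 2)
  d <- sqrt((pm$x[, idx[1, ], drop = FALSE] - pm$x[, idx[2, ], drop = FALSE])^2 +
    (pm$y[, idx[1, ], drop = FALSE] - pm$y[, idx[2, ], drop = FALSE])^2)
  tot <- rowSums(d)
  degenerate <- tot == 0
  norm <- d / ifelse(tot == 0, 1, tot)
  norm[degenerate, ] <- 1 / ncol(d)
  list(values = norm, degenerate = degenerate, frame = pm$frame)
}

#' Normalised pose-distance vector for one frame
#'
#' Builds the per-frame "pose matrix" entry: the 21 pairwise Euclidean
#' distances between the 7 upper-body joints (all neck/shoulder/elbow/hand
#' combinations, lexicographic in the joint enumeration), divided by their
#' sum. Distances remove absolute position and the L1 normalisation removes
#' overall scale, so the vector is invariant to a mover's height and
#' position relative to the camera. A frame with all joints coincident
#' yields the uniform vector with the `degenerate` flag set.
#'
#' @param seq A `pose_seq`.
#' @param frame Frame identifier (must occur in `seq$frame`).
#' @return Tibble with columns `joint_a`, `joint_b`, `value` (21 rows,
#'   summing to 1), plus attributes `frame_index` and `degenerate`.
#' @export
pose_distance_vector <- function(seq, frame) {
  pdf_all <- pose_distance_frames(seq)
  pos <- match(frame, pdf_all$frame)
  if (is.na(pos)) stop("frame ", frame, " not present in sequence", call. = FALSE)
  pairs <- joint_pairs()
  out <- tibble::tibble(
    joint_a = pairs$a, joint_b = pairs$b,
    value = as.numeric(pdf_all$values[pos, ])
  )
  attr(out, "frame_index") <- frame
  attr(out, "degenerate") <- pdf_all$degenerate[pos]
  out
}

#' Frame-wise pose similarity
#'
#' Total-variation similarity between two L1-normalised pose-distance
#' vectors: `1 - 0.5 * sum(|a - b|)`. Equals 1 for identical poses and 0
#' for vectors with disjoint support (maximally different poses).
#'
#' @param a,b Normalised distance vectors: numeric vectors of length 21 or
#'   tibbles from [pose_distance_vector()].
#' @return Similarity in `[0, 1]`.
#' @export
frame_similarity <- function(a, b) {
  va <- if (is.data.frame(a)) a$value else a
  vb <- if (is.data.frame(b)) b$value else b
  if (length(va) != length(vb)) {
    stop("distance vectors differ in length", call. = FALSE)
  }
  1 - 0.5 * sum(abs(va - vb))
}

#' Objective movement-synchrony score for a dyad
#'
#' Computes the pose-matrix synchrony measure: per frame, each mover's 21
#' normalised pairwise joint distances are compared with total-variation
#' similarity, and the per-frame similarities are averaged over the video.
#' The result lies in `[0, 1]`; 1 means identical poses in every frame.
#'
#' @param a,b `pose_seq` objects with equal frame counts and fps.
#' @param presmooth Apply [smooth_pose()] first (default TRUE; disable for
#'   sequences shorter than the filter window or already-smoothed data).
#' @param window,polyorder Savitzky-Golay parameters when `presmooth` is on.
#' @return A single synchrony score in `[0, 1]`.
#' @export
synchrony_score <- function(a, b, presmooth = TRUE, window = 13, polyorder = 2) {
  if (n_frames(a) != n_frames(b)) {
    stop("dyad members have different frame counts", call. = FALSE)
  }
  if (!isTRUE(all.equal(pose_fps(a), pose_fps(b)))) {
    stop("dyad members have different sampling rates", call. = FALSE)
  }
  if (presmooth) {
    a <- smooth_pose(a, window, polyorder)
    b <- smooth_pose(b, window, polyorder)
  }
  da <- pose_distance_frames(a)
  db <- pose_distance_frames(b)
  sims <- 1 - 0.5 * rowSums(abs(da$values - db$values))
  mean(sims)
}

#' Movement complexity of a dyad
#'
#' Sample entropy of the hand (wrist) trajectories: one entropy per
#' combination of 2 hands x 2 axes x 2 movers (8 components), averaged.
#' Values near 0 indicate regular, predictable movement; larger values
#' indicate more complex movement.
#'
#' @param a,b `pose_seq` objects for the two dyad members.
#' @param m Template length for [sample_entropy()].
#' @param r_factor Tolerance as a fraction of each series' SD.
#' @param presmooth Apply [smooth_pose()] first.
#' @param window,polyorder Savitzky-Golay parameters when `presmooth` is on.
#' @return A `complexity_score`: list with `value` (mean of the 8
#'   components) and named `components`.
#' @export
movement_complexity <- function(a, b, m = 2, r_factor = 0.2, presmooth = TRUE,
                                window = 13, polyorder = 2) {
  if (presmooth) {
    a <- smooth_pose(a, window, polyorder)
    b <- smooth_pose(b, window, polyorder)
  }
  series <- list()
  for (person in c("a", "b")) {
    pm <- pose_matrix(if (person == "a") a else b)
    for (hand in c("l_hand", "r_hand")) {
      j <- match(hand, pose_joints)
      for (axis in c("x", "y")) {
        series[[paste(person, hand, axis, sep = ".")]] <-
          (if (axis == "x") pm$x else pm$y)[, j]
      }
    }
  }
  components <- vapply(names(series), function(nm) {
    h <- tryCatch(
      sample_entropy(series[[nm]], m = m, r_factor = r_factor),
      error = function(e) {
        stop("complexity component ", nm, " failed: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    h
  }, numeric(1))
  structure(
    list(value = mean(components), components = components),
    class = "complexity_score"
  )
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("<complexity_score: %.4f (mean of %d components)>\n",
    x$value, length(x$components)
  ))
  print(round(x$components, 4))
  invisible(x)
}

#' Score a table of dyads
#'
#' Applies [synchrony_score()] and [movement_complexity()] to each dyad and
#' returns a tidy per-video metrics table.
#'
#' @param dyads Named list of dyads; each element a list with `leader` and
#'   `follower` `pose_seq` objects.
#' @param presmooth,window,polyorder,m,r_factor Passed to the metrics.
#' @return Tibble with columns `video_id`, `synchrony`, `complexity` and the
#'   eight complexity components.
#' @export
score_dyads <- function(dyads, presmooth = TRUE, window = 13, polyorder = 2,
                        m = 2, r_factor = 0.2) {
  purrr::imap_dfr(dyads, function(d, id) {
    comp <- movement_complexity(d$leader, d$follower,
      m = m, r_factor = r_factor,
      presmooth = presmooth, window = window, polyorder = polyorder
    )
    out <- tibble::tibble(
      video_id = id,
      synchrony = synchrony_score(d$leader, d$follower,
        presmooth = presmooth, window = window, polyorder = polyorder
      ),
      complexity = comp$value
    )
    comps <- tibble::as_tibble(as.list(comp$components))
    names(comps) <- paste0("sampen.", names(comps))
    dplyr::bind_cols(out, comps)
  })
}
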