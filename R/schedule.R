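#' Generate an experiment schedule
#'
#' Randomly splits the videos equally between the *performed* and *unknown*
#' conditions, then builds three-trial blocks: participants first mirror
#' the performed sequence themselves, then observe the performed and an
#' unknown dyad video in random order. With 40 videos this yields 20 blocks
#' and 60 trial slots.
#'
#' @param n_videos Even number of videos (default 40).
#' @param seed Integer seed; the split and orderings are deterministic per
#'   seed.
#' @return An `experiment_schedule`: list with `videos` (tibble `video_id`,
#'   `condition`) and `trials` (tibble `block`, `slot`, `phase`
#'   (mirror/observe), `video_id`, `condition`).
#' @export
generate_schedule <- function(n_videos = 40, seed = 1) {
  if (n_videos %% 2 != 0 || n_videos < 2) {
    stop("`n_videos` must be a positive even number", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("v%02d", seq_len(n_videos))
    cond <- sample(rep(c("performed", "unknown"), n_videos / 2))
    videos <- tibble::tibble(video_id = ids, condition = cond)
    performed <- sample(videos$video_id[videos$condition == "performed"])
    unknown <- sample(videos$video_id[videos$condition == "unknown"])
    trials <- purrr::map_dfr(seq_along(performed), function(b) {
      observe <- tibble::tibble(
        phase = "observe",
        video_id = c(performed[b], unknown[b]),
        condition = c("performed", "unknown")
      )
      observe <- observe[sample(1:2), ]
      dplyr::bind_rows(
        tibble::tibble(
          phase = "mirror", video_id = performed[b],
          condition = "performed"
        ),
        observe
      ) |>
        dplyr::mutate(block = b, slot = (b - 1) * 3 + dplyr::row_number())
    })
  })
  structure(
    list(
      videos = videos,
      trials = dplyr::select(trials, "block", "slot", "phase", "video_id", "condition")
    ),
    class = "experiment_schedule"
  )
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf(
    "<experiment_schedule: %d videos (%d performed / %d unknown), %d blocks, %d trial slots>\n",
    nrow(x$videos),
    sum(x$videos$condition == "performed"),
    sum(x$videos$condition == "unknown"),
    max(x$trials$block), nrow(x$trials)
  ))
  invisible(x)
}
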