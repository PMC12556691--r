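test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  t <- 0:39
  quad <- 2 + 0.5 * t - 0.01 * t^2
  coords <- lapply(seq_along(t), function(i) {
    cbind(rep(quad[i], 7), rep(3 + 0.2 * t[i], 7))
  })
  seq <- toy_pose(coords)
  sm <- smooth_pose(seq, window = 13, polyorder = 2)
  interior <- dplyr::filter(sm, frame >= 6, frame <= 33)
  orig <- dplyr::filter(seq, frame >= 6, frame <= 33)
  expect_equal(interior$x, orig$x, tolerance = 1e-8)
  expect_equal(interior$y, orig$y, tolerance = 1e-8)
})

test_that("smoothing a constant pose changes nothing and reduces noise variance", {
  const <- toy_pose(rep(list(toy_coords()), 30))
  expect_equal(as.data.frame(smooth_pose(const)), as.data.frame(const),
    tolerance = 1e-10
  )
  withr::with_seed(5, {
    t <- seq(0, 4, length.out = 100)
    clean <- sin(2 * pi * 0.5 * t)
    noisy <- clean + rnorm(100, 0, 0.3)
    coords <- lapply(seq_along(t), function(i) toy_coords(shift_x = noisy[i]))
    sm <- smooth_pose(toy_pose(coords))
    resid_after <- dplyr::filter(sm, joint == "neck")$x - clean
    resid_before <- noisy - clean
    expect_lt(stats::var(resid_after), stats::var(resid_before))
  })
})

test_that("smoothing errors on too-short sequences, naming the minimum", {
  short <- toy_pose(rep(list(toy_coords()), 5))
  expect_error(smooth_pose(short), "at least 13")
})

test_that("pose distance vector matches hand-computed Euclidean distances", {
  m <- toy_coords()
  seq <- toy_pose(list(m))
  pdv <- pose_distance_vector(seq, 0)
  expect_equal(nrow(pdv), 21)
  expect_equal(sum(pdv$value), 1, tolerance = 1e-9)
  # independent hand computation of raw distances in the same pair order
  raw <- c()
  for (i in 1:6) {
    for (j in (i + 1):7) {
      raw <- c(raw, sqrt(sum((m[i, ] - m[j, ])^2)))
    }
  }
  expect_equal(pdv$value, raw / sum(raw), tolerance = 1e-12)
  # e.g. neck to l_shoulder: sqrt((-2)^2 + 1^2)
  expect_equal(
    raw[1], sqrt(5),
    tolerance = 1e-12
  )
})

test_that("distance vectors are invariant to translation and uniform scaling", {
  base <- pose_distance_vector(toy_pose(list(toy_coords())), 0)
  shifted <- pose_distance_vector(
    toy_pose(list(toy_coords(shift_x = 57, shift_y = -12))), 0
  )
  scaled <- pose_distance_vector(toy_pose(list(toy_coords(scale = 2))), 0)
  expect_equal(base$value, shifted$value, tolerance = 1e-12)
  expect_equal(base$value, scaled$value, tolerance = 1e-12)
})

test_that("degenerate all-coincident frames yield flagged uniform vectors", {
  degen <- toy_pose(list(matrix(1, 7, 2)))
  pdv <- pose_distance_vector(degen, 0)
  expect_true(attr(pdv, "degenerate"))
  expect_equal(pdv$value, rep(1 / 21, 21))
})

test_that("frame similarity has the stated endpoints and hand-checked midpoint", {
  a <- c(0.5, 0.5, rep(0, 19))
  b <- c(0.25, 0.75, rep(0, 19))
  disjoint <- c(0, 1, rep(0, 20))[1:21]
  one_hot <- c(1, rep(0, 20))
  expect_equal(frame_similarity(a, a), 1)
  expect_equal(frame_similarity(one_hot, disjoint), 0)
  expect_equal(frame_similarity(a, b), 0.75)
  expect_error(frame_similarity(a, b[1:20]), "length")
})

test_that("synchrony score is 1 for identical sequences, symmetric, and hand-verifiable", {
  leader <- generate_leader(dyad_sim_config(n_frames = 80, seed = 9))
  expect_equal(synchrony_score(leader, leader), 1)
  d <- generate_dyad(dyad_sim_config(n_frames = 80, follower_noise_sd = 6, seed = 9))
  s_ab <- synchrony_score(d$leader, d$follower)
  s_ba <- synchrony_score(d$follower, d$leader)
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  expect_gte(s_ab, 0)
  expect_lte(s_ab, 1)

  # two-frame toy dyad, similarities computed by hand from the raw vectors
  a <- toy_pose(list(toy_coords(), toy_coords(scale = 1.3)))
  b <- toy_pose(list(toy_coords(shift_x = 4), matrix(c(1:7 / 3, rep(1, 7)), 7, 2)))
  va1 <- pose_distance_vector(a, 0)$value
  va2 <- pose_distance_vector(a, 1)$value
  vb1 <- pose_distance_vector(b, 0)$value
  vb2 <- pose_distance_vector(b, 1)$value
  by_hand <- mean(c(
    1 - 0.5 * sum(abs(va1 - vb1)),
    1 - 0.5 * sum(abs(va2 - vb2))
  ))
  expect_equal(synchrony_score(a, b, presmooth = FALSE), by_hand, tolerance = 1e-12)
})

test_that("synchrony score validates frame counts and sampling rates", {
  a <- generate_leader(dyad_sim_config(n_frames = 40, seed = 1))
  b <- generate_leader(dyad_sim_config(n_frames = 41, seed = 1))
  expect_error(synchrony_score(a, b), "frame counts")
})

test_that("synchrony score is invariant to per-mover translation and common scaling", {
  d <- generate_dyad(dyad_sim_config(n_frames = 60, follower_noise_sd = 3, seed = 21))
  base <- synchrony_score(d$leader, d$follower, presmooth = FALSE)
  translate <- function(seq, dx, dy) {
    out <- dplyr::mutate(seq, x = x + dx, y = y + dy)
    as_pose_seq(out, fps = pose_fps(seq))
  }
  rescale <- function(seq, k) {
    as_pose_seq(dplyr::mutate(seq, x = x * k, y = y * k), fps = pose_fps(seq))
  }
  expect_equal(
    synchrony_score(translate(d$leader, 100, -40), d$follower, presmooth = FALSE),
    base,
    tolerance = 1e-12
  )
  expect_equal(
    synchrony_score(d$leader, rescale(d$follower, 3.7), presmooth = FALSE),
    base,
    tolerance = 1e-12
  )
})

test_that("movement complexity averages exactly its 8 components and is symmetric", {
  d <- generate_dyad(dyad_sim_config(n_frames = 150, follower_noise_sd = 2, seed = 13))
  comp <- movement_complexity(d$leader, d$follower)
  expect_length(comp$components, 8)
  expect_equal(comp$value, mean(comp$components))
  swapped <- movement_complexity(d$follower, d$leader)
  expect_equal(comp$value, swapped$value, tolerance = 1e-12)
})

test_that("pose tables round-trip through TSV", {
  seq <- generate_leader(dyad_sim_config(n_frames = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pose_tsv(seq, path)
  back <- read_pose_tsv(path, fps = 25)
  for (col in c("frame", "joint", "x", "y")) {
    expect_equal(back[[col]], seq[[col]], tolerance = 1e-9)
  }
  expect_equal(pose_fps(back), 25)
})
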