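test_that("partial pathlength factor matches the acquisition convention", {
  expect_equal(partial_pathlength_factor(6, 60), 0.1)
  expect_equal(partial_pathlength_factor(3.5, 1), 3.5)
  expect_equal(partial_pathlength_factor(0, 60), 0)
  expect_error(partial_pathlength_factor(6, 0), "non-zero")
})

test_that("optical density of constant intensity is zero; halving adds ln 2", {
  const <- matrix(500, 100, 2, dimnames = list(NULL, c("c1_760", "c1_850")))
  expect_equal(intensity_to_od(const), matrix(0, 100, 2,
    dimnames = list(NULL, c("c1_760", "c1_850"))
  ))
  stepped <- matrix(1000, 100, 1, dimnames = list(NULL, "c1_760"))
  stepped[60, 1] <- 500
  od <- intensity_to_od(stepped)
  expect_equal(unname(od[60, 1] - od[1, 1]), log(2), tolerance = 1e-12)
  bad <- matrix(c(rep(1, 99), 0), 100, 1, dimnames = list(NULL, "c9_850"))
  expect_error(intensity_to_od(bad), "c9_850")
})

test_that("Beer-Lambert forward and inverse are exact mutual inverses", {
  withr::with_seed(12, {
    chbo <- rnorm(300, 0, 1)
    chbr <- rnorm(300, 0, 0.4)
    od <- haemo_to_od(chbo, chbr, distance_mm = 30, ppf = ppf_params())
    back <- od_to_haemo(od$od760, od$od850, distance_mm = 30, ppf = ppf_params())
    expect_lt(max(abs(back$hbo - chbo)), 1e-8)
    expect_lt(max(abs(back$hbr - chbr)), 1e-8)
  })
})

test_that("Beer-Lambert inversion matches a hand-solved 2x2 system", {
  ext <- extinction_coefficients()
  e <- log(10) * rbind(
    c(ext$hbo[ext$wavelength_nm == 760], ext$hbr[ext$wavelength_nm == 760]),
    c(ext$hbo[ext$wavelength_nm == 850], ext$hbr[ext$wavelength_nm == 850])
  )
  conc <- c(0.8, -0.3) * 1e-6 # molar
  L <- 3 * 0.1 # 30 mm in cm x ppf 0.1
  od <- as.numeric(e %*% conc) * L
  got <- od_to_haemo(od[1], od[2], distance_mm = 30, ppf = 0.1)
  expect_equal(got$hbo, 0.8, tolerance = 1e-10)
  expect_equal(got$hbr, -0.3, tolerance = 1e-10)
  expect_equal(od_to_haemo(0, 0, 30, 0.1), list(hbo = 0, hbr = 0))
})

test_that("TDDR leaves constant and clean signals essentially untouched", {
  const <- rep(4, 200)
  expect_equal(tddr_correct(const, 2.6), const, tolerance = 1e-9)
  # clean haemodynamic-band signal
  t <- seq(0, 200, by = 1 / 2.6)
  clean <- sin(2 * pi * 0.04 * t) + 0.4 * sin(2 * pi * 0.09 * t)
  out <- tddr_correct(clean, 2.6)
  expect_gt(stats::cor(out, clean), 0.99)
})

test_that("TDDR suppresses large motion spikes", {
  withr::with_seed(30, {
    t <- seq(0, 300, by = 1 / 2.6)
    x <- sin(2 * pi * 0.05 * t) + rnorm(length(t), 0, 0.2)
    spike <- x
    spike[400] <- spike[400] + 20 * stats::sd(x)
    out <- tddr_correct(spike, 2.6)
    z <- abs(out - mean(out)) / stats::sd(out)
    expect_lt(max(z), 5)
  })
  expect_error(tddr_correct(c(1, NA, 3), 2.6), "finite")
})

test_that("scalp coupling index separates coupled, independent and anti-phase channels", {
  fs <- 2.6
  t <- seq(0, 400, by = 1 / fs)
  withr::with_seed(17, {
    cardiac <- sin(2 * pi * 0.9 * t) # within the clipped cardiac band
    montage <- make_montage(n_long = 3, n_short = 1, rois = aon_rois[1:3])
    keep <- montage[montage$type == "long", ]
    noise <- function() rnorm(length(t), 0, 1)
    od <- cbind(
      # coupled: same cardiac wave on both wavelengths
      cardiac + 0.05 * noise(), cardiac + 0.05 * noise(),
      # independent noise, no cardiac component
      noise(), noise(),
      # anti-phase cardiac
      cardiac + 0.05 * noise(), -cardiac + 0.05 * noise()
    )
    colnames(od) <- as.vector(t(outer(keep$channel, c("760", "850"), paste, sep = "_")))
    rec <- structure(
      list(
        intensity = exp(-od) * 1000, channels = keep,
        sampling_rate = fs
      ),
      class = "fnirs_recording"
    )
    sci <- scalp_coupling_index(rec)
    expect_gt(sci$sci[1], 0.9)
    expect_lt(abs(sci$sci[2]), 0.3)
    expect_lt(sci$sci[3], -0.9)
  })
})

test_that("SCI requires at least 30 s of signal", {
  montage <- make_montage(n_long = 1, n_short = 1, rois = "LIFG")
  keep <- montage[montage$type == "long", ]
  short_rec <- structure(
    list(
      intensity = matrix(1000, 26, 2,
        dimnames = list(NULL, paste0(keep$channel[1], c("_760", "_850")))
      ),
      channels = keep, sampling_rate = 2.6
    ),
    class = "fnirs_recording"
  )
  expect_error(scalp_coupling_index(short_rec), "30 s")
})
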