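test_that("the Lorentzian closed form is exact at its anchor points", {
  expect_equal(lorentzian(1000, 1000, 20, 2), 2)
  expect_equal(lorentzian(c(990, 1010), 1000, 20, 2), c(1, 1))
  expect_equal(lorentzian(1020, 1000, 20, 2), 2 * 100 / (400 + 100)) # 0.4
  expect_error(lorentzian(1000, 1000, 0, 1), "fwhm")
})

test_that("class band tables carry the printed positions and directions", {
  ctr <- tear_bands("Ctr")
  mci <- tear_bands("MCI")
  ad <- tear_bands("AD")
  expect_equal(ctr$center[ctr$label == "Phe"], 998)
  expect_equal(ctr$center[ctr$label == "amide I"], 1639)
  expect_equal(mci$center[mci$label == "amide I"], 1625)
  expect_equal(ad$center[ad$label == "amide I"], 1628)
  # amide II is depressed in AD
  expect_lt(ad$height[ad$label == "amide II"], ctr$height[ctr$label == "amide II"])
  # MCI loses intensity at the amide III / Trp pair, AD gains at Phe and 1591
  expect_lt(mci$height[mci$label == "amide III beta"], ctr$height[ctr$label == "amide III beta"])
  expect_lt(mci$height[mci$label == "Trp"], ctr$height[ctr$label == "Trp"])
  expect_gt(ad$height[ad$label == "Phe"], ctr$height[ctr$label == "Phe"])
  expect_gt(ad$height[ad$label == "1591"], ctr$height[ctr$label == "1591"])
  expect_lt(ad$height[ad$label == "1459"], ctr$height[ctr$label == "1459"])
})

test_that("profile height ratios encode the printed class I1342/I1243 values", {
  sigma <- c(Ctr = 0.14, MCI = 0.12, AD = 0.09)
  targets <- c(Ctr = 1.1, MCI = 1.8, AD = 1.5)
  for (cl in names(targets)) {
    b <- tear_bands(cl)
    r0 <- b$height[b$label == "Trp"] / b$height[b$label == "amide III beta"]
    # expected subject-mean fitted ratio =
    #   profile ratio * exp(sigma^2) * fitted-recovery factor
    expect_equal(r0 * exp(sigma[[cl]]^2) * 0.956, unname(targets[cl]), tolerance = 1e-10)
  }
})

test_that("the null configuration collapses all class mean tables onto the control", {
  for (cl in c("MCI", "AD")) {
    expect_equal(tear_bands(cl, effect_scale = 0), tear_bands("Ctr"))
  }
  # and effect_scale interpolates continuously
  half <- tear_bands("AD", effect_scale = 0.5)
  full <- tear_bands("AD", effect_scale = 1)
  ctr <- tear_bands("Ctr")
  i <- which(ctr$label == "amide I")
  expect_equal(half$center[i], (ctr$center[i] + full$center[i]) / 2)
})

test_that("the noiseless limit reproduces the analytic band sum exactly", {
  cfg <- noiseless_config(n_subjects = c(Ctr = 1, AD = 1))
  sim <- simulate_tears(cfg, seed = 9)
  w <- tearspec:::spectra_matrix(sim$spectra)
  for (i in seq_len(nrow(w$meta))) {
    cl <- as.character(w$meta$class_label[i])
    expected <- bands_to_intensity(tear_bands(cl), cfg$grid) +
      pmax(tearspec:::eval_baseline(cfg$profiles[[cl]]$baseline_coeffs, cfg$grid), 0.05)
    expect_equal(unname(w$m[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_config()
  a <- simulate_tears(cfg, seed = 13)
  b <- simulate_tears(cfg, seed = 13)
  expect_identical(a$spectra$intensity, b$spectra$intensity)
  expect_identical(a$truth, b$truth)
})

test_that("replicate noise matches the configured level", {
  cfg <- default_profiles(
    n_subjects = c(Ctr = 8), n_replicates = 20,
    gain_sd = 0 # otherwise the per-subject gain rescales the noise
  )
  sim <- simulate_tears(cfg, seed = 17)
  w <- tearspec:::spectra_matrix(sim$spectra)
  resid_sd <- vapply(unique(w$meta$subject_id), function(id) {
    m <- w$m[w$meta$subject_id == id, ]
    mean(apply(m, 2, sd))
  }, 1)
  target <- cfg$profiles$Ctr$noise_sd * cfg$reference_height
  expect_equal(mean(resid_sd), target, tolerance = 0.05)
})

test_that("truth plus background reconstructs every noiseless spectrum", {
  cfg <- default_profiles(n_subjects = c(Ctr = 2, MCI = 2), noise_sd = 0)
  sim <- simulate_tears(cfg, seed = 19)
  w <- tearspec:::spectra_matrix(sim$spectra)
  for (id in unique(w$meta$subject_id)) {
    rec <- sim_noiseless(sim, id)
    obs <- w$m[which(w$meta$subject_id == id)[1], ]
    expect_equal(unname(obs), unname(rec), tolerance = 1e-10)
  }
})

test_that("noiseless spectra are non-negative everywhere", {
  cfg <- default_profiles(noise_sd = 0)
  sim <- simulate_tears(cfg, seed = 23)
  expect_true(all(sim$spectra$intensity >= 0))
})

test_that("the grid must cover all band centers", {
  expect_error(
    default_profiles(grid = seq(700, 1900, 2)),
    "does not cover"
  )
})
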