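test_that("peak seeding finds isolated bands and ignores flat spectra", {
  grid <- canonical_grid()
  one <- spec_from(lorentzian(grid, 1000, 20, 1))
  seeds <- seed_peaks(one, c(900, 1100))
  expect_equal(nrow(seeds), 1)
  expect_lt(abs(seeds$center - 1000), 2)

  two <- spec_from(lorentzian(grid, 1000, 20, 1) + lorentzian(grid, 1100, 20, 0.8))
  s2 <- seed_peaks(two, c(900, 1200))
  expect_equal(nrow(s2), 2)
  expect_lt(abs(s2$center[1] - 1000), 3)
  expect_lt(abs(s2$center[2] - 1100), 3)

  expect_equal(nrow(seed_peaks(spec_from(rep(1, 751)), c(900, 1100))), 0)
})

test_that("a noiseless band seeded at truth is a fixed point of the fit", {
  grid <- canonical_grid()
  s <- spec_from(lorentzian(grid, 1000, 20, 1))
  seeds <- tibble::tibble(label = "b", center = 1000, fwhm = 20, height = 1)
  fit <- fit_lorentzians(s, c(900, 1100), seeds = seeds, baseline = "none")
  expect_true(fit$converged)
  expect_equal(fit$bands$center, 1000, tolerance = 1e-6)
  expect_equal(fit$bands$height, 1, tolerance = 1e-6)
  expect_equal(fit$bands$fwhm, 20, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-6 * max(s$intensity))
})

test_that("the fit recovers a band from a displaced seed", {
  grid <- canonical_grid()
  s <- spec_from(lorentzian(grid, 1000, 20, 1))
  seeds <- tibble::tibble(label = "b", center = 1010, fwhm = 20, height = 0.8)
  fit <- fit_lorentzians(s, c(900, 1100), seeds = seeds, baseline = "none")
  expect_lt(abs(fit$bands$center - 1000), 0.1)
})

test_that("amide III triplet centers are recovered under noise", {
  grid <- canonical_grid()
  clean <- lorentzian(grid, 1173, 22, 0.8) + lorentzian(grid, 1248, 22, 1) +
    lorentzian(grid, 1346, 24, 1.1)
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    s <- spec_from(clean + rnorm(length(grid), 0, 0.05)) # SNR ~20
    fit <- fit_lorentzians(s, c(1100, 1400),
      seeds = tibble::tibble(
        label = c("a", "b", "c"), center = c(1173, 1248, 1346),
        fwhm = c(22, 22, 24), height = c(0.8, 1, 1.1)
      ),
      baseline = "constant"
    )
    all(abs(sort(fit$bands$center) - c(1173, 1248, 1346)) < 2)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("adding a band never increases the residual", {
  grid <- canonical_grid()
  set.seed(31)
  s <- spec_from(lorentzian(grid, 1000, 20, 1) + lorentzian(grid, 1060, 25, 0.4) +
    rnorm(length(grid), 0, 0.02))
  one <- fit_lorentzians(s, c(930, 1130),
    seeds = tibble::tibble(label = "a", center = 1000, fwhm = 20, height = 1)
  )
  two <- fit_lorentzians(s, c(930, 1130),
    seeds = tibble::tibble(
      label = c("a", "b"), center = c(1000, 1060),
      fwhm = c(20, 25), height = c(1, 0.4)
    )
  )
  expect_lte(two$residual_rms, one$residual_rms + 1e-10)
})

test_that("band ratio follows its definition and its invariances", {
  grid <- canonical_grid()
  s <- spec_from(lorentzian(grid, 1243, 22, 1.0) + lorentzian(grid, 1342, 24, 1.1))
  fit <- fit_lorentzians(s, c(1180, 1400),
    seeds = tibble::tibble(
      label = c("d", "n"), center = c(1243, 1342),
      fwhm = c(22, 24), height = c(1, 1.1)
    ),
    baseline = "none"
  )
  r <- band_ratio(fit, n_boot = 0)
  expect_equal(r$value, 1.1, tolerance = 1e-4)
  # numerator and denominator the same band -> exactly 1
  same <- band_ratio(fit, num_target = 1243, den_target = 1243, n_boot = 0)
  expect_equal(same$value, 1)
  # invariance under global rescaling
  s4 <- spec_from(4 * s$intensity)
  fit4 <- fit_lorentzians(s4, c(1180, 1400),
    seeds = tibble::tibble(
      label = c("d", "n"), center = c(1243, 1342),
      fwhm = c(22, 24), height = c(4, 4.4)
    ),
    baseline = "none"
  )
  expect_equal(band_ratio(fit4, n_boot = 0)$value, r$value, tolerance = 1e-6)
  # missing band is an informative error
  expect_error(band_ratio(fit, num_target = 1500, n_boot = 0), "1500")
})

test_that("residual bootstrap produces a finite ratio uncertainty", {
  grid <- canonical_grid()
  set.seed(41)
  s <- spec_from(lorentzian(grid, 1243, 22, 1) + lorentzian(grid, 1342, 24, 1.1) +
    rnorm(length(grid), 0, 0.03))
  fit <- fit_lorentzians(s, c(1180, 1400),
    seeds = tibble::tibble(
      label = c("d", "n"), center = c(1243, 1342),
      fwhm = c(22, 24), height = c(1, 1.1)
    )
  )
  r <- band_ratio(fit, n_boot = 30, seed = 1)
  expect_gt(r$uncertainty, 0)
  expect_lt(r$uncertainty, 0.5)
})

test_that("fit preconditions are enforced", {
  grid <- canonical_grid()
  s <- spec_from(lorentzian(grid, 1000, 20, 1))
  expect_error(
    fit_lorentzians(s, c(900, 1100),
      seeds = tibble::tibble(label = "x", center = 1200, fwhm = 20, height = 1)
    ),
    "inside the fit region"
  )
  expect_error(fit_lorentzians(s, c(100, 200)), "outside the grid")
})
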