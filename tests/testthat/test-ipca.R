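test_that("the 22 standard intervals partition the full window", {
  iv <- default_intervals()
  expect_equal(nrow(iv), 22)
  expect_equal(c(iv$lo[1], iv$hi[1]), c(400, 455))
  expect_equal(c(iv$lo[22], iv$hi[22]), c(1801, 1900))
  # non-overlapping, ascending, integer-adjacent
  expect_true(all(diff(iv$lo) > 0))
  expect_true(all(iv$hi[-22] + 1 == iv$lo[-1]))
  # every canonical grid point falls in exactly one interval
  grid <- canonical_grid()
  counts <- rowSums(vapply(seq_len(22), function(i) {
    grid >= iv$lo[i] & grid < iv$hi[i] + 1
  }, logical(length(grid))))
  expect_true(all(counts == 1))
})

test_that("two-spectrum PCA has one component with scores +/- d/2", {
  grid <- seq(400, 430, 2)
  set.seed(3)
  a <- rnorm(16)
  b <- rnorm(16)
  s <- as_spectra(rbind(
    data.frame(subject_id = "a", wavenumber = grid, intensity = a),
    data.frame(subject_id = "b", wavenumber = grid, intensity = b)
  ))
  p <- spectra_pca(s)
  d <- sqrt(sum(((a - b))^2))
  expect_equal(ncol(p$scores), 1)
  expect_equal(sort(abs(p$scores[, 1])), rep(d / 2, 2), tolerance = 1e-10)
  expect_equal(sum(p$scores[, 1]), 0, tolerance = 1e-10)
})

test_that("identical spectra give zero explained variance", {
  grid <- seq(400, 430, 2)
  s <- as_spectra(rbind(
    data.frame(subject_id = "a", wavenumber = grid, intensity = 1:16),
    data.frame(subject_id = "b", wavenumber = grid, intensity = 1:16)
  ))
  p <- spectra_pca(s)
  expect_equal(p$explained_variance, 0, tolerance = 1e-20)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(11)
  for (rep in 1:5) {
    grid <- seq(400, 416, 2) # 9 points
    m <- matrix(rnorm(45), 5, 9) # 5 spectra x 9 points
    s <- tearspec:::matrix_to_spectra(
      grid,
      tibble::tibble(
        subject_id = paste0("s", 1:5), replicate_id = "r1",
        class_label = factor("UNKNOWN", levels = c("Ctr", "MCI", "AD", "UNKNOWN"))
      ),
      m
    )
    p <- spectra_pca(s)
    eig <- eigen(stats::cov(m), symmetric = TRUE)
    k <- ncol(p$loadings)
    expect_equal(p$explained_variance, eig$values[seq_len(k)], tolerance = 1e-8)
    for (j in seq_len(k)) {
      v <- eig$vectors[, j]
      piv <- which.max(abs(v))
      if (v[piv] < 0) v <- -v
      expect_equal(unname(p$loadings[, j]), v, tolerance = 1e-8)
    }
    # orthonormality and full reconstruction
    expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-8, ignore_attr = TRUE)
    rec <- sweep(p$scores %*% t(p$loadings), 2, p$mean_vector, "+")
    expect_equal(unname(rec), unname(m), tolerance = 1e-8)
  }
})

test_that("score tables pool interval PCAs with exact column provenance", {
  sim <- simulate_tears(default_profiles(n_subjects = c(Ctr = 4, MCI = 4, AD = 4)), seed = 8)
  subj <- average_replicates(preprocess_spectra(sim$spectra))
  tab <- build_score_table(subj)
  feats <- setdiff(names(tab), c("subject_id", "replicate_id", "class_label"))
  expect_length(feats, 22 * 7) # 154 columns
  # a sampled column equals the corresponding interval PCA score column
  p <- spectra_pca(subj, "1202-1307")
  expect_equal(tab[["1202-1307.PC3"]], unname(p$scores[, 3]), tolerance = 1e-10)
  # per-column zero mean and diagonal empirical covariance within an interval
  sc <- as.matrix(tab[, sprintf("1202-1307.PC%d", 1:7)])
  expect_equal(colMeans(sc), rep(0, 7), tolerance = 1e-10, ignore_attr = TRUE)
  cv <- stats::cov(sc)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(build_score_table(subj, n_pcs = 20), "infeasible")
})

test_that("feature screening ranks the truly differing band region first", {
  grid <- canonical_grid()
  set.seed(13)
  mk_class <- function(cl, shift) {
    do.call(rbind, lapply(1:6, function(i) {
      data.frame(
        subject_id = sprintf("%s%d", cl, i), class_label = cl,
        wavenumber = grid,
        intensity = lorentzian(grid, 1000, 20, 1 + shift) +
          lorentzian(grid, 1400, 24, 0.8) + rnorm(length(grid), 0, 0.03)
      )
    }))
  }
  s <- as_spectra(rbind(mk_class("Ctr", 0), mk_class("AD", 0.6)))
  sc <- screen_features(s)
  top_region <- attr(sc, "regions")[1, ]
  expect_true(top_region$lo <= 1010 && top_region$hi >= 990)

  # identical class means, unequal variances: criterion stays near zero
  mk_noise <- function(cl, sdv) {
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(
        subject_id = sprintf("%s%d", cl, i), class_label = cl,
        wavenumber = grid, intensity = rnorm(length(grid), 0, sdv)
      )
    }))
  }
  s0 <- as_spectra(rbind(mk_noise("Ctr", 0.5), mk_noise("AD", 1.5)))
  sc0 <- screen_features(s0)
  # permutation null threshold for the max |t| criterion
  expect_lt(median(sc0$stat), 2)
  expect_error(screen_features(as_spectra(mk_noise("Ctr", 1))), "two classes")
})

test_that("null-configuration screening stays below the permutation threshold", {
  cfg <- default_profiles(
    effect_scale = 0, n_subjects = c(Ctr = 6, AD = 6),
    subject_sd = c(Ctr = 0.12, MCI = 0.12, AD = 0.12)
  )
  sim <- simulate_tears(cfg, seed = 31)
  subj <- average_replicates(preprocess_spectra(sim$spectra))
  sc <- screen_features(subj)
  # permutation null for the maximum over the grid of |t|
  w <- tearspec:::spectra_matrix(subj)
  set.seed(32)
  null_max <- vapply(1:99, function(b) {
    labs <- sample(as.character(w$meta$class_label))
    a <- w$m[labs == "Ctr", , drop = FALSE]
    d <- w$m[labs == "AD", , drop = FALSE]
    sp2 <- ((nrow(a) - 1) * apply(a, 2, var) + (nrow(d) - 1) * apply(d, 2, var)) /
      (nrow(a) + nrow(d) - 2)
    max(abs(colMeans(a) - colMeans(d)) / sqrt(sp2 * (1 / nrow(a) + 1 / nrow(d))))
  }, 1)
  expect_lt(max(sc$stat), quantile(null_max, 0.99) * 1.05)
})
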