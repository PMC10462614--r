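# a small fitted encoding model on noiseless synthetic data, reused by
# the decoding blocks
fit_toy_model <- function(n_train = 40, n_vox = 8, noise_sd = 0,
                          seed = 1) {
  net <- scnn("character_natural", n_out = 6, seed = seed)
  stim <- generate_stimuli("glyphs", n_train, size = c(16, 16),
                           seed = seed + 1)
  feats <- scnn_features(net, stim)
  gt <- generate_voxels(n_vox, dim(feats)[-1], noise_sd = noise_sd,
                        seed = seed + 2)
  y <- simulate_responses(feats, gt, seed = seed + 3)$responses
  list(fit = fit_encoding(feats, y, seed = seed + 4, scnn = net),
       net = net, stim = stim, feats = feats, y = y, gt = gt)
}

test_that("noise covariance shrinks toward its diagonal", {
  set.seed(5)
  meas <- matrix(rnorm(30 * 5), 30, 5)
  pred <- meas + matrix(rnorm(30 * 5, 0, 0.3), 30, 5)
  # exact predictions: zero covariance at lambda = 0
  expect_equal(max(abs(estimate_noise_covariance(meas, meas, 0))), 0)
  # lambda = 1: diagonal of residual variances
  s1 <- estimate_noise_covariance(meas, pred, 1)
  expect_equal(s1, diag(apply(meas - pred, 2, var)), tolerance = 1e-12)
  # textbook sample covariance at lambda = 0
  r <- meas - pred
  s0 <- estimate_noise_covariance(meas, pred, 0)
  expect_equal(s0, cov(r), tolerance = 1e-12)
  # interpolation and symmetry
  s <- estimate_noise_covariance(meas, pred, 0.1)
  expect_equal(s, 0.9 * cov(r) + 0.1 * diag(diag(cov(r))),
               tolerance = 1e-12)
  expect_equal(s, t(s))
  expect_true(all(eigen(s, symmetric = TRUE)$values > -1e-12))
  expect_error(estimate_noise_covariance(meas[1, , drop = FALSE],
                                         pred[1, , drop = FALSE]),
               "trials")
})

test_that("Gaussian log-likelihood peaks at the prediction", {
  sigma <- diag(3)
  r <- c(1, 2, 3)
  expect_equal(log_likelihood(r, r, sigma), 0)
  # identity covariance: negative squared distance
  r2 <- r + c(1, -1, 2)
  expect_equal(log_likelihood(r2, r, sigma), -6)
  # non-diagonal toy against an explicit matrix inversion
  S <- matrix(c(2, 0.5, 0.1,
                0.5, 1.5, 0.2,
                0.1, 0.2, 1.0), 3, 3)
  d <- c(0.3, -0.7, 0.2)
  expect_equal(log_likelihood(r + d, r, S),
               -drop(t(d) %*% solve(S) %*% d), tolerance = 1e-12)
  # invariant under a simultaneous permutation of voxels
  p <- c(3, 1, 2)
  expect_equal(log_likelihood((r + d)[p], r[p], S[p, p]),
               log_likelihood(r + d, r, S), tolerance = 1e-12)
  expect_error(log_likelihood(r, r, matrix(0, 3, 3)), "singular")
})

test_that("diagonal-covariance ranking equals variance-weighted distance", {
  set.seed(9)
  v <- runif(6, 0.5, 2)
  sigma <- diag(v)
  r_obs <- rnorm(6)
  preds <- matrix(rnorm(10 * 6), 10, 6)
  ll <- apply(preds, 1, function(p) log_likelihood(r_obs, p, sigma))
  wd <- apply(preds, 1, function(p) sum((r_obs - p)^2 / v))
  expect_equal(order(-ll), order(wd))
  expect_equal(ll, -wd, tolerance = 1e-10)
})

test_that("reconstruction returns the true stimulus at zero noise", {
  toy <- fit_toy_model(n_train = 40, n_vox = 8, noise_sd = 0)
  vox <- select_top_voxels(toy$fit, 8)
  # shrinkage keeps the residual covariance (which is ~0 here) solvable
  sigma <- estimate_noise_covariance(
    toy$y[, vox], predict(toy$fit, toy$feats, voxels = vox), 0.1)
  sigma <- sigma + diag(1e-6, ncol(sigma))
  prior <- toy$stim  # the true stimulus is part of the prior set
  k <- 17
  r_obs <- toy$y[k, vox]
  rec <- reconstruct_image(toy$fit, r_obs, prior, sigma, voxels = vox,
                           top_n = 1)
  expect_equal(rec$ranked_ids[1], k)
  expect_identical(rec$reconstruction, prior[[k]])
  # the top-ranked likelihood dominates every other (brute force)
  expect_true(all(rec$log_likelihoods[rec$ranked_ids[1]] >=
                    rec$log_likelihoods))
  # identical prior images reconstruct to that image, any top_n
  same <- replicate(5, prior[[3]], simplify = FALSE)
  rec2 <- reconstruct_image(toy$fit, r_obs, same, sigma, voxels = vox,
                            top_n = 3)
  expect_equal(rec2$reconstruction, prior[[3]], tolerance = 1e-12)
  # top_n = n_prior averages the whole prior set regardless of r_obs
  recA <- reconstruct_image(toy$fit, r_obs, prior, sigma, voxels = vox,
                            top_n = length(prior))
  recB <- reconstruct_image(toy$fit, -5 * r_obs, prior, sigma,
                            voxels = vox, top_n = length(prior))
  expect_equal(recA$reconstruction, recB$reconstruction,
               tolerance = 1e-10)
  expect_equal(recA$reconstruction, Reduce(`+`, prior) / length(prior),
               tolerance = 1e-10)
  expect_error(reconstruct_image(toy$fit, r_obs, prior, sigma,
                                 voxels = vox, top_n = 99), "top_n")
})

test_that("identification is perfect at zero noise and degrades with noise", {
  toy <- fit_toy_model(n_train = 40, n_vox = 8, noise_sd = 0)
  net <- toy$net
  test_stim <- generate_stimuli("glyphs", 12, size = c(16, 16),
                                seed = 77)
  tf <- scnn_features(net, test_stim)
  clean <- simulate_responses(tf, toy$gt, seed = 78)$noiseless
  vox <- select_top_voxels(toy$fit, 8)
  # exact candidate match: correlation 1 for the matching candidate
  cand_pred <- predict(toy$fit, tf, voxels = vox)
  r <- identify_image(toy$fit, cand_pred[4, ], cand_pred = cand_pred,
                      voxels = vox)
  expect_equal(r$index, 4)
  expect_equal(r$correlations[4], 1, tolerance = 1e-12)
  # zero-noise identification accuracy is 100%
  acc0 <- identification_accuracy(toy$fit, clean, test_stim,
                                  voxels = vox)
  expect_equal(acc0$accuracy, 1)
  # accuracy decreases monotonically (allowing small MC wiggle) as the
  # noise grows past the signal scale
  sig_sd <- mean(apply(clean[, vox], 2, sd))
  accs <- sapply(c(0, 1, 4) * sig_sd, function(ns) {
    set.seed(123)
    noisy <- clean + matrix(rnorm(length(clean), 0, ns),
                            nrow(clean), ncol(clean))
    identification_accuracy(toy$fit, noisy, test_stim,
                            voxels = vox)$accuracy
  })
  expect_true(all(diff(accs) <= 0.1))
  expect_lt(accs[3], accs[1])
})

test_that("reconstruction metrics respond to shift and inversion", {
  set.seed(4)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  m <- evaluate_reconstruction(img, img)
  expect_equal(unname(m["pcc"]), 1, tolerance = 1e-12)
  expect_equal(unname(m["ssim"]), 1, tolerance = 1e-12)
  # constant shift: correlation stays 1, SSIM drops
  shifted <- evaluate_reconstruction(img + 40, img)
  expect_equal(unname(shifted["pcc"]), 1, tolerance = 1e-12)
  expect_lt(unname(shifted["ssim"]), 1)
  # checkerboard against its inverse: perfectly anticorrelated
  cb <- matrix(rep(c(0, 255), 32 * 16), 32, 32)
  inv <- 255 - cb
  expect_equal(unname(evaluate_reconstruction(cb, inv)["pcc"]), -1,
               tolerance = 1e-12)
  # small images fall back to the global window
  tiny <- matrix(runif(25, 0, 255), 5, 5)
  expect_equal(ssim(tiny, tiny), 1, tolerance = 1e-12)
  expect_error(evaluate_reconstruction(img, img[1:10, 1:10]),
               "dimension")
})
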