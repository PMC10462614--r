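#' Noise standard deviation from repeated presentations
#'
#' Assumes observed signal = response + zero-mean Gaussian noise.
#' The noise sd is estimated as the square root of the mean (over test
#' images) of the across-repeat response variance.
#'
#' @param rr repeated responses: numeric array
#'   (n_images, n_repeats, n_voxels), e.g. 35 repeats per test image.
#' @param voxel voxel index (or omit to get all voxels).
#' @return estimated noise sd (scalar, or vector over voxels).
#' @export
estimate_noise_sd <- function(rr, voxel = NULL) {
  d <- dim(rr)
  stopifnot(length(d) == 3L)
  if (d[2] < 2) stop("need at least 2 repeats per image")
  one <- function(v) sqrt(mean(apply(rr[, , v, drop = FALSE], 1,
                                     stats::var)))
  if (is.null(voxel)) vapply(seq_len(d[3]), one, numeric(1)) else one(voxel)
}

#' Response variance from repeated presentations
#'
#' Variance of the per-image mean response minus the estimated noise
#' variance. By default the subtraction uses the full noise variance
#' (the field's conventional formula); `correct_repeats = TRUE` divides
#' the noise variance by the repeat count, which is the variance a mean
#' of `n_repeats` noisy repeats actually carries. Negative estimates
#' (noise-dominated voxels) are clipped to 0 with a warning.
#'
#' @inheritParams estimate_noise_sd
#' @param correct_repeats divide the subtracted noise variance by the
#'   repeat count (default FALSE).
#' @return estimated response variance (scalar or vector, >= 0).
#' @export
estimate_response_variance <- function(rr, voxel = NULL,
                                       correct_repeats = FALSE) {
  d <- dim(rr)
  stopifnot(length(d) == 3L)
  if (d[2] < 2) stop("need at least 2 repeats per image")
  one <- function(v) {
    mu <- rowMeans(rr[, , v, drop = FALSE][, , 1])
    s2n <- mean(apply(rr[, , v, drop = FALSE], 1, stats::var))
    if (correct_repeats) s2n <- s2n / d[2]
    stats::var(mu) - s2n
  }
  out <- if (is.null(voxel)) vapply(seq_len(d[3]), one, numeric(1))
         else one(voxel)
  if (any(out < 0)) {
    warning("negative response variance clipped to 0 ",
            "(noise-dominated voxel)")
    out <- pmax(out, 0)
  }
  out
}

#' Monte-Carlo noise ceiling
#'
#' Simulates the upper bound on encoding accuracy given the estimated
#' response and noise variances: in each of `n_sims` simulations,
#' responses `~ N(0, sigma2_r)` and noise `~ N(0, sigma2_n)` are drawn
#' for `n_images` test images, and the Pearson correlation between
#' signal (= response + noise) and response is computed. The mean
#' correlation over simulations is the noise ceiling; it converges to
#' the closed form `sigma_r / sqrt(sigma_r^2 + sigma_n^2)` and is 1
#' exactly when `sigma2_n = 0`.
#'
#' @param sigma2_r response variance (>= 0).
#' @param sigma2_n noise variance (>= 0); not both zero.
#' @param n_images number of test images per simulation (>= 3).
#' @param n_sims number of simulations (default 1000).
#' @param seed RNG seed.
#' @return scalar noise ceiling in \[-1, 1\] (typically \[0, 1\]).
#' @export
simulate_noise_ceiling <- function(sigma2_r, sigma2_n, n_images,
                                   n_sims = 1000L, seed = 1L) {
  stopifnot(sigma2_r >= 0, sigma2_n >= 0)
  if (sigma2_r == 0 && sigma2_n == 0)
    stop("response and noise variance cannot both be zero")
  if (n_images < 3) stop("need at least 3 images")
  if (sigma2_n == 0) return(1)
  with_seed(seed, {
    mean(vapply(seq_len(n_sims), function(s) {
      resp <- stats::rnorm(n_images, 0, sqrt(sigma2_r))
      noise <- stats::rnorm(n_images, 0, sqrt(sigma2_n))
      if (stats::sd(resp) == 0) 0 else stats::cor(resp + noise, resp)
    }, numeric(1)))
  })
}

#' Per-voxel noise ceilings from repeated responses
#'
#' Convenience wrapper chaining [estimate_noise_sd()],
#' [estimate_response_variance()] and [simulate_noise_ceiling()] for
#' every voxel of a repeated-presentation array.
#'
#' @inheritParams estimate_noise_sd
#' @inheritParams simulate_noise_ceiling
#' @inheritParams estimate_response_variance
#' @return numeric vector of per-voxel ceilings.
#' @export
noise_ceiling <- function(rr, n_sims = 1000L, seed = 1L,
                          correct_repeats = FALSE) {
  d <- dim(rr)
  stopifnot(length(d) == 3L)
  sn <- estimate_noise_sd(rr)
  sr <- suppressWarnings(
    estimate_response_variance(rr, correct_repeats = correct_repeats))
  vapply(seq_len(d[3]), function(v) {
    if (sr[v] == 0 && sn[v] == 0) return(NA_real_)
    simulate_noise_ceiling(sr[v], sn[v]^2, n_images = d[1],
                           n_sims = n_sims, seed = seed + v)
  }, numeric(1))
}
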