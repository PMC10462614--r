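#' Noise covariance of the encoding residuals
#'
#' Sample covariance of the measured-minus-predicted training responses,
#' with diagonal shrinkage: `Sigma = (1 - lambda) * S + lambda * diag(S)`.
#' With a few hundred trials and hundreds of voxels the raw sample
#' covariance is ill-conditioned; a small shrinkage keeps the Gaussian
#' likelihood solvable without changing the ranking much.
#'
#' @param meas,pred matrices (n_trials, n_voxels) of measured and
#'   predicted training responses.
#' @param shrinkage shrinkage weight lambda in \[0, 1\] (default 0.1).
#' @return symmetric PSD matrix (n_voxels x n_voxels).
#' @export
estimate_noise_covariance <- function(meas, pred, shrinkage = 0.1) {
  meas <- as.matrix(meas); pred <- as.matrix(pred)
  if (!all(dim(meas) == dim(pred))) stop("shape mismatch")
  if (nrow(meas) < 2) stop("need at least 2 trials")
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  S <- stats::cov(meas - pred)
  (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(S))
}

#' Gaussian log-likelihood of an observed response
#'
#' Log of the multivariate Gaussian likelihood (up to an additive
#' constant) of observing response `r` when the predicted response is
#' `r_hat` with noise covariance `sigma`:
#' `-(r - r_hat)' sigma^{-1} (r - r_hat)`, computed via a Cholesky solve.
#' Maximal (zero) exactly when the observed and predicted responses
#' coincide.
#'
#' @param r observed response vector.
#' @param r_hat predicted response vector.
#' @param sigma noise covariance (see [estimate_noise_covariance()]).
#' @return scalar log-likelihood (non-positive).
#' @export
log_likelihood <- function(r, r_hat, sigma) {
  d <- as.numeric(r - r_hat)
  if (length(d) != ncol(sigma)) stop("dimension mismatch")
  R <- tryCatch(chol(sigma), error = function(e)
    stop("noise covariance is singular; increase the shrinkage"))
  z <- forwardsolve(t(R), d)
  -sum(z^2)
}

#' Reconstruct a stimulus from an observed response
#'
#' Selection-and-averaging reconstruction over a prior image set: every
#' prior image is scored by the Gaussian log-likelihood of the observed
#' response given the image's predicted response, and the pixel arrays
#' of the `top_n` best-scoring images are averaged.
#'
#' @param model a fitted [fit_encoding()] model.
#' @param r_obs observed response vector over the selected voxels.
#' @param prior list of prior stimulus matrices, or a precomputed matrix
#'   (n_prior x n_voxels) of their predicted responses via
#'   `prior_pred`.
#' @param sigma noise covariance over the selected voxels.
#' @param voxels voxel ids defining the response space (default: top 200
#'   by training CV R², the reconstruction convention).
#' @param top_n number of prior images averaged (default 15).
#' @param prior_pred optional precomputed predicted responses for the
#'   prior set (n_prior x length(voxels)); skips feature extraction.
#' @return object of class `"scnn_reconstruction"`: list with
#'   `reconstruction` (stimulus matrix), `ranked_ids` (prior indices,
#'   best first) and `log_likelihoods`.
#' @export
reconstruct_image <- function(model, r_obs, prior, sigma,
                              voxels = NULL, top_n = 15L,
                              prior_pred = NULL) {
  stopifnot(inherits(model, "scnn_encoding"))
  if (is.null(voxels))
    voxels <- select_top_voxels(model, min(200L, nrow(model$voxels)))
  if (is.null(prior_pred)) {
    if (length(prior) < 1) stop("empty prior image set")
    prior_pred <- predict(model, prior, voxels = voxels)
  }
  n_prior <- nrow(prior_pred)
  if (top_n > n_prior)
    stop("top_n (", top_n, ") exceeds the prior set size (", n_prior, ")")
  r_obs <- as.numeric(r_obs)
  ll <- vapply(seq_len(n_prior), function(s)
    log_likelihood(r_obs, prior_pred[s, ], sigma), numeric(1))
  ranked <- order(-ll, seq_len(n_prior))
  top <- ranked[seq_len(top_n)]
  recon <- Reduce(`+`, prior[top]) / top_n
  structure(list(reconstruction = recon, ranked_ids = ranked,
                 log_likelihoods = ll, top_n = top_n, voxels = voxels),
            class = "scnn_reconstruction")
}

#' @export
print.scnn_reconstruction <- function(x, ...) {
  cat("Reconstruction from ", length(x$log_likelihoods),
      " prior images (top ", x$top_n, " averaged, ",
      length(x$voxels), " voxels)\n", sep = "")
  cat("  best prior index:", x$ranked_ids[1], "\n")
  invisible(x)
}

#' @export
plot.scnn_reconstruction <- function(x, ...) {
  img <- x$reconstruction
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, main = "reconstruction", ...)
  invisible(x)
}

#' Identify the viewed image by predicted-response correlation
#'
#' Scores every candidate image by the Pearson correlation between the
#' observed response and the candidate's predicted response over the
#' selected voxels; the highest-correlation candidate is the
#' identification (ties: lowest index). Candidates whose predicted
#' response has zero variance are scored `-Inf`.
#'
#' @param model a fitted [fit_encoding()] model.
#' @param r_obs observed response vector over the selected voxels.
#' @param candidates list of candidate stimulus matrices, or `NULL` when
#'   `cand_pred` is given.
#' @param voxels voxel ids defining the response space (default: top 500
#'   by training CV R², the identification convention).
#' @param cand_pred optional precomputed predicted responses
#'   (n_candidates x length(voxels)).
#' @return list with `index` (identified candidate) and `correlations`
#'   (the full score vector, one row of the identification matrix).
#' @export
identify_image <- function(model, r_obs, candidates = NULL,
                           voxels = NULL, cand_pred = NULL) {
  stopifnot(inherits(model, "scnn_encoding"))
  if (is.null(voxels))
    voxels <- select_top_voxels(model, min(500L, nrow(model$voxels)))
  if (length(voxels) < 3) stop("need at least 3 voxels")
  if (is.null(cand_pred)) {
    if (length(candidates) < 2) stop("need at least 2 candidates")
    cand_pred <- predict(model, candidates, voxels = voxels)
  }
  if (nrow(cand_pred) < 2) stop("need at least 2 candidates")
  r_obs <- as.numeric(r_obs)
  cors <- apply(cand_pred, 1, function(p)
    if (stats::sd(p) == 0 || stats::sd(r_obs) == 0) -Inf
    else stats::cor(r_obs, p))
  list(index = which.max(cors), correlations = cors)
}

#' Identification accuracy over a test set
#'
#' Runs [identify_image()] for every test trial against the full test
#' image set and reports the fraction of correct identifications plus
#' the trial-by-candidate correlation matrix.
#'
#' @param model a fitted [fit_encoding()] model.
#' @param responses matrix (n_trials, n_voxels_all) of observed test
#'   responses (columns named by voxel id).
#' @param images list of the candidate stimuli, trial k's true image at
#'   position k.
#' @param voxels voxel ids (default: top 500).
#' @return list with `accuracy`, `identified` (indices) and
#'   `correlations` (n_trials x n_candidates matrix).
#' @export
identification_accuracy <- function(model, responses, images,
                                    voxels = NULL) {
  stopifnot(inherits(model, "scnn_encoding"))
  if (is.null(voxels))
    voxels <- select_top_voxels(model, min(500L, nrow(model$voxels)))
  cand_pred <- predict(model, images, voxels = voxels)
  Y <- as.matrix(responses)[, voxels, drop = FALSE]
  n <- nrow(Y)
  cors <- matrix(NA_real_, n, nrow(cand_pred))
  idx <- integer(n)
  for (k in seq_len(n)) {
    r <- identify_image(model, Y[k, ], cand_pred = cand_pred,
                        voxels = voxels)
    cors[k, ] <- r$correlations
    idx[k] <- r$index
  }
  list(accuracy = mean(idx == seq_len(n)), identified = idx,
       correlations = cors)
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`
#' (`K = (0.01, 0.03)`, dynamic range `L = 255`). The default window
#' policy is the usual 11x11 Gaussian (sd 1.5), averaged over the valid
#' region; `window = "global"` computes a single SSIM over the whole
#' image (used for very small images).
#'
#' @param x,y image matrices on the \[0, 255\] scale.
#' @param L dynamic range (default 255).
#' @param K the two stabilising constants (default `c(0.01, 0.03)`).
#' @param window `"gaussian"` or `"global"`.
#' @param win_size,win_sigma Gaussian window size and sd.
#' @return scalar SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y, L = 255, K = c(0.01, 0.03),
                 window = c("gaussian", "global"),
                 win_size = 11L, win_sigma = 1.5) {
  window <- match.arg(window)
  if (!all(dim(x) == dim(y))) stop("dimension mismatch")
  C1 <- (K[1] * L)^2; C2 <- (K[2] * L)^2
  if (window == "global" || any(dim(x) < win_size)) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  g <- exp(-((seq_len(win_size) - (win_size + 1) / 2)^2) /
             (2 * win_sigma^2))
  g <- g / sum(g)
  smooth <- function(m) {
    # separable Gaussian filter, valid region
    m1 <- apply(m, 2, function(col) stats::filter(col, g, sides = 2))
    m2 <- t(apply(m1, 1, function(row) stats::filter(row, g, sides = 2)))
    half <- (win_size - 1) / 2
    m2[(half + 1):(nrow(m2) - half), (half + 1):(ncol(m2) - half)]
  }
  mx <- smooth(x); my <- smooth(y)
  sxx <- smooth(x * x) - mx^2
  syy <- smooth(y * y) - my^2
  sxy <- smooth(x * y) - mx * my
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(smap)
}

#' Evaluate a reconstruction against the true stimulus
#'
#' @param recon,truth stimulus matrices of equal size.
#' @param ... passed to [ssim()].
#' @return named numeric vector `c(pcc, ssim)`: pixelwise Pearson
#'   correlation and structural similarity.
#' @export
evaluate_reconstruction <- function(recon, truth, ...) {
  if (!all(dim(recon) == dim(truth))) stop("dimension mismatch")
  c(pcc = stats::cor(as.vector(recon), as.vector(truth)),
    ssim = ssim(recon, truth, ...))
}
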