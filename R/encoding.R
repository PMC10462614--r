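#' Feature vectors at one map location
#'
#' Slices the per-trial feature volumes at a single spatial location,
#' giving the design matrix for that candidate receptive field.
#'
#' @param features numeric array (n_trials, channels, h, w), e.g. from
#'   [scnn_features()].
#' @param loc integer `c(i, j)`, 1-based row/column into the feature map.
#' @return numeric matrix (n_trials, channels).
#' @export
feature_vectors_at <- function(features, loc) {
  d <- dim(features)
  stopifnot(length(d) == 4L, length(loc) == 2L)
  if (loc[1] < 1 || loc[1] > d[3] || loc[2] < 1 || loc[2] > d[4])
    stop("location (", loc[1], ",", loc[2], ") outside the ",
         d[3], "x", d[4], " feature map")
  matrix(features[, , loc[1], loc[2]], d[1], d[2])
}

# seeded shuffle, then contiguous blocks: fold id per trial
cv_folds <- function(n, folds, seed) {
  stopifnot(n >= 2 * folds)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  rem <- n %% folds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(folds), sizes)
  fold
}

# OLS on (X, Y) with intercept column already included in X; falls back
# to a tiny ridge penalty when the normal equations are singular.
ols_multi <- function(X, Y) {
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  # pivoted Cholesky detects rank deficiency without erroring
  Rp <- suppressWarnings(chol(XtX, pivot = TRUE))
  ridge <- attr(Rp, "rank") < ncol(X)
  R <- if (ridge) NULL else tryCatch(chol(XtX), error = function(e) NULL)
  ridge <- ridge || is.null(R)
  if (ridge) {
    lambda <- 1e-8 * mean(diag(XtX))
    if (lambda <= 0) lambda <- 1e-8
    R <- chol(XtX + diag(lambda, ncol(X)))
  }
  list(beta = backsolve(R, forwardsolve(t(R), XtY)), ridge = ridge)
}

# pooled out-of-fold predictions for one design matrix over all voxels
oof_predict <- function(X, Y, fold, intercept) {
  Xd <- if (intercept) cbind(1, X) else X
  P <- matrix(NA_real_, nrow(Y), ncol(Y))
  ridge <- FALSE
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- ols_multi(Xd[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    ridge <- ridge || fit$ridge
    P[!tr, ] <- Xd[!tr, , drop = FALSE] %*% fit$beta
  }
  list(pred = P, ridge = ridge)
}

#' Cross-validated R-squared of a linear readout
#'
#' Threefold (by default) cross-validation: folds are contiguous blocks
#' of a seeded shuffle; an ordinary-least-squares model (with intercept
#' unless disabled) is fitted per fold, and R² is computed on the pooled
#' out-of-fold predictions, `1 - SS_res / SS_tot`. A zero-variance
#' target is scored 0. Rank-deficient fold designs fall back to a tiny
#' ridge penalty, flagged in the `"ridge"` attribute.
#'
#' @param X design matrix (n x p).
#' @param y response vector.
#' @param folds number of folds (default 3).
#' @param seed seed for the fold shuffle.
#' @param intercept include an intercept (default TRUE).
#' @return numeric R² (<= 1) with attribute `"ridge"`.
#' @export
cross_validated_r2 <- function(X, y, folds = 3L, seed = 1L,
                               intercept = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  fold <- cv_folds(length(y), folds, seed)
  sstot <- sum((y - mean(y))^2)
  o <- oof_predict(X, cbind(y), fold, intercept)
  r2 <- if (sstot == 0) 0 else 1 - sum((o$pred[, 1] - y)^2) / sstot
  structure(r2, ridge = o$ridge)
}

#' Fit a receptive-field encoding model
#'
#' The core model of the package. Each voxel's response is a linear
#' readout of the feature vector at a single location of the spiking
#' network's feature maps:
#' \deqn{y_v = w_v \cdot f_{ij} + b_v + \epsilon}
#' For every voxel, all `h x w` map locations are scanned; at each, a
#' linear model is scored by k-fold cross-validated R² on the training
#' trials ([cross_validated_r2()]), and the location with the highest R²
#' (ties: smallest row, then column) becomes the voxel's receptive
#' field. The readout is then refitted on all training trials at that
#' location.
#'
#' @param features numeric array (n_trials, channels, h, w) of feature
#'   volumes, from [scnn_features()].
#' @param responses numeric matrix (n_trials, n_voxels); column names are
#'   used as voxel ids.
#' @param folds cross-validation folds (default 3).
#' @param seed seed for the fold shuffle.
#' @param intercept include an intercept in the readout (default TRUE;
#'   set `FALSE` for the strict zero-intercept form).
#' @param scnn optional trained [scnn()] attached to the model so that
#'   [predict.scnn_encoding()] can accept raw stimuli.
#' @return object of class `"scnn_encoding"`: list with
#'   \describe{
#'     \item{voxels}{data frame: `voxel_id`, `i`, `j`, `cv_r2`, `ridge`}
#'     \item{weights}{matrix (n_voxels x channels)}
#'     \item{intercepts}{numeric vector}
#'     \item{sigma}{per-voxel training residual sd}
#'     \item{fitted}{training-set fitted values}
#'   }
#' @examples
#' \donttest{
#' net <- scnn("character_natural", n_out = 8, seed = 1)
#' stim <- generate_stimuli("glyphs", 60, size = c(16, 16), seed = 2)
#' feats <- scnn_features(net, stim)
#' gt <- generate_voxels(5, dim(feats)[-1], noise_sd = 0.1, seed = 3)
#' y <- simulate_responses(feats, gt, seed = 4)$responses
#' fit <- fit_encoding(feats, y, seed = 5)
#' summary(fit)
#' }
#' @export
fit_encoding <- function(features, responses, folds = 3L, seed = 1L,
                         intercept = TRUE, scnn = NULL) {
  d <- dim(features)
  stopifnot(length(d) == 4L)
  Y <- as.matrix(responses)
  if (!all(is.finite(Y))) stop("responses contain non-finite values")
  n <- d[1]; h <- d[3]; w <- d[4]; V <- ncol(Y)
  if (nrow(Y) != n) stop("responses and features disagree on trial count")
  if (n < 2 * folds)
    stop("need at least ", 2 * folds, " trials for ", folds, "-fold CV")
  ids <- colnames(Y)
  if (is.null(ids)) ids <- sprintf("v%04d", seq_len(V))

  fold <- cv_folds(n, folds, seed)
  mu <- colMeans(Y)
  sstot <- colSums(sweep(Y, 2, mu)^2)

  best_r2 <- rep(-Inf, V)
  best_i <- integer(V); best_j <- integer(V)
  best_ridge <- logical(V)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      X <- matrix(features[, , i, j], n, d[2])
      o <- oof_predict(X, Y, fold, intercept)
      ssres <- colSums((o$pred - Y)^2)
      r2 <- ifelse(sstot == 0, 0, 1 - ssres / sstot)
      upd <- r2 > best_r2  # strict: ties keep the earlier (smaller) location
      if (any(upd)) {
        best_r2[upd] <- r2[upd]
        best_i[upd] <- i; best_j[upd] <- j
        best_ridge[upd] <- o$ridge
      }
    }
  }

  # refit on all training trials at each voxel's chosen location
  W <- matrix(0, V, d[2])
  b <- numeric(V)
  fitted <- matrix(NA_real_, n, V, dimnames = list(NULL, ids))
  for (loc in unique(paste(best_i, best_j))) {
    vs <- which(paste(best_i, best_j) == loc)
    i <- best_i[vs[1]]; j <- best_j[vs[1]]
    X <- matrix(features[, , i, j], n, d[2])
    Xd <- if (intercept) cbind(1, X) else X
    fit <- ols_multi(Xd, Y[, vs, drop = FALSE])
    beta <- fit$beta
    if (intercept) {
      b[vs] <- beta[1, ]
      W[vs, ] <- t(beta[-1, , drop = FALSE])
    } else {
      W[vs, ] <- t(beta)
    }
    fitted[, vs] <- Xd %*% beta
  }
  sigma <- sqrt(colSums((Y - fitted)^2) / max(n - ncol(W) - intercept, 1))

  structure(list(
    voxels = data.frame(voxel_id = ids, i = best_i, j = best_j,
                        cv_r2 = best_r2, ridge = best_ridge,
                        stringsAsFactors = FALSE),
    weights = W, intercepts = b, sigma = sigma, fitted = fitted,
    map_shape = d[-1], folds = folds, seed = seed,
    intercept = intercept, n_trials = n, scnn = scnn,
    residuals = Y - fitted),
    class = "scnn_encoding")
}

#' Locate one voxel's receptive field
#'
#' Single-voxel convenience wrapper around [fit_encoding()]: scans every
#' feature-map location, picks the one with the highest cross-validated
#' R², and refits the readout there on all trials.
#'
#' @inheritParams fit_encoding
#' @param y response vector for one voxel.
#' @return list with `rf_location` (`c(i, j)`), `weights`, `intercept`,
#'   `cv_r2`, `ridge`.
#' @export
annotate_receptive_field <- function(features, y, folds = 3L, seed = 1L,
                                     intercept = TRUE) {
  fit <- fit_encoding(features, cbind(v = y), folds = folds, seed = seed,
                      intercept = intercept)
  list(rf_location = c(fit$voxels$i[1], fit$voxels$j[1]),
       weights = fit$weights[1, ], intercept = fit$intercepts[1],
       cv_r2 = fit$voxels$cv_r2[1], ridge = fit$voxels$ridge[1])
}

#' @export
print.scnn_encoding <- function(x, ...) {
  cat("Receptive-field encoding model: ", nrow(x$voxels), " voxels, ",
      x$map_shape[1], " channels, ", x$map_shape[2], "x", x$map_shape[3],
      " feature map\n", sep = "")
  cat("  fitted on ", x$n_trials, " trials, ", x$folds,
      "-fold CV (seed ", x$seed, "), intercept ",
      if (x$intercept) "on" else "off", "\n", sep = "")
  cat("  cross-validated R2: median ",
      signif(stats::median(x$voxels$cv_r2), 3), ", max ",
      signif(max(x$voxels$cv_r2), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.scnn_encoding <- function(object, ...) {
  s <- list(n_voxels = nrow(object$voxels),
            r2 = summary(object$voxels$cv_r2),
            n_ridge = sum(object$voxels$ridge),
            locations = table(paste0("(", object$voxels$i, ",",
                                     object$voxels$j, ")")))
  class(s) <- "summary.scnn_encoding"
  s
}

#' @export
print.summary.scnn_encoding <- function(x, ...) {
  cat("Encoding model over", x$n_voxels, "voxels\n")
  cat("cross-validated R2:\n"); print(x$r2)
  if (x$n_ridge > 0)
    cat(x$n_ridge, "voxel(s) used the ridge fallback\n")
  cat("distinct receptive-field locations:", length(x$locations), "\n")
  invisible(x)
}

#' @export
coef.scnn_encoding <- function(object, ...) {
  cf <- cbind(`(Intercept)` = object$intercepts, object$weights)
  rownames(cf) <- object$voxels$voxel_id
  if (!object$intercept) cf <- cf[, -1, drop = FALSE]
  cf
}

#' @export
fitted.scnn_encoding <- function(object, ...) object$fitted

#' @export
residuals.scnn_encoding <- function(object, ...) object$residuals

#' Predict voxel responses for new stimuli
#'
#' @param object a fitted [fit_encoding()] model.
#' @param newdata feature array (n, channels, h, w), a list of stimulus
#'   matrices (requires the model to carry its `scnn`), or `NULL` for
#'   the training fitted values.
#' @param voxels optional character vector of voxel ids to predict.
#' @param ... unused.
#' @return matrix (n_trials, n_voxels) of predicted responses.
#' @export
predict.scnn_encoding <- function(object, newdata = NULL, voxels = NULL,
                                  ...) {
  if (is.null(newdata)) {
    P <- object$fitted
    return(if (is.null(voxels)) P else P[, voxels, drop = FALSE])
  }
  if (is.list(newdata)) {
    if (is.null(object$scnn))
      stop("model carries no scnn; supply a feature array instead")
    newdata <- scnn_features(object$scnn, newdata)
  }
  d <- dim(newdata)
  if (length(d) != 4L || !all(d[-1] == object$map_shape))
    stop("newdata must be a feature array with map shape (",
         paste(object$map_shape, collapse = ", "), ")")
  vsel <- if (is.null(voxels)) seq_len(nrow(object$voxels))
          else match(voxels, object$voxels$voxel_id)
  if (anyNA(vsel)) stop("unknown voxel id(s)")
  P <- matrix(NA_real_, d[1], length(vsel),
              dimnames = list(NULL, object$voxels$voxel_id[vsel]))
  key <- paste(object$voxels$i[vsel], object$voxels$j[vsel])
  for (loc in unique(key)) {
    ks <- which(key == loc)
    vs <- vsel[ks]
    i <- object$voxels$i[vs[1]]; j <- object$voxels$j[vs[1]]
    X <- matrix(newdata[, , i, j], d[1], d[2])
    P[, ks] <- sweep(X %*% t(object$weights[vs, , drop = FALSE]),
                     2, object$intercepts[vs], `+`)
  }
  P
}

#' Simulate responses from a fitted encoding model
#'
#' Draws `nsim` noisy response matrices: predicted responses plus
#' independent Gaussian noise with each voxel's training residual sd
#' (the generative model the fit assumes).
#'
#' @param object a fitted [fit_encoding()] model.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed.
#' @param newdata passed to [predict.scnn_encoding()] (default: training
#'   fitted values).
#' @param ... unused.
#' @return list of `nsim` response matrices.
#' @export
simulate.scnn_encoding <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, ...) {
  P <- predict(object, newdata)
  draw <- function() P + matrix(stats::rnorm(length(P), 0,
                                             rep(object$sigma,
                                                 each = nrow(P))),
                                nrow(P), ncol(P))
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  sims
}

#' @export
plot.scnn_encoding <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$voxels$cv_r2, breaks = 20, main = "CV R2",
                 xlab = expression(R^2))
  graphics::plot(x$voxels$j, x$voxels$i, pch = 16,
                 cex = 0.6, xlim = c(1, x$map_shape[3]),
                 ylim = c(x$map_shape[2], 1),
                 xlab = "map column", ylab = "map row",
                 main = "receptive-field locations", ...)
  invisible(x)
}

#' Per-voxel encoding accuracy (Pearson correlation)
#'
#' @param pred,meas matrices (n_trials, n_voxels) of predicted and
#'   measured responses.
#' @return numeric vector of per-voxel Pearson correlations; voxels with
#'   a constant predicted or measured series score 0, with a warning.
#' @export
encoding_accuracy <- function(pred, meas) {
  pred <- as.matrix(pred); meas <- as.matrix(meas)
  if (!all(dim(pred) == dim(meas))) stop("shape mismatch")
  if (nrow(pred) < 3) stop("need at least 3 trials")
  out <- numeric(ncol(pred))
  const <- FALSE
  for (v in seq_len(ncol(pred))) {
    if (stats::sd(pred[, v]) == 0 || stats::sd(meas[, v]) == 0) {
      out[v] <- 0; const <- TRUE
    } else out[v] <- stats::cor(pred[, v], meas[, v])
  }
  if (const) warning("constant series scored as correlation 0")
  names(out) <- colnames(meas)
  out
}

#' Select the best-encoded voxels
#'
#' Ranks voxels by their training cross-validated R² (the train-set
#' criterion, avoiding test-set circularity) and returns the top `k` ids
#' in descending score order, ties broken by voxel id.
#'
#' @param model a fitted [fit_encoding()] model.
#' @param k number of voxels (paper conventions: 500 for identification,
#'   200 for reconstruction).
#' @return character vector of voxel ids, best first.
#' @export
select_top_voxels <- function(model, k) {
  stopifnot(inherits(model, "scnn_encoding"))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(model$voxels)) stop("k exceeds the number of voxels")
  ord <- order(-model$voxels$cv_r2, model$voxels$voxel_id)
  model$voxels$voxel_id[ord][seq_len(k)]
}
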