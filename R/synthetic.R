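# stroke rendering: intensity `amp` within `thick/2` of the segment
# p0 -> p1, on a zero background
render_segment <- function(size, p0, p1, thick, amp) {
  yy <- matrix(seq_len(size[1]), size[1], size[2])
  xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  dx <- p1[2] - p0[2]; dy <- p1[1] - p0[1]
  len2 <- dx^2 + dy^2
  tt <- if (len2 == 0) 0 else
    pmin(pmax(((xx - p0[2]) * dx + (yy - p0[1]) * dy) / len2, 0), 1)
  d2 <- (xx - (p0[2] + tt * dx))^2 + (yy - (p0[1] + tt * dy))^2
  ifelse(d2 <= (thick / 2)^2, amp, 0)
}

#' Generate synthetic visual stimuli
#'
#' Deterministic (seeded) stimulus generators standing in for the
#' handwritten-character and natural-image material the encoding model
#' is used with:
#'
#' * `"bars"` — one high-contrast oriented bar per image, orientation
#'   drawn uniformly from 0/45/90/135 degrees with positional jitter;
#'   drives center-surround filtering and STDP feature learning.
#' * `"blobs"` — 1-3 Gaussian luminance bumps, smooth low-frequency
#'   structure.
#' * `"glyphs"` — 2-4 jittered strokes composed like handwritten
#'   characters (random orientation, length, thickness, position).
#'
#' All images are `size` matrices with values in \[0, 255\]. Bar images
#' carry an `"orientation"` attribute (degrees, per image).
#'
#' @param kind `"bars"`, `"blobs"` or `"glyphs"`.
#' @param n number of images.
#' @param size `c(H, W)` (default 56 x 56, the handwritten-character
#'   scale).
#' @param seed RNG seed; same seed, same images.
#' @return list of `n` stimulus matrices.
#' @export
generate_stimuli <- function(kind = c("bars", "blobs", "glyphs"), n,
                             size = c(56L, 56L), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  size <- as.integer(size)
  mindim <- min(size)
  with_seed(seed, {
    out <- vector("list", n)
    oris <- numeric(n)
    for (im in seq_len(n)) {
      if (kind == "bars") {
        ori <- sample(c(0, 45, 90, 135), 1)
        oris[im] <- ori
        th <- ori * pi / 180
        ctr <- size / 2 + stats::runif(2, -mindim / 5, mindim / 5)
        half <- mindim * 0.45
        dir <- c(sin(th), cos(th))  # (dy, dx)
        p0 <- ctr - half * dir; p1 <- ctr + half * dir
        thick <- stats::runif(1, mindim / 14, mindim / 8)
        amp <- stats::runif(1, 230, 255)
        img <- render_segment(size, p0, p1, thick, amp)
      } else if (kind == "blobs") {
        k <- sample(1:3, 1)
        yy <- matrix(seq_len(size[1]), size[1], size[2])
        xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
        img <- matrix(0, size[1], size[2])
        for (b in seq_len(k)) {
          c0 <- c(stats::runif(1, 1, size[1]), stats::runif(1, 1, size[2]))
          s <- stats::runif(1, mindim / 12, mindim / 5)
          a <- stats::runif(1, 120, 255)
          img <- img + a * exp(-((yy - c0[1])^2 + (xx - c0[2])^2) /
                                 (2 * s^2))
        }
        img <- img / max(img) * 255
      } else {
        k <- sample(2:4, 1)
        img <- matrix(0, size[1], size[2])
        for (s in seq_len(k)) {
          ctr <- c(stats::runif(1, size[1] * 0.2, size[1] * 0.8),
                   stats::runif(1, size[2] * 0.2, size[2] * 0.8))
          th <- stats::runif(1, 0, pi)
          half <- stats::runif(1, mindim * 0.15, mindim * 0.4)
          dir <- c(sin(th), cos(th))
          p0 <- ctr - half * dir; p1 <- ctr + half * dir
          thick <- stats::runif(1, mindim / 16, mindim / 9)
          amp <- stats::runif(1, 200, 255)
          img <- pmax(img, render_segment(size, p0, p1, thick, amp))
        }
      }
      out[[im]] <- img
    }
    if (kind == "bars") attr(out, "orientation") <- oris
    out
  })
}

#' Generate ground-truth synthetic voxels
#'
#' Each synthetic voxel reads out one location of the feature maps with
#' a sparse Gaussian weight vector plus an intercept, mirroring the
#' generative assumption behind the encoding model. Locations are drawn
#' uniformly over the map, or center-weighted (Gaussian eccentricity
#' falloff) to mimic receptive fields concentrated where stimulus energy
#' is.
#'
#' @param n_voxels number of voxels.
#' @param map_shape `c(channels, h, w)` of the feature maps.
#' @param sparsity expected fraction of non-zero weights (default 0.2);
#'   at least one weight per voxel is always non-zero.
#' @param noise_sd response noise sd (>= 0) attached to each voxel.
#' @param seed RNG seed.
#' @param center_weighted draw locations concentrated at the map center.
#' @return list of class `"gt_voxels"`: `location` (n x 2 matrix, i/j),
#'   `weights` (n x channels), `intercept`, `noise_sd`, `map_shape`.
#' @export
generate_voxels <- function(n_voxels, map_shape, sparsity = 0.2,
                            noise_sd = 1, seed = 1L,
                            center_weighted = FALSE) {
  stopifnot(n_voxels >= 1, length(map_shape) == 3L, noise_sd >= 0,
            sparsity > 0, sparsity <= 1)
  C <- map_shape[1]; h <- map_shape[2]; w <- map_shape[3]
  with_seed(seed, {
    if (center_weighted) {
      grid <- expand.grid(i = seq_len(h), j = seq_len(w))
      ecc2 <- (grid$i - (h + 1) / 2)^2 + (grid$j - (w + 1) / 2)^2
      p <- exp(-ecc2 / (2 * (min(h, w) / 4)^2))
      pick <- sample.int(nrow(grid), n_voxels, replace = TRUE,
                         prob = p / sum(p))
      loc <- cbind(i = grid$i[pick], j = grid$j[pick])
    } else {
      loc <- cbind(i = sample.int(h, n_voxels, replace = TRUE),
                   j = sample.int(w, n_voxels, replace = TRUE))
    }
    W <- matrix(stats::rnorm(n_voxels * C), n_voxels, C) *
      matrix(stats::rbinom(n_voxels * C, 1, sparsity), n_voxels, C)
    dead <- rowSums(W != 0) == 0
    if (any(dead))  # force at least one active channel
      W[cbind(which(dead), sample.int(C, sum(dead), replace = TRUE))] <-
        stats::rnorm(sum(dead))
    structure(list(location = loc, weights = W,
                   intercept = stats::rnorm(n_voxels, 0, 1),
                   noise_sd = rep(noise_sd, n_voxels),
                   map_shape = map_shape, seed = seed),
              class = "gt_voxels")
  })
}

#' Simulate voxel responses from feature volumes
#'
#' Generates responses as the noisy linear readout the encoding model
#' assumes: `y = w . f_ij + intercept + N(0, noise_sd^2)`, independently
#' per repeat.
#'
#' @param features numeric array (n_trials, channels, h, w), from
#'   [scnn_features()].
#' @param voxels a [generate_voxels()] object.
#' @param n_repeats number of repeated presentations (default 1).
#' @param seed RNG seed for the noise.
#' @return list with `responses` (matrix n_trials x n_voxels, repeat 1),
#'   `repeated` (array n_trials x n_repeats x n_voxels), `noiseless`
#'   (matrix, no noise), `voxels`.
#' @export
simulate_responses <- function(features, voxels, n_repeats = 1L,
                               seed = 1L) {
  stopifnot(inherits(voxels, "gt_voxels"), length(dim(features)) == 4L)
  d <- dim(features)
  if (!all(d[-1] == voxels$map_shape))
    stop("feature map shape does not match the voxels' map_shape")
  n <- d[1]; V <- nrow(voxels$location)
  clean <- matrix(NA_real_, n, V)
  for (v in seq_len(V)) {
    X <- matrix(features[, , voxels$location[v, 1],
                         voxels$location[v, 2]], n, d[2])
    clean[, v] <- X %*% voxels$weights[v, ] + voxels$intercept[v]
  }
  colnames(clean) <- sprintf("v%04d", seq_len(V))
  rep_arr <- with_seed(seed, {
    arr <- array(NA_real_, c(n, n_repeats, V))
    for (r in seq_len(n_repeats))
      arr[, r, ] <- clean + matrix(stats::rnorm(n * V, 0,
                                                rep(voxels$noise_sd,
                                                    each = n)), n, V)
    arr
  })
  resp <- rep_arr[, 1, ]
  dim(resp) <- c(n, V)
  colnames(resp) <- colnames(clean)
  list(responses = resp, repeated = rep_arr, noiseless = clean,
       voxels = voxels)
}

#' Build a complete synthetic encoding dataset
#'
#' One call producing everything the pipeline consumes: train/test
#' stimuli, a (fixed or trained) spiking feature extractor, feature
#' volumes, ground-truth voxels, and noisy train/test responses with
#' optional repeated test sessions for noise-ceiling work. Default
#' sizes mirror the handwritten-character regime: 270 train and 90 test
#' trials of 56 x 56 images.
#'
#' @param model an [scnn()] (trained or untrained; features are read out
#'   with the current weights).
#' @param n_train,n_test trial counts (defaults 270 / 90).
#' @param size image size `c(H, W)` (default 56 x 56).
#' @param kind stimulus kind, see [generate_stimuli()].
#' @param n_voxels number of synthetic voxels (default 100).
#' @param noise_sd response noise sd (default 1).
#' @param sparsity,center_weighted passed to [generate_voxels()].
#' @param n_repeats_test repeated test sessions (default 1; use e.g. 35
#'   for noise-ceiling studies).
#' @param seed master seed; all internal seeds derive from it.
#' @return list of class `"scnn_synth"` with elements `train_images`,
#'   `test_images`, `train_features`, `test_features`, `train_responses`,
#'   `test_responses`, `test_repeated`, `test_noiseless`, `voxels`,
#'   `model`, `seed`.
#' @export
synth_dataset <- function(model, n_train = 270L, n_test = 90L,
                          size = c(56L, 56L), kind = "glyphs",
                          n_voxels = 100L, noise_sd = 1,
                          sparsity = 0.2, center_weighted = FALSE,
                          n_repeats_test = 1L, seed = 1L) {
  stopifnot(inherits(model, "scnn"))
  tr <- generate_stimuli(kind, n_train, size, seed = seed)
  te <- generate_stimuli(kind, n_test, size, seed = seed + 1L)
  ftr <- scnn_features(model, tr)
  fte <- scnn_features(model, te)
  vox <- generate_voxels(n_voxels, dim(ftr)[-1], sparsity = sparsity,
                         noise_sd = noise_sd, seed = seed + 2L,
                         center_weighted = center_weighted)
  rtr <- simulate_responses(ftr, vox, n_repeats = 1L, seed = seed + 3L)
  rte <- simulate_responses(fte, vox, n_repeats = n_repeats_test,
                            seed = seed + 4L)
  structure(list(train_images = tr, test_images = te,
                 train_features = ftr, test_features = fte,
                 train_responses = rtr$responses,
                 test_responses = rte$responses,
                 test_repeated = rte$repeated,
                 test_noiseless = rte$noiseless,
                 voxels = vox, model = model, seed = seed),
            class = "scnn_synth")
}

#' @export
print.scnn_synth <- function(x, ...) {
  cat("Synthetic encoding dataset (seed ", x$seed, ")\n", sep = "")
  cat("  ", length(x$train_images), " train / ", length(x$test_images),
      " test stimuli (", paste(dim(x$train_images[[1]]), collapse = "x"),
      "), ", nrow(x$voxels$location), " voxels, noise sd ",
      x$voxels$noise_sd[1], "\n", sep = "")
  invisible(x)
}
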