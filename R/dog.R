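#' Difference-of-Gaussians kernel
#'
#' Center-surround retinal filter: the difference of two concentric
#' unit-mass Gaussians discretised on a `size` x `size` grid. Each
#' Gaussian is normalised by its grid sum, so the kernel coefficients sum
#' to exactly zero. `sigma[1] < sigma[2]` gives an ON-center kernel
#' (positive center, negative surround); the OFF kernel is its negation.
#'
#' @param size odd kernel width.
#' @param sigma length-2 vector `(sigma_center, sigma_surround)`.
#' @param polarity `"ON"` or `"OFF"`.
#' @return numeric `size` x `size` matrix.
#' @export
dog_kernel <- function(size, sigma, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(size %% 2 == 1, length(sigma) == 2, all(sigma > 0))
  r <- (size - 1) / 2
  d2 <- outer((-r:r)^2, (-r:r)^2, `+`)
  g1 <- exp(-d2 / (2 * sigma[1]^2)); g1 <- g1 / sum(g1)
  g2 <- exp(-d2 / (2 * sigma[2]^2)); g2 <- g2 / sum(g2)
  k <- g1 - g2
  if (polarity == "OFF") k <- -k
  k
}

#' Build a preset DoG filter bank
#'
#' Two presets mirror the two stimulus regimes the model is used with:
#'
#' * `"character_natural"` (handwritten characters and natural images):
#'   ON and OFF kernels at sizes 3, 7, 13 with standard-deviation pairs
#'   (3/9, 6/9), (7/9, 14/9), (13/9, 26/9); zero padding 6.
#' * `"digit"` (small handwritten digits): ON and OFF kernels of size 7
#'   with standard deviations (1, 2); zero padding 3.
#'
#' All kernels of a bank are embedded, centered, in a common canvas the
#' size of the largest kernel, so that after convolution with the bank's
#' single padding every channel has the same spatial size (equal to the
#' input size, since `pad = (common_window - 1) / 2`).
#'
#' The spike threshold (50) is the DoG activation above which a site emits
#' a spike during latency coding; it is carried on the bank so the whole
#' frontend is configured in one object.
#'
#' @param preset `"character_natural"` or `"digit"`.
#' @return object of class `"dog_bank"`: list with `kernels` (list of
#'   matrices, all `common_window` x `common_window`), `polarity`, `size`,
#'   `sigma`, `common_window`, `pad`, `spike_threshold`.
#' @examples
#' bank <- dog_bank("character_natural")
#' length(bank$kernels)  # 6
#' sapply(bank$kernels, sum)  # all ~0
#' @export
dog_bank <- function(preset = c("character_natural", "digit")) {
  preset <- match.arg(preset)
  if (preset == "character_natural") {
    sizes <- c(3L, 7L, 13L)
    sigmas <- list(c(3, 6) / 9, c(7, 14) / 9, c(13, 26) / 9)
    pad <- 6L
  } else {
    sizes <- 7L
    sigmas <- list(c(1, 2))
    pad <- 3L
  }
  common <- max(sizes)
  kernels <- list(); polarity <- character(); size <- integer()
  sigma <- list()
  for (s in seq_along(sizes)) {
    for (pol in c("ON", "OFF")) {
      k <- dog_kernel(sizes[s], sigmas[[s]], pol)
      # embed centered in the common canvas
      canvas <- matrix(0, common, common)
      off <- (common - sizes[s]) / 2
      canvas[off + seq_len(sizes[s]), off + seq_len(sizes[s])] <- k
      kernels[[length(kernels) + 1L]] <- canvas
      polarity <- c(polarity, pol)
      size <- c(size, sizes[s])
      sigma[[length(sigma) + 1L]] <- sigmas[[s]]
    }
  }
  structure(list(kernels = kernels, polarity = polarity, size = size,
                 sigma = sigma, common_window = common, pad = pad,
                 spike_threshold = 50, preset = preset),
            class = "dog_bank")
}

#' @export
print.dog_bank <- function(x, ...) {
  cat("DoG filter bank (preset '", x$preset, "'): ", length(x$kernels),
      " kernels, pad ", x$pad, ", spike threshold ", x$spike_threshold,
      "\n", sep = "")
  cat("  sizes:", paste(x$size, x$polarity, sep = "/"), "\n")
  invisible(x)
}

# 2-d cross-correlation ("valid" on the zero-padded image), vectorised as
# a sum of shifted sub-matrices; exact to machine precision.
conv2d_valid <- function(img, kern, pad) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  if (kh > hp || kw > wp) stop("kernel larger than padded image")
  padded <- matrix(0, hp, wp)
  padded[pad + seq_len(h), pad + seq_len(w)] <- img
  oh <- hp - kh + 1L; ow <- wp - kw + 1L
  out <- matrix(0, oh, ow)
  for (dy in seq_len(kh)) {
    for (dx in seq_len(kw)) {
      kv <- kern[dy, dx]
      if (kv != 0) {
        out <- out + kv * padded[dy:(dy + oh - 1L), dx:(dx + ow - 1L)]
      }
    }
  }
  out
}

#' Apply a DoG filter bank to a stimulus
#'
#' Convolves (correlation convention; all kernels are centro-symmetric up
#' to sign) the single-channel stimulus with every kernel of the bank,
#' using the bank's zero padding and common canvas, producing one channel
#' per kernel with identical spatial size.
#'
#' @param img stimulus matrix (see [preprocess_image()]).
#' @param bank a [dog_bank()].
#' @return numeric array (channels, H, W) of DoG activations.
#' @export
apply_dog <- function(img, bank) {
  stopifnot(is.matrix(img), inherits(bank, "dog_bank"))
  if (!all(is.finite(img))) stop("image contains non-finite values")
  first <- conv2d_valid(img, bank$kernels[[1L]], bank$pad)
  out <- array(0, c(length(bank$kernels), nrow(first), ncol(first)))
  out[1L, , ] <- first
  for (k in seq_along(bank$kernels)[-1L]) {
    # OFF kernel is the exact negation of the preceding ON kernel
    if (bank$polarity[k] == "OFF" && bank$polarity[k - 1L] == "ON" &&
        bank$size[k] == bank$size[k - 1L]) {
      out[k, , ] <- -out[k - 1L, , ]
    } else {
      out[k, , ] <- conv2d_valid(img, bank$kernels[[k]], bank$pad)
    }
  }
  out
}
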