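#' Spike waves: the temporal code between layers
#'
#' A spike wave records, for every site (channel, row, col), the time step
#' (1..T) of its single spike, or `NA` if it stays silent — each site
#' spikes at most once per stimulus (rank-order coding). This spike-time
#' representation is equivalent to the dense binary (T, C, H, W) tensor,
#' which [as.array.spike_wave()] materialises.
#'
#' @param times integer array (C, H, W); values in 1..T or `NA`.
#' @param T number of time steps.
#' @return object of class `"spike_wave"`.
#' @export
spike_wave <- function(times, T) {
  stopifnot(length(dim(times)) == 3L, T >= 1)
  tv <- times[!is.na(times)]
  if (length(tv) && (any(tv < 1) || any(tv > T)))
    stop("spike times must lie in 1..T")
  structure(list(times = times, T = as.integer(T)), class = "spike_wave")
}

#' @export
print.spike_wave <- function(x, ...) {
  d <- dim(x$times)
  cat("spike wave: ", d[1], " channels x ", d[2], "x", d[3],
      ", T = ", x$T, ", ", sum(!is.na(x$times)), " spikes\n", sep = "")
  invisible(x)
}

#' @describeIn spike_wave dense binary tensor (T, C, H, W).
#' @param x a `spike_wave`.
#' @param ... unused.
#' @export
as.array.spike_wave <- function(x, ...) {
  d <- dim(x$times)
  out <- array(0L, c(x$T, d))
  idx <- which(!is.na(x$times))
  if (length(idx)) {
    ci <- arrayInd(idx, d)
    out[cbind(x$times[idx], ci)] <- 1L
  }
  out
}

#' Intensity-to-latency spike coding
#'
#' Converts real-valued feature maps into a spike wave: sites whose value
#' exceeds `threshold` spike, stronger activations earlier. Eligible
#' sites are sorted in descending value order and split into `T`
#' rank-contiguous bins as equal as possible (the earliest bins take the
#' remainder when the count does not divide evenly); bin index = spike
#' time. Value ties are broken by row-major site index (channel, then
#' row, then column), making the code deterministic.
#'
#' @param features numeric array (C, H, W), e.g. from [apply_dog()].
#' @param T number of time steps (default 30).
#' @param threshold activation required to spike (default 50).
#' @return a [spike_wave()].
#' @export
intensity_to_latency <- function(features, T = 30L, threshold = 50) {
  stopifnot(length(dim(features)) == 3L, T >= 1)
  if (!all(is.finite(features))) stop("non-finite feature values")
  d <- dim(features)
  times <- array(NA_integer_, d)
  idx <- which(features > threshold)
  n <- length(idx)
  if (n > 0) {
    ci <- arrayInd(idx, d)  # (channel, row, col)
    rowmajor <- ((ci[, 1] - 1) * d[2] + (ci[, 2] - 1)) * d[3] + ci[, 3]
    ord <- order(-features[idx], rowmajor)
    base <- n %/% T; rem <- n %% T
    sizes <- rep(base, T)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    times[idx[ord]] <- rep.int(seq_len(T), sizes)
  }
  spike_wave(times, T)
}

#' Temporal max-pooling of spike waves
#'
#' Spatial max-pooling of the cumulative spike trains: a pooled site
#' spikes at the earliest spike time over its window (and stays silent if
#' the whole window is silent), preserving the at-most-one-spike
#' invariant. The standard configuration is a 2x2 window with stride 2.
#'
#' @param sw a [spike_wave()].
#' @param window pooling window size (default 2).
#' @param stride pooling stride (default 2).
#' @return a [spike_wave()] with pooled spatial dimensions.
#' @export
max_pool_spikes <- function(sw, window = 2L, stride = 2L) {
  stopifnot(inherits(sw, "spike_wave"))
  if (window < 1 || stride < 1) stop("window and stride must be >= 1")
  d <- dim(sw$times)
  oh <- (d[2] - window) %/% stride + 1L
  ow <- (d[3] - window) %/% stride + 1L
  if (oh < 1 || ow < 1) stop("window larger than input")
  out <- array(NA_integer_, c(d[1], oh, ow))
  ys <- (seq_len(oh) - 1L) * stride
  xs <- (seq_len(ow) - 1L) * stride
  for (dy in seq_len(window)) {
    for (dx in seq_len(window)) {
      slice <- sw$times[, ys + dy, xs + dx, drop = FALSE]
      out <- pmin(out, slice, na.rm = TRUE)
    }
  }
  storage.mode(out) <- "integer"
  spike_wave(out, sw$T)
}

#' Retinal frontend: image to spike wave
#'
#' Chains the first processing stage: DoG filtering ([apply_dog()]),
#' intensity-to-latency coding ([intensity_to_latency()]) and spike
#' max-pooling ([max_pool_spikes()]).
#'
#' @param img stimulus matrix.
#' @param bank a [dog_bank()].
#' @param T time steps for latency coding.
#' @param pool pooling window/stride (0 disables pooling).
#' @return a [spike_wave()].
#' @export
spike_frontend <- function(img, bank, T = 30L, pool = 2L) {
  sw <- intensity_to_latency(apply_dog(img, bank), T = T,
                             threshold = bank$spike_threshold)
  if (pool > 0) sw <- max_pool_spikes(sw, window = pool, stride = pool)
  sw
}
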