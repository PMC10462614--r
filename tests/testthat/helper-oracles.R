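# Independent brute-force oracles, deliberately written as plain nested
# loops with no shared code with the package internals.

# direct 2-d cross-correlation of `img` with `kern` after zero-padding
oracle_conv2 <- function(img, kern, pad) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  padded <- matrix(0, h + 2 * pad, w + 2 * pad)
  padded[pad + (1:h), pad + (1:w)] <- img
  oh <- h + 2 * pad - kh + 1; ow <- w + 2 * pad - kw + 1
  out <- matrix(0, oh, ow)
  for (y in 1:oh) for (x in 1:ow) {
    acc <- 0
    for (dy in 1:kh) for (dx in 1:kw)
      acc <- acc + kern[dy, dx] * padded[y + dy - 1, x + dx - 1]
    out[y, x] <- acc
  }
  out
}

# scalar time-stepped IF simulator: voltage v(t) = v(t-1) + sum w s(t-1),
# fire-and-reset at threshold, at most one spike per site per stimulus
oracle_if_sim <- function(times, weights, vth, T, pad) {
  C <- dim(times)[1]; H <- dim(times)[2]; W <- dim(times)[3]
  K <- dim(weights)[1]; kh <- dim(weights)[3]; kw <- dim(weights)[4]
  Ho <- H + 2 * pad - kh + 1; Wo <- W + 2 * pad - kw + 1
  v <- array(0, c(K, Ho, Wo))
  fired <- array(FALSE, c(K, Ho, Wo))
  ev <- list()
  for (t in 2:T) {
    for (k in 1:K) for (y in 1:Ho) for (x in 1:Wo) {
      acc <- 0
      for (cc in 1:C) for (dy in 1:kh) for (dx in 1:kw) {
        yi <- y + dy - 1 - pad; xi <- x + dx - 1 - pad
        if (yi >= 1 && yi <= H && xi >= 1 && xi <= W) {
          tj <- times[cc, yi, xi]
          if (!is.na(tj) && tj == t - 1)
            acc <- acc + weights[k, cc, dy, dx]
        }
      }
      v[k, y, x] <- v[k, y, x] + acc
      if (!fired[k, y, x] && v[k, y, x] >= vth) {
        ev[[length(ev) + 1]] <- data.frame(t = t, channel = k, row = y,
                                           col = x,
                                           potential = v[k, y, x])
        fired[k, y, x] <- TRUE
        v[k, y, x] <- 0
      }
    }
  }
  if (!length(ev))
    return(data.frame(t = integer(), channel = integer(), row = integer(),
                      col = integer(), potential = numeric()))
  out <- do.call(rbind, ev)
  out[order(out$t, out$channel, out$row, out$col), , drop = FALSE]
}

# no-reset voltage read-out: the weighted sum of every input spike
oracle_extract <- function(times, weights, pad) {
  C <- dim(times)[1]; H <- dim(times)[2]; W <- dim(times)[3]
  K <- dim(weights)[1]; kh <- dim(weights)[3]; kw <- dim(weights)[4]
  Ho <- H + 2 * pad - kh + 1; Wo <- W + 2 * pad - kw + 1
  out <- array(0, c(K, Ho, Wo))
  for (k in 1:K) for (y in 1:Ho) for (x in 1:Wo) {
    acc <- 0
    for (cc in 1:C) for (dy in 1:kh) for (dx in 1:kw) {
      yi <- y + dy - 1 - pad; xi <- x + dx - 1 - pad
      if (yi >= 1 && yi <= H && xi >= 1 && xi <= W &&
          !is.na(times[cc, yi, xi]))
        acc <- acc + weights[k, cc, dy, dx]
    }
    out[k, y, x] <- acc
  }
  out
}

# random spike wave with roughly `density` active sites
random_wave <- function(C, H, W, T, density = 0.3, seed = 1) {
  set.seed(seed)
  times <- array(NA_integer_, c(C, H, W))
  n <- C * H * W
  on <- which(runif(n) < density)
  times[on] <- sample.int(T, length(on), replace = TRUE)
  spike_wave(times, T)
}

# small IF layer with reproducible random weights
random_layer <- function(n_in, n_out, kernel = 3, pad = 1, v_th = 2,
                         seed = 1) {
  layer <- if_layer(n_in, n_out, kernel = kernel, pad = pad, v_th = v_th,
                    seed = seed)
  set.seed(seed + 100)
  layer$weights[] <- runif(length(layer$weights))
  layer
}
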