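#' Integrate-and-Fire convolutional layer
#'
#' A bank of `n_out` convolutional kernels of IF neurons. Each output
#' neuron integrates the weighted spikes of its receptive field
#' (`kernel` x `kernel` x `n_in`), fires once its voltage reaches `v_th`,
#' and is then silenced for the rest of the stimulus. Synaptic weights
#' live in \[0, 1\] and are initialised from a clipped normal with mean
#' 0.8 and sd 0.05 (the usual starting point for simplified STDP, high
#' enough that untrained neurons fire and can compete for plasticity).
#'
#' @param n_in input channels (6 for the character/natural DoG bank).
#' @param n_out number of kernels (default 64).
#' @param kernel kernel width (default 5).
#' @param pad zero padding (default 2, keeping the map size).
#' @param v_th firing threshold (default 10).
#' @param init_mean,init_sd weight initialisation parameters.
#' @param seed RNG seed for the initial weights.
#' @return object of class `"if_layer"`: list with `weights`
#'   (array `n_out` x `n_in` x `kernel` x `kernel`), `v_th`, `pad`.
#' @export
if_layer <- function(n_in, n_out = 64L, kernel = 5L, pad = 2L, v_th = 10,
                     init_mean = 0.8, init_sd = 0.05, seed = 1L) {
  w <- with_seed(seed, {
    array(pmin(pmax(stats::rnorm(n_out * n_in * kernel * kernel,
                                 init_mean, init_sd), 0), 1),
          c(n_out, n_in, kernel, kernel))
  })
  structure(list(weights = w, v_th = v_th, pad = as.integer(pad)),
            class = "if_layer")
}

#' @export
print.if_layer <- function(x, ...) {
  d <- dim(x$weights)
  cat("IF convolutional layer: ", d[1], " kernels (", d[2], " x ", d[3],
      " x ", d[4], "), v_th = ", x$v_th, ", pad = ", x$pad,
      ", C = ", signif(convergence_measure(x), 4), "\n", sep = "")
  invisible(x)
}

#' STDP training control parameters
#'
#' @param a_plus potentiation rate (> 0, default 0.004).
#' @param a_minus depression rate (< 0, default -0.003).
#' @param convergence_stop training stops once the convergence measure
#'   falls below this value (default 0.01); must lie in (0, 0.25).
#' @param winners_per_image maximum STDP winners per stimulus. The
#'   default `NULL` means one winner per output channel (i.e. `n_out`),
#'   so every kernel can learn from every stimulus it wins somewhere —
#'   required for all kernels to converge; set to a small integer for
#'   stricter competition.
#' @param inhibition_radius a winner suppresses later same-channel
#'   candidates within this Chebyshev radius (default 2).
#' @param max_epochs sweep budget over the training set (default 64).
#' @param seed seed for the per-epoch presentation order.
#' @return list of class `"stdp_control"`.
#' @export
stdp_control <- function(a_plus = 0.004, a_minus = -0.003,
                         convergence_stop = 0.01,
                         winners_per_image = NULL,
                         inhibition_radius = 2L,
                         max_epochs = 64L, seed = 1L) {
  stopifnot(a_plus > 0, a_minus < 0,
            convergence_stop > 0, convergence_stop < 0.25,
            inhibition_radius >= 0, max_epochs >= 1)
  if (!is.null(winners_per_image)) stopifnot(winners_per_image >= 1)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 convergence_stop = convergence_stop,
                 winners_per_image = winners_per_image,
                 inhibition_radius = as.integer(inhibition_radius),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "stdp_control")
}

#' Simulate the IF layer on a spike wave
#'
#' Runs the time-stepped Integrate-and-Fire dynamics: at step t each
#' neuron adds the weighted input spikes of step t-1 to its voltage and
#' fires (once per stimulus, resetting to 0) when the voltage reaches
#' `v_th`. Returns every firing event.
#'
#' @param sw a [spike_wave()].
#' @param layer an [if_layer()].
#' @return data frame with columns `t`, `channel`, `row`, `col` (1-based)
#'   and `potential` (voltage at firing), sorted by time.
#' @export
if_convolve_spikes <- function(sw, layer) {
  stopifnot(inherits(sw, "spike_wave"), inherits(layer, "if_layer"))
  cpp_if_events(sw$times, layer$weights, layer$pad, layer$v_th, sw$T)
}

#' Lateral inhibition across channels
#'
#' At each map position only the earliest firing event across channels
#' survives (ties broken by the lowest channel index), implementing the
#' cross-channel competition used during STDP training.
#'
#' @param events event data frame from [if_convolve_spikes()].
#' @return filtered event data frame.
#' @export
lateral_inhibition <- function(events) {
  if (nrow(events) == 0) return(events)
  ord <- order(events$row, events$col, events$t, events$channel)
  ev <- events[ord, , drop = FALSE]
  keep <- !duplicated(ev[, c("row", "col")])
  ev <- ev[keep, , drop = FALSE]
  ev[order(ev$t, ev$channel, ev$row, ev$col), , drop = FALSE]
}

#' Select STDP winners
#'
#' From post-inhibition events, picks at most `k` winners in order of
#' spike time (earliest first; ties by highest potential at firing, then
#' lowest channel, then row-major position), with at most one winner per
#' output channel; a chosen winner suppresses later same-channel
#' candidates within `radius` (Chebyshev distance).
#'
#' @param events post-[lateral_inhibition()] event data frame.
#' @param k maximum number of winners.
#' @param radius same-channel suppression radius.
#' @return data frame of winning events.
#' @export
select_stdp_winners <- function(events, k = 1L, radius = 2L) {
  if (nrow(events) == 0) return(events)
  ord <- order(events$t, -events$potential, events$channel,
               events$row, events$col)
  ev <- events[ord, , drop = FALSE]
  sel <- integer(0)
  used <- integer(0)
  for (i in seq_len(nrow(ev))) {
    if (length(sel) >= k) break
    ch <- ev$channel[i]
    if (ch %in% used) next
    if (length(sel)) {
      same <- ev$channel[sel] == ch &
        abs(ev$row[sel] - ev$row[i]) <= radius &
        abs(ev$col[sel] - ev$col[i]) <= radius
      if (any(same)) next
    }
    sel <- c(sel, i)
    used <- c(used, ch)
  }
  ev[sel, , drop = FALSE]
}

#' Simplified STDP weight update for one winner
#'
#' Applies the multiplicative soft-bounded rule to every synapse of the
#' winning neuron's receptive field: `dw = a_plus * w * (1 - w)` when the
#' presynaptic site spiked at or before the winner (`t_j <= t_i`), and
#' `dw = a_minus * w * (1 - w)` otherwise — silent presynaptic sites
#' (including zero padding) count as "after" and are depressed. The rule
#' has fixed points at w = 0 and w = 1 and keeps weights inside \[0, 1\].
#'
#' @param layer an [if_layer()].
#' @param winner one-row event data frame (a row of
#'   [select_stdp_winners()] output).
#' @param sw the input [spike_wave()] for the same stimulus.
#' @param a_plus,a_minus learning rates (see [stdp_control()]).
#' @return the layer with updated weights.
#' @export
stdp_update <- function(layer, winner, sw, a_plus = 0.004,
                        a_minus = -0.003) {
  stopifnot(inherits(layer, "if_layer"), inherits(sw, "spike_wave"),
            nrow(winner) == 1)
  d <- dim(layer$weights)  # (K, C, kh, kw)
  dt <- dim(sw$times)
  k <- winner$channel; ti <- winner$t
  for (dy in seq_len(d[3])) {
    yi <- winner$row + dy - 1L - layer$pad
    for (dx in seq_len(d[4])) {
      xi <- winner$col + dx - 1L - layer$pad
      for (cc in seq_len(d[2])) {
        tj <- if (yi >= 1 && yi <= dt[2] && xi >= 1 && xi <= dt[3])
          sw$times[cc, yi, xi] else NA_integer_
        w <- layer$weights[k, cc, dy, dx]
        dw <- if (!is.na(tj) && tj <= ti) a_plus * w * (1 - w)
              else a_minus * w * (1 - w)
        layer$weights[k, cc, dy, dx] <- min(max(w + dw, 0), 1)
      }
    }
  }
  layer
}

#' STDP learning-convergence measure
#'
#' `C = sum(w * (1 - w)) / N` over all synapses: 0.25 when all weights
#' sit at 0.5, 0 when every weight has saturated at 0 or 1. Training is
#' stopped once C drops below the configured threshold (0.01 by default),
#' at which point the kernels encode near-binary selectivity.
#'
#' @param layer an [if_layer()] (or any object with a `weights` field).
#' @return the convergence measure, in \[0, 0.25\].
#' @export
convergence_measure <- function(layer) {
  w <- layer$weights
  sum(w * (1 - w)) / length(w)
}

#' Spiking convolutional feature extractor
#'
#' Bundles the retinal frontend (a [dog_bank()] preset, latency coding
#' with `T` time steps, 2x2 spike pooling) with an [if_layer()] into the
#' two-layer spiking network used for feature extraction. Train the
#' layer with [train_scnn()]; extract features with [scnn_features()].
#'
#' @param preset DoG preset, see [dog_bank()].
#' @param T latency-coding time steps (default 30).
#' @param pool pooling window/stride (default 2).
#' @param n_out,kernel,pad,v_th IF layer geometry, see [if_layer()].
#' @param seed seed for weight initialisation.
#' @return object of class `"scnn"`.
#' @export
scnn <- function(preset = c("character_natural", "digit"), T = 30L,
                 pool = 2L, n_out = 64L, kernel = 5L, pad = 2L, v_th = 10,
                 seed = 1L) {
  preset <- match.arg(preset)
  bank <- dog_bank(preset)
  layer <- if_layer(n_in = length(bank$kernels), n_out = n_out,
                    kernel = kernel, pad = pad, v_th = v_th, seed = seed)
  structure(list(bank = bank, T = as.integer(T), pool = as.integer(pool),
                 layer = layer, trace = NULL, converged = NA,
                 epochs_run = 0L),
            class = "scnn")
}

#' @export
print.scnn <- function(x, ...) {
  cat("Spiking convolutional feature extractor\n")
  print(x$bank)
  cat("  latency coding: T =", x$T, "; pooling", x$pool, "x", x$pool, "\n")
  print(x$layer)
  if (!is.null(x$trace)) {
    cat("  trained: ", length(x$trace), " presentations over ",
        x$epochs_run, " epoch(s); ",
        if (isTRUE(x$converged)) "converged" else "NOT converged",
        " (final C = ", signif(convergence_measure(x$layer), 4), ")\n",
        sep = "")
  } else cat("  untrained\n")
  invisible(x)
}

#' Encode stimuli through the retinal frontend
#'
#' @param model an [scnn()].
#' @param stimuli list of stimulus matrices (or a single matrix).
#' @return list of [spike_wave()]s.
#' @export
encode_stimuli <- function(model, stimuli) {
  stopifnot(inherits(model, "scnn"))
  if (is.matrix(stimuli)) stimuli <- list(stimuli)
  lapply(stimuli, spike_frontend, bank = model$bank, T = model$T,
         pool = model$pool)
}

#' Train the IF layer with unsupervised STDP
#'
#' Sweeps over the training stimuli (reshuffled every epoch with the
#' control seed); for each stimulus the spiking dynamics are simulated,
#' lateral inhibition keeps the earliest event per position, at most
#' `winners_per_image` winners (one per channel) are selected, and each
#' winner's receptive field is updated with the simplified STDP rule.
#' Training stops as soon as the convergence measure drops below
#' `convergence_stop`, or after `max_epochs` sweeps (with a warning).
#'
#' @param model an [scnn()].
#' @param stimuli list of stimulus matrices, or list of pre-encoded
#'   [spike_wave()]s (e.g. from [encode_stimuli()], to avoid re-encoding
#'   across experiments).
#' @param control an [stdp_control()].
#' @return the trained `"scnn"` with `trace` (convergence measure after
#'   every presentation), `converged`, `epochs_run` filled in.
#' @examples
#' \donttest{
#' stim <- generate_stimuli("bars", 40, size = c(24, 24), seed = 1)
#' net <- scnn("character_natural", n_out = 8, seed = 1)
#' net <- train_scnn(net, stim, stdp_control(max_epochs = 2))
#' }
#' @export
train_scnn <- function(model, stimuli, control = stdp_control()) {
  stopifnot(inherits(model, "scnn"), inherits(control, "stdp_control"))
  if (length(stimuli) < 1) stop("at least one training stimulus required")
  waves <- if (inherits(stimuli[[1]], "spike_wave")) stimuli
           else encode_stimuli(model, stimuli)
  n <- length(waves)
  kwin <- control$winners_per_image
  if (is.null(kwin)) kwin <- dim(model$layer$weights)[1]
  orders <- with_seed(control$seed, {
    vapply(seq_len(control$max_epochs), function(e) sample.int(n),
           integer(n))
  })
  dim(orders) <- c(n, control$max_epochs)
  times <- lapply(waves, function(w) w$times)
  fit <- cpp_train_scnn(times, model$layer$weights, model$layer$pad,
                        model$layer$v_th, model$T, control$a_plus,
                        control$a_minus, control$convergence_stop,
                        orders, kwin, control$inhibition_radius)
  model$layer$weights <- fit$weights
  model$trace <- fit$trace
  model$converged <- fit$converged
  model$epochs_run <- fit$epochs_run
  model$control <- control
  if (!fit$converged)
    warning(sprintf(
      "STDP did not reach C < %g within %d epochs (final C = %.4f)",
      control$convergence_stop, control$max_epochs, fit$final_c))
  model
}

#' @export
plot.scnn <- function(x, ...) {
  if (is.null(x$trace)) stop("model is untrained; nothing to plot")
  graphics::plot(x$trace, type = "l", xlab = "presentation",
                 ylab = "convergence measure C",
                 main = "STDP convergence", ...)
  graphics::abline(h = x$control$convergence_stop, lty = 2)
  invisible(x)
}

#' Infinite-threshold feature read-out for one spike wave
#'
#' With the firing threshold set to infinity the IF neurons never fire or
#' reset, so the voltage at the final time step equals the weighted sum
#' of all presynaptic spikes — the convolution of the layer weights with
#' the spike-count map. This real-valued volume is the feature
#' representation used by the encoding model.
#'
#' @param sw a [spike_wave()].
#' @param layer an [if_layer()].
#' @return numeric array (n_out, H, W).
#' @export
extract_features <- function(sw, layer) {
  stopifnot(inherits(sw, "spike_wave"), inherits(layer, "if_layer"))
  counts <- array(as.numeric(!is.na(sw$times)), dim(sw$times))
  cpp_extract_features(counts, layer$weights, layer$pad)
}

#' Feature volumes for a set of stimuli
#'
#' @param model a (trained) [scnn()].
#' @param stimuli list of stimulus matrices or of [spike_wave()]s.
#' @return numeric array (n_stimuli, channels, H, W).
#' @export
scnn_features <- function(model, stimuli) {
  stopifnot(inherits(model, "scnn"))
  waves <- if (length(stimuli) && inherits(stimuli[[1]], "spike_wave"))
    stimuli else encode_stimuli(model, stimuli)
  f1 <- extract_features(waves[[1]], model$layer)
  out <- array(0, c(length(waves), dim(f1)))
  out[1, , , ] <- f1
  for (i in seq_along(waves)[-1])
    out[i, , , ] <- extract_features(waves[[i]], model$layer)
  out
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
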