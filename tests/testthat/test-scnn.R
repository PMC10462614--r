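test_that("IF dynamics fire one step after sufficient input", {
  # all weights 1, v_th 10, >=10 in-field spikes at the first step:
  # the covering neuron fires at the next step, exactly once
  tm <- array(NA_integer_, c(1, 5, 5))
  tm[1, 1:3, 1:4] <- 1L  # 12 spikes at t = 1
  sw <- spike_wave(tm, 10)
  layer <- if_layer(1, n_out = 1, kernel = 5, pad = 2, v_th = 10)
  layer$weights[] <- 1
  ev <- if_convolve_spikes(sw, layer)
  center <- ev[ev$row == 2 & ev$col == 2, ]
  expect_equal(nrow(center), 1)
  expect_equal(center$t, 2)
  expect_gte(center$potential, 10)
  # empty input: no events
  empty <- spike_wave(array(NA_integer_, c(1, 5, 5)), 10)
  expect_equal(nrow(if_convolve_spikes(empty, layer)), 0)
  # channel mismatch is an error
  expect_error(if_convolve_spikes(spike_wave(array(1L, c(2, 5, 5)), 10),
                                  layer), "channels")
})

test_that("vectorised IF simulation equals the scalar oracle", {
  for (seed in 1:8) {
    sw <- random_wave(2, 8, 8, 10, density = 0.35, seed = seed)
    layer <- random_layer(2, 2, kernel = 3, pad = 1, v_th = 2,
                          seed = seed)
    got <- if_convolve_spikes(sw, layer)
    want <- oracle_if_sim(sw$times, layer$weights, layer$v_th, sw$T,
                          layer$pad)
    expect_equal(nrow(got), nrow(want))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("lateral inhibition keeps the earliest event per position", {
  ev <- data.frame(t = c(5L, 2L, 4L), channel = c(1L, 2L, 3L),
                   row = c(3L, 3L, 1L), col = c(3L, 3L, 2L),
                   potential = c(4, 3, 5))
  out <- lateral_inhibition(ev)
  expect_equal(nrow(out), 2)
  expect_equal(out$channel[out$row == 3 & out$col == 3], 2L)
  # single event unchanged
  one <- ev[1, , drop = FALSE]
  expect_equal(lateral_inhibition(one)$t, 5L)
  # tie at the same time: lowest channel survives
  tie <- data.frame(t = c(2L, 2L), channel = c(7L, 3L),
                    row = c(1L, 1L), col = c(1L, 1L),
                    potential = c(9, 1))
  expect_equal(lateral_inhibition(tie)$channel, 3L)
})

test_that("winner selection ranks by time then potential with one per channel", {
  ev <- data.frame(t = c(1L, 1L, 2L, 3L, 3L),
                   channel = c(2L, 4L, 2L, 1L, 5L),
                   row = c(1L, 5L, 2L, 3L, 4L),
                   col = c(1L, 5L, 2L, 3L, 4L),
                   potential = c(3, 8, 9, 2, 2))
  # k = 1: the globally earliest event, ties by higher potential
  w1 <- select_stdp_winners(ev, k = 1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$channel, 4L)
  # k = 2, radius 0: two earliest on distinct channels (brute force:
  # order by (t, -potential) -> ch4@t1, ch2@t1)
  w2 <- select_stdp_winners(ev, k = 2, radius = 0)
  expect_equal(sort(w2$channel), c(2L, 4L))
  expect_true(all(w2$t == 1))
  # empty input
  expect_equal(nrow(select_stdp_winners(ev[0, ], k = 3)), 0)
  # one winner per channel even with k large
  wall <- select_stdp_winners(ev, k = 10, radius = 0)
  expect_equal(anyDuplicated(wall$channel), 0)
})

test_that("STDP rule has the printed magnitudes and fixed points", {
  tm <- array(NA_integer_, c(1, 3, 3))
  tm[1, 1, 1] <- 2L  # presynaptic spike before the winner
  sw <- spike_wave(tm, 10)
  layer <- if_layer(1, n_out = 1, kernel = 3, pad = 1, v_th = 10)
  layer$weights[] <- 0.5
  winner <- data.frame(t = 5L, channel = 1L, row = 2L, col = 2L,
                       potential = 1)
  up <- stdp_update(layer, winner, sw, a_plus = 0.004, a_minus = -0.003)
  # potentiated synapse: dw = 0.004 * 0.5 * 0.5 = 0.001
  expect_equal(up$weights[1, 1, 1, 1] - 0.5, 0.001, tolerance = 1e-12)
  # silent presynaptic site: dw = -0.003 * 0.25 = -0.00075
  expect_equal(up$weights[1, 1, 2, 2] - 0.5, -0.00075, tolerance = 1e-12)
  # w = 0 and w = 1 are fixed points
  layer$weights[] <- 0
  expect_equal(stdp_update(layer, winner, sw)$weights, layer$weights)
  layer$weights[] <- 1
  expect_equal(stdp_update(layer, winner, sw)$weights, layer$weights)
})

test_that("convergence measure evaluates w(1-w)/N", {
  layer <- if_layer(1, n_out = 1, kernel = 3, pad = 1)
  layer$weights[] <- rep(c(0, 1), length.out = 9)
  expect_equal(convergence_measure(layer), 0)
  layer$weights[] <- 0.5
  expect_equal(convergence_measure(layer), 0.25)
  layer$weights[] <- rep(c(0.2, 0.8), length.out = 9)
  # direct evaluation: mean of 0.16
  expect_equal(convergence_measure(layer), 0.16, tolerance = 1e-12)
})

test_that("one training presentation via R ops matches the C++ trainer", {
  # the fast C++ loop must implement exactly the documented pipeline:
  # simulate -> lateral inhibition -> winner selection -> STDP
  sw <- random_wave(2, 8, 8, 12, density = 0.4, seed = 21)
  net <- scnn("digit", T = 12, pool = 0, n_out = 3, kernel = 3, pad = 1,
              v_th = 2, seed = 5)
  ctrl <- stdp_control(winners_per_image = 3, inhibition_radius = 2,
                       max_epochs = 1, seed = 1,
                       convergence_stop = 1e-6)
  trained <- suppressWarnings(train_scnn(net, list(sw), ctrl))
  # replicate by hand with the R-level operations
  ev <- if_convolve_spikes(sw, net$layer)
  winners <- select_stdp_winners(lateral_inhibition(ev), k = 3,
                                 radius = 2)
  layer <- net$layer
  for (i in seq_len(nrow(winners)))
    layer <- stdp_update(layer, winners[i, , drop = FALSE], sw)
  expect_equal(trained$layer$weights, layer$weights, tolerance = 1e-12)
})

test_that("training is seed-deterministic and obeys the stopping rule", {
  stim <- generate_stimuli("bars", 15, size = c(20, 20), seed = 4)
  net <- scnn("character_natural", n_out = 4, seed = 2)
  ctrl <- stdp_control(max_epochs = 3, seed = 7)
  a <- suppressWarnings(train_scnn(net, stim, ctrl))
  b <- suppressWarnings(train_scnn(net, stim, ctrl))
  expect_identical(a$layer$weights, b$layer$weights)
  expect_identical(a$trace, b$trace)
  # stopping threshold just above the initial C: crossed at the first
  # check, so training halts after a single presentation
  c0 <- convergence_measure(net$layer)
  eager <- stdp_control(convergence_stop = c0 * 1.01, max_epochs = 3,
                        seed = 7)
  tr <- train_scnn(net, stim, eager)
  expect_true(tr$converged)
  expect_equal(length(tr$trace), 1)
})

test_that("weights stay in [0,1] under sustained STDP", {
  stim <- generate_stimuli("bars", 20, size = c(20, 20), seed = 8)
  net <- scnn("character_natural", n_out = 4, seed = 3)
  tr <- suppressWarnings(
    train_scnn(net, stim, stdp_control(max_epochs = 120, seed = 1,
                                       convergence_stop = 0.01)))
  expect_true(all(tr$layer$weights >= 0 & tr$layer$weights <= 1))
  # convergence decreased relative to the start on structured stimuli
  expect_lt(tail(tr$trace, 1), convergence_measure(net$layer))
})

test_that("feature extraction is the no-reset final-voltage read-out", {
  layer <- random_layer(2, 3, kernel = 3, pad = 1, seed = 31)
  # silent input: all-zero features
  empty <- spike_wave(array(NA_integer_, c(2, 6, 6)), 10)
  expect_equal(max(abs(extract_features(empty, layer))), 0)
  # random input equals the brute-force all-spike integration
  sw <- random_wave(2, 6, 6, 10, density = 0.5, seed = 32)
  expect_equal(extract_features(sw, layer),
               oracle_extract(sw$times, layer$weights, layer$pad),
               tolerance = 1e-10)
  # linearity in the spike-count map: doubled counts double the voltage
  counts <- array(as.numeric(!is.na(sw$times)), dim(sw$times))
  f1 <- scnnenc:::cpp_extract_features(counts, layer$weights, layer$pad)
  f2 <- scnnenc:::cpp_extract_features(2 * counts, layer$weights,
                                       layer$pad)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})
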