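test_that("spike detection counts constructed spikes and ignores flat traces", {
  flat <- trace(seq(0, 10, by = 0.001), rep(-50, 10001))
  expect_length(detect_spikes(flat), 0)
  tr <- make_square_trace(durations = c(2, 2, 2), amplitudes = rep(25, 3),
                          period = 5, spike_rate = 10)
  expect_length(detect_spikes(tr), 3 * 20)
  # doubling the sampling rate leaves the count unchanged
  tr2 <- make_square_trace(durations = c(2, 2, 2), amplitudes = rep(25, 3),
                           period = 5, spike_rate = 10, dt = 0.0005)
  expect_length(detect_spikes(tr2), 3 * 20)
})

test_that("spike detection respects the refractory interval", {
  tt <- seq(0, 1, by = 0.0005)
  v <- rep(-60, length(tt))
  v[tt %in% c(0.1, 0.1005, 0.101, 0.2)] <- 0   # burst of crossings 0.5 ms apart
  tr <- trace(tt, v)
  expect_length(detect_spikes(tr, refractory_ms = 2), 2)
})

test_that("the envelope strips spikes but preserves square DPs and monotonicity", {
  sq <- make_square_trace(durations = c(2.9, 2.9, 2.9), amplitudes = rep(30, 3))
  env <- dp_envelope(sq)
  expect_lt(max(abs(env$V_mV - sq$V_mV)), 1)   # near-identity without spikes
  spiky <- make_square_trace(durations = c(2.9, 2.9, 2.9),
                             amplitudes = rep(30, 3), spike_rate = 15)
  env2 <- dp_envelope(spiky)
  expect_lt(max(abs(env2$V_mV - sq$V_mV)), 2)  # spikes removed
  mono <- trace(seq(0, 10, by = 0.001), seq(-70, -20, length.out = 10001))
  expect_false(is.unsorted(dp_envelope(mono)$V_mV))
  expect_error(dp_envelope(sq, window_ms = 0.5), "window")
})

test_that("segmentation recovers square drive potentials and tolerates offsets", {
  expect_identical(nrow(segment_bursts(
    trace(seq(0, 30, by = 0.001), rep(-50, 30001)))), 0L)
  tr <- make_square_trace(durations = rep(2.9, 3), amplitudes = rep(30, 3))
  ev <- segment_bursts(dp_envelope(tr))
  expect_identical(nrow(ev), 3L)
  expect_true(all(abs(ev$dp_duration - 2.9) / 2.9 < 0.05))
  expect_true(all(abs(ev$dp_amplitude - 30) < 1))
  expect_true(all(ev$offset > ev$onset))
  # amplitude estimate invariant to a DC offset
  off <- tr
  off$V_mV <- off$V_mV + 17.3
  ev2 <- segment_bursts(dp_envelope(off))
  expect_equal(ev2$dp_amplitude, ev$dp_amplitude, tolerance = 1e-6)
  expect_equal(attr(ev2, "baseline_vm"), attr(ev, "baseline_vm") + 17.3,
               tolerance = 1e-6)
})

test_that("events merge across gaps shorter than the configured minimum", {
  tt <- seq(0, 12, by = 0.001)
  v <- rep(-50, length(tt))
  v[tt >= 2 & tt < 4] <- -20
  v[tt >= 4.1 & tt < 5.1] <- -20      # 0.1 s gap -> merged
  v[tt >= 8 & tt < 9] <- -20          # separate event
  ev <- segment_bursts(trace(tt, v))
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$dp_duration[1], 3, tolerance = 0.01)   # time above threshold
  expect_gt(ev$offset[1] - ev$onset[1], 3.05)            # spans the merged gap
})

test_that("depolarization block is flagged only for early-confined spiking", {
  blocked <- make_square_trace(durations = 2.9, amplitudes = 30,
                               spike_rate = 15, spike_end_frac = 0.35)
  sp <- detect_spikes(blocked)
  ev <- segment_bursts(dp_envelope(blocked), spike_times = sp,
                       cfg = classifier_config())
  expect_true(ev$depol_block[1])
  expect_identical(ev$n_spikes[1], length(sp))
  throughout <- make_square_trace(durations = 2.9, amplitudes = 30,
                                  spike_rate = 15, spike_end_frac = 1)
  ev2 <- segment_bursts(dp_envelope(throughout),
                        spike_times = detect_spikes(throughout),
                        cfg = classifier_config())
  expect_false(ev2$depol_block[1])
})

test_that("the five-way classifier follows the per-event composition rules", {
  cfg <- classifier_config()
  # silent
  flat <- trace(seq(0, 40, by = 0.001), rep(-50, 40001))
  expect_identical(classify_discharge(flat, cfg)$label, "silent")
  # plateau: long events with depolarization block
  pl <- make_square_trace(durations = rep(2.9, 4), amplitudes = rep(30, 4),
                          spike_rate = 15, spike_end_frac = 0.35)
  clp <- classify_discharge(pl, cfg)
  expect_identical(clp$label, "plateau")
  expect_true(all(clp$per_event_labels == "plateau"))
  # oscillatory: short events, spikes throughout
  os <- make_square_trace(durations = rep(0.79, 6), amplitudes = rep(13, 6),
                          period = 4, baseline = -49.2, spike_rate = 15)
  expect_identical(classify_discharge(os, cfg)$label, "oscillatory")
  # mixed: half long, half short
  mx <- make_square_trace(durations = rep(c(2.9, 0.79), 3),
                          amplitudes = rep(c(30, 13), 3), period = 6,
                          spike_rate = 15)
  expect_identical(classify_discharge(mx, cfg)$label, "mixed")
  # indeterminate: active but too few events
  few <- make_square_trace(durations = rep(0.79, 2), amplitudes = rep(13, 2),
                           period = 4, spike_rate = 15)
  clf <- classify_discharge(few, cfg)
  expect_identical(clf$label, "indeterminate")
  expect_true(clf$indeterminate)
})

test_that("continuous spiking with no quiescence is tonic", {
  tt <- seq(0, 40, by = 0.001)
  v <- rep(-50, length(tt))
  sp_t <- seq(0.5, 39.5, by = 0.2)
  for (s0 in sp_t) {
    sel <- tt >= s0 - 0.002 & tt <= s0 + 0.002
    v[sel] <- v[sel] + 45 * (1 - abs(tt[sel] - s0) / 0.002)
  }
  expect_identical(classify_discharge(trace(tt, v))$label, "tonic")
})

test_that("classification is invariant to DC offset, time shift and resampling", {
  tr <- make_square_trace(durations = rep(c(2.9, 0.79), 3),
                          amplitudes = rep(c(30, 13), 3), period = 6,
                          spike_rate = 15)
  ref <- classify_discharge(tr)
  shifted <- trace(tr$t_s + 11.7, tr$V_mV + 8.25)
  expect_identical(classify_discharge(shifted)$label, ref$label)
  fine <- make_square_trace(durations = rep(c(2.9, 0.79), 3),
                            amplitudes = rep(c(30, 13), 3), period = 6,
                            spike_rate = 15, dt = 0.0005)
  expect_identical(classify_discharge(fine)$label, ref$label)
})

test_that("burst statistics reduce to their closed forms", {
  tr <- make_square_trace(durations = rep(2, 5), amplitudes = rep(25, 5),
                          period = 7)
  ev <- segment_bursts(dp_envelope(tr))
  st <- burst_statistics(ev)
  expect_identical(st$n, 5L)
  expect_equal(st$frequency_hz, 1 / 7, tolerance = 1e-3)  # periodic train
  expect_equal(st$amplitude$mean, 25, tolerance = 0.5)
  one <- ev[1, ]
  st1 <- burst_statistics(one)
  expect_true(st1$single_event)
  expect_true(is.na(st1$amplitude$sd))
  expect_equal(st1$duration$mean, ev$dp_duration[1])
  expect_error(burst_statistics(ev[0, ]), "no burst events")
})

test_that("drive-current measurement averages the requested cycles", {
  flat <- trace(seq(0, 80, by = 0.005), rep(0, 16001))
  expect_error(measure_drive_current(flat), "0 burst cycles")
  eq <- generate_drive_current(15, amp_mean = 55, amp_sd = 0, seed = 3)
  expect_equal(measure_drive_current(eq, 15), 55, tolerance = 0.5)
  drawn <- generate_drive_current(15, amp_mean = 55, amp_sd = 0.9 * sqrt(15),
                                  seed = 4)
  gt <- attr(drawn, "ground_truth")
  sem <- stats::sd(gt) / sqrt(length(gt))
  expect_lt(abs(measure_drive_current(drawn, 15) - mean(gt)), 2 * sem + 0.5)
  expect_error(measure_drive_current(
    generate_drive_current(10, amp_mean = 55, seed = 5), 15), "10 burst cycles")
})
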