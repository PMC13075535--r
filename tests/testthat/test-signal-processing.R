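test_that("band-pass rejects DC and matches its designed magnitude response", {
  rate <- 500
  t <- seq(0, 4, by = 1 / rate)[-1]
  rec <- function(x) data.frame(time_s = t, BBL = x)

  # DC input: essentially eliminated after the edge transient
  dc <- bandpass_filter(rec(rep(1, length(t))))
  mid <- dc$recording$BBL[(0.5 * rate):(3.5 * rate)]
  expect_lt(max(abs(mid)), 0.01)

  # 100 Hz (mid-band): steady-state amplitude within 5% of unity, and
  # within 1% of the designed |H|^2 response evaluated independently;
  # amplitude estimated as sqrt(2) * RMS over whole cycles (a sample max
  # misses the peak of a 5-sample-per-cycle tone)
  s100 <- bandpass_filter(rec(sin(2 * pi * 100 * t)))
  mid100 <- s100$recording$BBL[(1 * rate + 1):(3 * rate)]
  amp <- sqrt(2 * mean(mid100^2))
  expect_lt(abs(amp - 1), 0.05)
  expect_lt(abs(amp - default_chain_gain(100)), 0.01)

  # 1 Hz (stop band): attenuated by at least 20 dB
  s1 <- bandpass_filter(rec(sin(2 * pi * 1 * t)))
  amp1 <- sqrt(2 * mean(s1$recording$BBL[(1 * rate + 1):(3 * rate)]^2))
  expect_lt(amp1, 0.1)
  expect_lt(default_chain_gain(1), 0.1)
})

test_that("filter specification is validated against the recording rate", {
  expect_error(filter_spec(low_cut = 0), "low_cut")
  expect_error(filter_spec(low_cut = 30, high_cut = 20), "low_cut")
  rec <- generate_recording(quick_schedule(1), quick_model())
  expect_error(bandpass_filter(rec, filter_spec(high_cut = 250)), "Nyquist")
})

test_that("zero-phase filtering keeps a symmetric burst peak in place", {
  rate <- 500
  n <- 2000
  x <- numeric(n)
  # symmetric 80 Hz burst with a triangular envelope centred at sample 1000
  idx <- 901:1099
  tri <- 1 - abs(seq(-1, 1, length.out = length(idx)))
  x[idx] <- tri * cos(2 * pi * 80 * (idx - 1000) / rate)
  env <- rectify_and_smooth(filter_series(x), 50)
  expect_lt(abs(which.max(env) - 1000), 3)
})

test_that("rectify_and_smooth matches its closed forms and preserves shape", {
  expect_equal(rectify_and_smooth(c(-1, 1, -1, 1), 2), rep(1, 4))
  x <- c(-3, 0.5, 2, -7)
  expect_equal(rectify_and_smooth(x, 1), abs(x))
  expect_equal(rectify_and_smooth(rep(2.5, 100), 50), rep(2.5, 100))
  set.seed(1)
  y <- rnorm(400)
  env <- rectify_and_smooth(y, 50)
  expect_length(env, 400)
  expect_true(all(env >= 0))
  expect_error(rectify_and_smooth(y, 401), "window")
  expect_error(rectify_and_smooth(numeric(0)), "empty")
})

test_that("activation detection finds real bursts and ignores noise", {
  set.seed(42)
  # pure baseline noise: no events
  expect_equal(nrow(detect_activations(filter_series(rnorm(5000)))), 0)
  # all-constant input: empty result, no error
  expect_equal(nrow(detect_activations(rep(3, 500), on = "envelope")), 0)

  burst_at <- function(onset, len, amp = 10, n = 2000, seed = 1) {
    set.seed(seed)
    x <- rnorm(n)
    k <- seq_len(len) - 1
    x[onset + k] <- x[onset + k] + amp * sin(2 * pi * 80 * k / 500)
    filter_series(x)
  }
  # a 50-sample burst at 10x baseline SD: exactly one event, onset close
  for (seed in 1:5) {
    ev <- detect_activations(burst_at(1001, 50, seed = seed))
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$onset - 1001), 10)
    expect_gt(ev$offset, ev$onset)
  }
  # a 10-sample burst is killed by the 25-sample duration rule
  expect_equal(nrow(detect_activations(burst_at(1001, 10))), 0)
})

test_that("raising the minimum duration never increases the event count", {
  rec <- generate_recording(quick_schedule(3), quick_model(amp = 12, seed = 8L))
  x <- bandpass_filter(rec)$recording$BBL
  counts <- vapply(c(5, 15, 25, 60, 150, 400, 600),
                   function(d) nrow(detect_activations(x,
                                                       min_duration_samples = d)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events are sorted, non-overlapping, and respect the duration rule", {
  rec <- generate_recording(quick_schedule(4), quick_model(amp = 15, seed = 2L))
  filt <- bandpass_filter(rec)
  ev <- detect_activations_all(filt)
  for (ch in unique(ev$channel)) {
    e <- ev[ev$channel == ch, ]
    expect_true(all(diff(e$onset) > 0))
    expect_true(all(utils::head(e$offset, -1) < e$onset[-1]))
    expect_true(all(e$offset - e$onset + 1 >= 25))
  }
})

test_that("pull and push activations pair into propulsion cycles", {
  mk <- function(channel, onsets, len = 100) {
    data.frame(channel = channel, onset = onsets, offset = onsets + len - 1,
               peak_value = 1)
  }
  # 3 pulls alternating with 3 pushes: 3 complete cycles
  ev <- rbind(mk("BBL", c(1, 1001, 2001)), mk("TBL", c(501, 1501, 2501)))
  out <- segment_pull_push(ev)
  expect_equal(nrow(out$cycles), 3)
  expect_equal(nrow(out$residual), 0)
  expect_equal(out$cycles$pull_onset, c(1, 1001, 2001))
  expect_equal(out$cycles$push_onset, c(501, 1501, 2501))

  # 3 pulls, 2 pushes: 2 cycles plus one flagged pull residual
  ev2 <- rbind(mk("BBL", c(1, 1001, 2001)), mk("TBL", c(501, 1501)))
  out2 <- segment_pull_push(ev2)
  expect_equal(nrow(out2$cycles), 2)
  expect_equal(nrow(out2$residual), 1)
  expect_equal(out2$residual$phase, "pull")

  # overlapping pull-channel events collapse into one pull window
  ev3 <- rbind(mk("BBL", 1), mk("BRD", 21), mk("PDT", 11), mk("TBL", 501))
  out3 <- segment_pull_push(ev3)
  expect_equal(nrow(out3$cycles), 1)
  expect_equal(out3$cycles$pull_onset, 1)
  expect_equal(out3$cycles$pull_offset, 120)

  empty <- segment_pull_push(ev[0, ])
  expect_equal(nrow(empty$cycles), 0)
  expect_equal(nrow(empty$residual), 0)
})
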