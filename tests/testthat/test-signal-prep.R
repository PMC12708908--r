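test_that("segmentation keeps exactly the in-interval samples and rejects bad boundaries", {
  fs <- 50
  n_int <- 12
  iv_len <- 2    # seconds per interval, desk-scale
  gap <- 1
  rows <- list()
  bounds <- data.frame(interval_index = 0:(n_int - 1),
                       start_s = (0:(n_int - 1)) * (iv_len + gap),
                       end_s = (0:(n_int - 1)) * (iv_len + gap) + iv_len)
  total <- n_int * (iv_len + gap)
  tt <- seq(0, total - 1 / fs, by = 1 / fs)
  in_interval <- rep(FALSE, length(tt))
  for (k in seq_len(n_int))
    in_interval <- in_interval |
      (tt >= bounds$start_s[k] - 1e-9 & tt < bounds$end_s[k] - 1e-9)
  for (p in 1:2) for (ch in c("ecg", "eda", "resp", "temp")) {
    val <- rnorm(length(tt))
    val[!in_interval] <- 999   # sentinel outside intervals
    rows[[length(rows) + 1]] <- data.frame(dyad_id = 1, participant = p,
                                           channel = ch, time_s = tt,
                                           value = val)
  }
  raw <- do.call(rbind, rows)
  out <- segment_recording(raw, bounds, fs)
  expect_length(out, 12 * 2 * 4)
  for (si in out) {
    expect_s3_class(si, "signal_interval")
    expect_length(si$samples, iv_len * fs)
    expect_false(any(si$samples == 999))
  }
  bad <- bounds
  bad$end_s[1] <- bad$start_s[2] + 0.5
  expect_error(segment_recording(raw, bad, fs), "overlap")
  outside <- bounds
  outside$end_s[n_int] <- total + 10
  expect_error(segment_recording(raw, outside, fs), "span")
})

test_that("R-peak detection recovers constructed pulse trains", {
  fs <- 100
  x <- make_pulse_signal(seq(0.5, 119.5, by = 1), fs, 120, noise_sd = 0.01)
  pk <- detect_r_peaks(signal_interval(x, fs, "ecg"))
  expect_true(abs(length(pk$times) - 120) <= 1)
  expect_equal(median(diff(pk$times)), 1.0, tolerance = 1 / fs)
  expect_true(all(diff(pk$times) > 0))

  x8 <- make_pulse_signal(seq(0.4, 119.6, by = 0.8), fs, 120, noise_sd = 0.01)
  pk8 <- detect_r_peaks(signal_interval(x8, fs, "ecg"))
  expect_lte(abs(median(diff(pk8$times)) - 0.8), 1 / fs)

  flat <- signal_interval(rep(0.3, 120 * fs), fs, "ecg")
  expect_error(detect_r_peaks(flat), "quality error")
  expect_error(detect_r_peaks(signal_interval(rnorm(50), fs, "ecg")), "10 s")
  expect_error(detect_r_peaks(signal_interval(rnorm(1200), fs, "eda")), "ecg")
})

test_that("peak detection is translation-equivariant", {
  fs <- 100
  times <- c(1.1, 2.4, 3.3, 4.9, 6.2, 7.7, 9.1, 10.4, 11.9)
  x <- make_pulse_signal(times, fs, 13)
  k <- 37
  xs <- c(rep(0, k), x)[seq_along(x)]
  p1 <- detect_r_peaks(signal_interval(x, fs, "ecg"))
  p2 <- detect_r_peaks(signal_interval(xs, fs, "ecg"))
  shifted <- p1$times + k / fs
  expect_equal(p2$times, shifted[shifted <= 13 - 1 / fs], tolerance = 1e-9)
})

test_that("respiration peaks follow oscillation frequency", {
  fs <- 50
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 0.25 * tt)
  pk <- detect_respiration_peaks(signal_interval(sine, fs, "resp"))
  expect_true(abs(length(pk$times) - 30) <= 1)
  expect_error(detect_respiration_peaks(signal_interval(rep(1, 6000), fs, "resp")),
               "quality error")
  # chirp 0.2 -> 0.3 Hz: cycle count = integral of instantaneous frequency
  f_inst <- 0.2 + 0.1 * tt / 120
  phase <- 2 * pi * cumsum(f_inst) / fs
  chirp <- sin(phase)
  pkc <- detect_respiration_peaks(signal_interval(chirp, fs, "resp"))
  expect_gte(length(pkc$times), 24)
  expect_lte(length(pkc$times), 36)
})

test_that("SCR detection applies the trough-to-peak amplitude and latency criterion", {
  fs <- 20
  mk_bump <- function(rise, rise_s) {
    tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
    x <- 2 - 0.0005 * tt          # slight decline so extrema are strict
    on <- tt >= 10 & tt < 10 + rise_s
    x[on] <- x[on] + rise * (tt[on] - 10) / rise_s
    after <- tt >= 10 + rise_s
    x[after] <- x[after] + rise * exp(-(tt[after] - 10 - rise_s) / 5)
    x
  }
  s1 <- detect_scrs(signal_interval(mk_bump(0.06, 2), fs, "eda"), smooth_s = 0)
  expect_length(s1$times, 1)
  expect_equal(s1$amplitudes, 0.06, tolerance = 0.03)
  expect_lte(s1$times - s1$valley_times, 5)

  s2 <- detect_scrs(signal_interval(mk_bump(0.04, 2), fs, "eda"), smooth_s = 0)
  expect_length(s2$times, 0)

  s3 <- detect_scrs(signal_interval(mk_bump(0.5, 8), fs, "eda"), smooth_s = 0)
  expect_length(s3$times, 0)
})

test_that("SCR detection matches the exhaustive valley-peak scan on random signals", {
  fs <- 10
  for (seed in 1:8) {
    set.seed(seed)
    x <- as.numeric(stats::filter(cumsum(rnorm(600, 0, 0.05)),
                                  rep(0.2, 5), sides = 2))
    x <- x[!is.na(x)] + 5
    det <- detect_scrs(signal_interval(x, fs, "eda"), smooth_s = 0)
    orc <- oracle_scr_scan(x, fs)
    if (is.null(orc)) {
      expect_length(det$times, 0)
    } else {
      expect_equal(det$times, unname(orc[, "peak"]), tolerance = 1e-9)
      expect_equal(det$valley_times, unname(orc[, "valley"]), tolerance = 1e-9)
      expect_equal(det$amplitudes, unname(orc[, "amp"]), tolerance = 1e-9)
    }
  }
})

test_that("instantaneous rate implements the piecewise-constant 60/IBI convention", {
  mk_train <- function(times) structure(list(channel = "ecg", times = times),
                                        class = "peak_train")
  r1 <- instantaneous_rate(mk_train(seq(0, 120, by = 1)), 4, 120)
  expect_true(all(abs(r1$values - 60) < 1e-9))
  expect_length(r1$values, 480)
  r2 <- instantaneous_rate(mk_train(seq(0, 120, by = 0.5)), 4, 120)
  expect_true(all(abs(r2$values - 120) < 1e-9))
  # alternating 0.5 / 1.0 s spacing: values in {120, 60}, time-weighted mean 80
  times <- cumsum(c(0, rep(c(0.5, 1.0), 80)))
  r3 <- instantaneous_rate(mk_train(times[times <= 120]), 4, 120)
  expect_true(all(r3$values %in% c(60, 120)))
  expect_equal(mean(r3$values), 80, tolerance = 2)
  expect_error(instantaneous_rate(mk_train(1), 4, 120), "quality error")
})

test_that("time-weighted mean rate is invariant to grid refinement", {
  set.seed(3)
  times <- cumsum(runif(100, 0.6, 1.2))
  times <- times[times < 80]
  tr <- structure(list(channel = "ecg", times = times), class = "peak_train")
  m4 <- mean(instantaneous_rate(tr, 4, 80)$values)
  m32 <- mean(instantaneous_rate(tr, 32, 80)$values)
  expect_equal(m4, m32, tolerance = 1 / 4)
})

test_that("channel filters run and preserve length", {
  fs <- 50
  x <- rnorm(fs * 30)
  for (ch in c("ecg", "eda", "resp", "temp")) {
    f <- filter_channel(signal_interval(x, fs, ch))
    expect_length(f$samples, length(x))
    expect_true(all(is.finite(f$samples)))
  }
  # low-pass removes a fast oscillation from EDA
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * tt)
  fast <- 0.5 * sin(2 * pi * 10 * tt)
  f <- filter_channel(signal_interval(slow + fast, fs, "eda"))
  expect_lt(sd(f$samples - slow), 0.15)
})
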