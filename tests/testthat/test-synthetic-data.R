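test_that("all three generators are bit-reproducible under a fixed seed", {
  sp <- fictive_spec("bg_ctrl", duration_s = 6, seed = 7)
  r1 <- generate_fictive_trace(sp)
  r2 <- generate_fictive_trace(sp)
  expect_identical(r1$trace$samples, r2$trace$samples)
  expect_identical(r1$truth, r2$truth)

  i1 <- generate_ipsc_trace(25, rhythmic = TRUE, duration_s = 3, seed = 11)
  i2 <- generate_ipsc_trace(25, rhythmic = TRUE, duration_s = 3, seed = 11)
  expect_identical(i1$trace$samples, i2$trace$samples)

  v1 <- generate_swim_video(n_frames = 8, seed = 3)
  v2 <- generate_swim_video(n_frames = 8, seed = 3)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$angles, v2$angles)
})

test_that("fictive episodes respect the 200-ms minimum and do not overlap", {
  for (mode in c("burst_ctrl", "burst_str", "bg_ctrl", "bg_str")) {
    r <- generate_fictive_trace(fictive_spec(mode, duration_s = 25, seed = 5))
    tr <- r$truth
    expect_true(all(tr$end_s - tr$start_s > 0.2))
    if (nrow(tr) > 1) {
      expect_true(all(diff(tr$start_s) > 0))
      expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
    }
  }
})

test_that("control episodes concentrate 20-40 Hz power; strychnine mode loses it", {
  sp <- fictive_spec("bg_ctrl", tailbeat_hz = 30, snr = 5,
                     duration_s = 20, seed = 21)
  r <- generate_fictive_trace(sp)
  x <- r$trace$samples; rate <- r$trace$rate_hz
  in_ep <- rep(FALSE, length(x))
  for (k in seq_len(nrow(r$truth))) {
    i0 <- round(r$truth$start_s[k] * rate) + 1
    i1 <- round(r$truth$end_s[k] * rate)
    in_ep[i0:i1] <- TRUE
  }
  # band power per sample inside vs outside episodes, direct periodogram
  bp_in <- oracle_band_power(x[in_ep], rate, 20, 40) / sum(in_ep)
  bp_out <- oracle_band_power(x[!in_ep], rate, 20, 40) / sum(!in_ep)
  expect_gt(bp_in / bp_out, 10)

  # matched strychnine spec, same seed: smaller fraction of episode power
  # in the tail-beat band
  sps <- fictive_spec("bg_str", tailbeat_hz = 30, snr = 5,
                      duration_s = 20, seed = 21)
  rs <- generate_fictive_trace(sps)
  xs <- rs$trace$samples
  in_s <- rep(FALSE, length(xs))
  for (k in seq_len(nrow(rs$truth))) {
    i0 <- round(rs$truth$start_s[k] * rate) + 1
    i1 <- round(rs$truth$end_s[k] * rate)
    in_s[i0:i1] <- TRUE
  }
  frac_ctrl <- oracle_band_power(x[in_ep], rate, 20, 40) /
    oracle_band_power(x[in_ep], rate, 0, rate / 2)
  frac_str <- oracle_band_power(xs[in_s], rate, 20, 40) /
    oracle_band_power(xs[in_s], rate, 0, rate / 2)
  expect_lt(frac_str, frac_ctrl)
})

test_that("per-episode dominant frequency matches the ground-truth tail beat", {
  r <- generate_fictive_trace(fictive_spec("bg_ctrl", tailbeat_hz = 28,
                                           duration_s = 20, seed = 9))
  rate <- r$trace$rate_hz
  for (k in seq_len(nrow(r$truth))) {
    i0 <- round(r$truth$start_s[k] * rate) + 1
    i1 <- round(r$truth$end_s[k] * rate)
    seg <- r$trace$samples[i0:i1]
    bin <- rate / length(seg)
    expect_lte(abs(oracle_dominant_freq(seg, rate) - 28), bin + 1e-9)
  }
})

test_that("generator errors are explicit", {
  expect_error(fictive_spec("bg_ctrl", tailbeat_hz = 45), "20, 40")
  expect_error(fictive_spec("bg_ctrl", episode_dur_s = 0.1), "0.2")
  expect_error(generate_fictive_trace(
    fictive_spec("burst_ctrl", duration_s = 0.5)), "too short")
  expect_error(generate_ipsc_trace(25, TRUE, jitter_sd_ms = -1), ">= 0")
  expect_error(generate_ipsc_trace(0, TRUE), "> 0")
  expect_error(generate_swim_video(wave_hz = 300, fps = 500), "twice")
  expect_error(generate_swim_video(thickness_px = c(16, 2)), "3 px")
})

test_that("IPSC event statistics match closed-form interval laws", {
  # rhythmic, zero jitter: all intervals exactly the period
  r0 <- generate_ipsc_trace(25, rhythmic = TRUE, jitter_sd_ms = 0,
                            duration_s = 4, seed = 2)
  iv <- diff(r0$truth$event_times_s)
  expect_true(all(abs(iv - 0.04) < 1e-12))

  # Poisson: interval CV ~ 1 (CV of the exponential law)
  rp <- generate_ipsc_trace(25, rhythmic = FALSE, duration_s = 100, seed = 5)
  ivp <- diff(rp$truth$event_times_s)
  cv <- sd(ivp) / mean(ivp)
  expect_gt(cv, 0.9); expect_lt(cv, 1.1)

  # jitter 2 ms: interval SD ~ sqrt(2)*2 ms = 2.83 ms
  rj <- generate_ipsc_trace(25, rhythmic = TRUE, jitter_sd_ms = 2,
                            duration_s = 50, seed = 8)
  expect_gte(length(rj$truth$event_times_s), 1000)
  sd_ms <- sd(diff(rj$truth$event_times_s)) * 1000
  expect_gt(sd_ms, 1.5); expect_lt(sd_ms, 3.5)
})

test_that("swim-video ground truth behaves as constructed", {
  # zero amplitude: every frame identical, all angles zero
  v0 <- generate_swim_video(amp_px = 0, n_frames = 6)
  expect_true(all(vapply(v0$frames, identical, TRUE, v0$frames[[1]])))
  expect_true(all(abs(v0$angles) < 1e-9))

  # ground-truth caudal-most segment oscillates at the wave frequency
  v <- generate_swim_video(wave_hz = 30, n_frames = 200, fps = 500)
  caudal <- v$angles[30, ]
  f <- oracle_dominant_freq(caudal, 500, f_min = 2, f_max = 200)
  expect_lte(abs(f - 30), 500 / 200 + 1e-9)

  # caudally growing envelope: caudal excursions exceed rostral ones
  expect_gt(max(abs(v$angles[30, ])), max(abs(v$angles[1, ])))
})

test_that("trace CSV round trip preserves samples and rate", {
  r <- generate_fictive_trace(fictive_spec("bg_ctrl", duration_s = 2, seed = 1))
  path <- file.path(tempdir(), "trace.csv")
  write_trace_csv(r$trace, path)
  back <- read_trace_csv(path)
  expect_equal(back$samples, r$trace$samples)
  expect_equal(back$rate_hz, r$trace$rate_hz)
  file.remove(path, paste0(path, ".json"))
})
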