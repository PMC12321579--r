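# Offline detectors: sleep scoring, MUA, IED, spindle and DOWN-state rules
# on constructed signals and ground-truthed synthetic sessions.

test_that("sleep scoring recovers the generator's state blocks", {
  b <- fixture_short()
  st <- score_sleep(b)
  fs <- b$meta$fs_hz
  n <- b$meta$n_samples
  truth <- character(n %/% fs)
  scored <- character(n %/% fs)
  secs <- seq_len(n %/% fs) - 0.5
  for (s in c("NREM", "REM", "WAKE")) {
    truth[in_intervals(secs, slice_by_state(b, s))] <- s
    scored[in_intervals(secs, st[st$state == s, ])] <- s
  }
  expect_gt(mean(truth == scored), 0.9)
  expect_error(score_sleep(noise_bundle(rnorm(2500), rnorm(2500))),
               "assume-immobile|accelerometer")
  # all-zero signal: delta criterion can never fire
  z <- rep(0, 1250 * 120)
  bz <- noise_bundle(z, z, accel = rep(0, length(z)))
  expect_equal(sum(score_sleep(bz)$state == "NREM"), 0)
})

test_that("motion bursts are scored as WAKE", {
  b <- fixture_short()
  acc <- b$lfp[, 3]
  fs <- b$meta$fs_hz
  acc[(100 * fs):(130 * fs)] <- rnorm(30 * fs + 1, sd = 300)
  b$lfp[, 3] <- acc
  st <- score_sleep(b)
  wake <- st[st$state == "WAKE", ]
  expect_true(any(wake$start_s < 130 & wake$end_s > 100))
})

test_that("MUA detection thresholds behave monotonically", {
  set.seed(2)
  x <- rnorm(1250 * 60, sd = 20)
  b <- noise_bundle(x, x)
  counts <- vapply(c(3, 4, 5, 6), function(k) {
    length(detect_mua(b, "HC", thr_mult = k))
  }, 0)
  expect_true(all(diff(counts) <= 0))
  # injected spike-like transients at 8x noise are recovered
  spikes_t <- seq(1, 59, length.out = 100)
  xs <- x
  tpl <- 160 * exp(-((-6:6) / 2)^2 / 2) * cos(seq(-pi, pi, length.out = 13))
  for (t in spikes_t) {
    i <- round(t * 1250)
    xs[i:(i + 12)] <- xs[i:(i + 12)] + tpl
  }
  det <- detect_mua(noise_bundle(xs, xs), "HC")
  hits <- vapply(spikes_t, function(t) any(abs(det - t) < 0.01), TRUE)
  expect_gte(sum(hits), 95)
  expect_length(detect_mua(noise_bundle(rep(0, 1250 * 10),
                                        rep(0, 1250 * 10)), "HC"), 0)
  expect_warning(detect_mua(b, "HC", band = c(80, 700)), "Nyquist")
})

test_that("IED detector recovers injected events and rejects artifacts", {
  fx <- fixture_recovery()
  gt <- fx$bundle$ground_truth$events
  m <- match_point_events(fx$ied_hc$events$peak_s,
                          gt$t_peak_s[gt$origin == "hc_ied"])
  expect_gte(m["sensitivity"], 0.9)
  expect_gte(m["precision"], 0.9)
  # white noise only: false positives below 0.5/min over 10 minutes
  set.seed(77)
  wn <- rnorm(1250 * 600, sd = 60)
  bw <- noise_bundle(wn, wn)
  fp <- nrow(detect_ied(bw, "HC")$events) / 10
  expect_lte(fp, 0.5)
  # a lone transient scaled beyond the 100-SD artifact bound is rejected
  amp_sd <- stats::sd(abs(bandpass(wn, 1250, 15, NULL, order = 3)))
  wa <- wn
  i0 <- 1250 * 300
  tt <- seq(-0.05, 0.05, by = 1 / 1250)
  sharp <- exp(-tt^2 / (2 * 0.0025^2)) - 0.6 * exp(-tt^2 / (2 * 0.005^2))
  wa[i0 + seq_along(tt)] <- wa[i0 + seq_along(tt)] +
    150 * amp_sd * sharp / max(abs(sharp))
  ba <- noise_bundle(wa, wa)
  det_a <- detect_ied(ba, "HC")$events
  expect_false(any(abs(det_a$peak_s - 300) < 0.2))
  # monotonicity: raising the envelope multiplier never adds detections
  n5 <- nrow(detect_ied(fx$bundle, "HC", k_env = 5)$events)
  n7 <- nrow(detect_ied(fx$bundle, "HC", k_env = 7)$events)
  n9 <- nrow(detect_ied(fx$bundle, "HC", k_env = 9)$events)
  expect_true(n5 >= n7 && n7 >= n9)
  # too little NREM is a hard error
  short <- noise_bundle(rnorm(1250 * 30), rnorm(1250 * 30))
  expect_error(detect_ied(short, "HC"), "60 s")
})

test_that("spindle rules: duration filter, merging and amplitude clauses", {
  set.seed(12)
  fs <- 1250
  base <- rnorm(fs * 300, sd = 60)
  env0 <- hilbert_envelope(bandpass(base, fs, 10, 20, order = 4))
  amp_ok <- mean(env0) + 8 * stats::sd(env0)    # mid-band amplitude
  amp_big <- mean(env0) + 25 * stats::sd(env0)  # beyond the 14-SD clause
  inject_burst <- function(x, t0, dur, freq = 13, amp = amp_ok) {
    tt <- seq(0, dur, by = 1 / fs)
    env <- rep(1, length(tt))
    r <- floor(0.15 * length(tt))
    env[1:r] <- seq(0, 1, length.out = r)
    env[(length(tt) - r + 1):length(tt)] <- seq(1, 0, length.out = r)
    i0 <- round(t0 * fs)
    x[i0:(i0 + length(tt) - 1)] <- x[i0:(i0 + length(tt) - 1)] +
      amp * env * sin(2 * pi * freq * tt)
    x
  }
  x1 <- inject_burst(base, 150, 1.0)
  b1 <- noise_bundle(x1, x1)
  sp1 <- detect_spindles(b1, "MPFC")$events
  hit <- sp1[sp1$start_s < 151.2 & sp1$end_s > 149.9, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$end_s - hit$start_s >= 0.35 &&
                hit$end_s - hit$start_s <= 3)
  # a 0.3 s burst fails the duration filter
  x2 <- inject_burst(base, 150, 0.30)
  sp2 <- detect_spindles(noise_bundle(x2, x2), "MPFC")$events
  expect_false(any(sp2$start_s < 150.4 & sp2$end_s > 149.9))
  # two 0.5 s bursts 0.2 s apart merge into one event
  x3 <- inject_burst(inject_burst(base, 150, 0.5), 150.7, 0.5)
  sp3 <- detect_spindles(noise_bundle(x3, x3), "MPFC")$events
  inwin <- sp3[sp3$start_s < 151.3 & sp3$end_s > 149.8, ]
  expect_equal(nrow(inwin), 1)
  # over-amplitude bursts (artifact clause, > 14 SD) are rejected
  x4 <- inject_burst(base, 150, 1.0, amp = amp_big)
  sp4 <- detect_spindles(noise_bundle(x4, x4), "MPFC")$events
  expect_false(any(sp4$start_s < 151.2 & sp4$end_s > 149.8))
})

test_that("spindle recovery on the ground-truthed session", {
  fx <- fixture_recovery()
  gt <- fx$bundle$ground_truth$events
  tru <- gt[gt$kind == "SPINDLE" & gt$cancelled == 0, ]
  m <- match_interval_events(fx$spindles$events$start_s,
                             fx$spindles$events$end_s,
                             tru$t_start_s, tru$t_end_s)
  expect_gte(m["sensitivity"], 0.9)
  expect_gte(m["precision"], 0.9)
  durs <- fx$spindles$events$end_s - fx$spindles$events$start_s
  expect_true(all(durs >= 0.35 & durs <= 3.0))
})

test_that("DOWN-state clauses, durations and classification", {
  fx <- fixture_recovery()
  downs <- fx$downs
  expect_gt(nrow(downs), 50)
  durs <- downs$t_end - downs$t_start
  expect_true(all(durs >= 0.15 & durs <= 0.5))
  expect_true(all(downs$t_start < downs$t_peak & downs$t_peak < downs$t_end))
  # amplitude clauses hold for every accepted event
  ok <- (downs$z_peak > 1 & downs$z_end < -1.5) |
    (downs$z_peak > 2 & downs$z_end < 0)
  expect_true(all(ok))
  # pathological events follow hippocampal IEDs within 200 ms
  gt <- fx$bundle$ground_truth$events
  hc_t <- gt$t_peak_s[gt$origin == "hc_ied"]
  path_ok <- vapply(which(downs$pathological), function(i) {
    any(hc_t >= downs$t_start[i] - 0.2 & hc_t <= downs$t_peak[i])
  }, TRUE)
  expect_true(all(path_ok))
  # injected coupled DOWNs are recovered as pathological
  tru_d <- gt[gt$origin == "coupled_down" & gt$cancelled == 0, ]
  rec <- vapply(tru_d$t_peak_s, function(t) {
    any(abs(downs$t_peak - t) < 0.15 & downs$pathological)
  }, TRUE)
  expect_gt(mean(rec), 0.6)
  cls <- classify_transitions(downs)
  expect_equal(cls$counts[["pathological"]] + cls$counts[["physiological"]],
               nrow(downs))
  expect_equal(nrow(classify_transitions(downs[0, ])$pathological), 0)
  # without coupling, pathological co-occurrence is at chance level
  b0 <- generate_session(gen_params(duration_s = 600, p_couple = 0),
                         1, seed = 44)
  ied0 <- detect_ied(b0, "HC")
  mua0 <- sort(unlist(lapply(b0$units, `[[`, "spike_times_s")))
  d0 <- detect_down_states(b0, "MPFC", mua_times = mua0, ied_hc = ied0)
  n_ied <- nrow(ied0$events)
  nrem_s <- interval_duration(slice_by_state(b0, "NREM"))
  chance <- n_ied / nrem_s * 0.35         # rate x (window + start-to-peak)
  expect_lte(mean(d0$pathological),
             chance + 3 * sqrt(chance * (1 - chance) / nrow(d0)) + 0.02)
  # no MUA: validation flag unset with warning
  expect_warning(dn <- detect_down_states(fx$bundle, "MPFC",
                                          mua_times = NULL),
                 "multiunit")
  expect_true(all(is.na(dn$mua_validated)))
})

test_that("MUA validation marks injected DOWN states", {
  fx <- fixture_recovery()
  gt <- fx$bundle$ground_truth$events
  tru_d <- gt[gt$kind == "DOWN" & gt$cancelled == 0, ]
  downs <- fx$downs
  inj <- vapply(seq_len(nrow(downs)), function(i) {
    any(abs(tru_d$t_peak_s - downs$t_peak[i]) < 0.1)
  }, TRUE)
  # injected DOWNs (true spiking suppression) validate far more often than
  # incidental delta-wave troughs
  expect_gt(mean(downs$mua_validated[inj]), 0.5)
  expect_gt(mean(downs$mua_validated[inj]),
            mean(downs$mua_validated[!inj]) + 0.2)
})
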