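# Shared fixtures and matching helpers.  Heavy synthetic sessions are
# generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# the seed-fixed default-SNR 20-minute session of the detector-recovery
# criterion, plus its detections
fixture_recovery <- function() {
  fixture("recovery", function() {
    b <- generate_session(gen_params(), day_index = 3, seed = 11)
    ied_hc <- detect_ied(b, "HC")
    ied_mp <- detect_ied(b, "MPFC")
    sp <- detect_spindles(b, "MPFC", ied_series = ied_mp)
    mua <- sort(unlist(lapply(b$units, `[[`, "spike_times_s")))
    downs <- detect_down_states(b, "MPFC", mua_times = mua, ied_hc = ied_hc)
    list(bundle = b, ied_hc = ied_hc, ied_mp = ied_mp, spindles = sp,
         downs = downs)
  })
}

# a short session for cheap unit tests
fixture_short <- function() {
  fixture("short", function() {
    generate_session(gen_params(duration_s = 300), day_index = 2, seed = 21)
  })
}

# point-event matching at a tolerance: returns sensitivity and precision
match_point_events <- function(detected, truth, tol_s = 0.025) {
  if (!length(truth)) return(c(sensitivity = NA, precision = NA))
  tp <- vapply(truth, function(t) any(abs(detected - t) <= tol_s), TRUE)
  fp <- vapply(detected, function(t) all(abs(truth - t) > tol_s), TRUE)
  c(sensitivity = mean(tp),
    precision = if (length(detected)) 1 - mean(fp) else NA)
}

# interval-overlap matching for spindles
match_interval_events <- function(det_start, det_end, tru_start, tru_end) {
  ov <- function(a0, a1, b0v, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0v)) > 0
  sens <- mean(vapply(seq_along(tru_start), function(i) {
    any(ov(tru_start[i], tru_end[i], det_start, det_end))
  }, TRUE))
  prec <- mean(vapply(seq_along(det_start), function(i) {
    any(ov(det_start[i], det_end[i], tru_start, tru_end))
  }, TRUE))
  c(sensitivity = sens, precision = prec)
}

# minimal two-LFP-channel bundle from raw signal vectors (1250 Hz), scored
# as a single NREM block
noise_bundle <- function(hc, mpfc, accel = NULL, fs = 1250) {
  n <- length(hc)
  chans <- list(channel_info("hc1", "HC", "LFP"),
                channel_info("mpfc1", "MPFC", "LFP"))
  mat <- cbind(hc, mpfc)
  if (!is.null(accel)) {
    chans <- c(chans, list(channel_info("accel", "OTHER", "ACCEL")))
    mat <- cbind(mat, accel)
  }
  meta <- session_meta("noise", 0, "BASELINE", fs, n, chans)
  session_bundle(meta, mat, state_intervals(0, n / fs, "NREM"))
}
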