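# Offline event detectors: sleep scoring, multiunit threshold crossings,
# IEDs, sleep spindles and cortical DOWN states.
#
# All detectors operate on the canonical 1250 Hz LFP, use zero-phase
# filtering so event timing is unbiased, and compute their baseline
# statistics over NREM sleep (excluding stimulation-artifact blanking
# intervals recorded in `bundle$blank_intervals`, when present).

nrem_baseline_mask <- function(bundle, n, region = "MPFC") {
  fs <- bundle$meta$fs_hz
  m <- interval_mask(slice_by_state(bundle, "NREM"), n, fs)
  # artifact-blanked samples exist only on the (stimulated) cortical
  # channels; hippocampal data remain observable throughout
  if (identical(region, "MPFC") &&
      !is.null(bundle$blank_intervals) && nrow(bundle$blank_intervals)) {
    m[interval_mask(bundle$blank_intervals, n, fs)] <- FALSE
  }
  m
}

#' Threshold-based sleep scoring
#'
#' Scores the session in fixed windows: WAKE when accelerometer power
#' exceeds `motion_thr`; otherwise REM when the hippocampal theta (5-8 Hz)
#' to delta (0.5-4 Hz) power ratio exceeds `r_rem`; otherwise NREM when the
#' cortical delta log-power z-score exceeds `d_nrem`.  Window labels are
#' smoothed by a 5-window majority vote and merged into intervals.
#' Windows matching no rule are labelled WAKE (indeterminate/drowsy).
#'
#' @param bundle Session bundle with HC and MPFC LFP plus an accelerometer
#'   channel.
#' @param window_s Scoring window (s), default 1.
#' @param r_rem Theta/delta ratio threshold for REM (default 2).
#' @param d_nrem Cortical delta log-power robust-z threshold for NREM
#'   (default -1.5: delta power must not collapse below the session's
#'   typical sleep level; 1-s delta power estimates are noisy, so the
#'   margin is wide).
#' @param motion_thr Accelerometer mean-square threshold; default
#'   `1e4` (amplitude units squared).
#' @param assume_immobile If `TRUE`, score without an accelerometer
#'   (no WAKE from motion).
#' @return A [state_intervals()] table.
#' @export
score_sleep <- function(bundle, window_s = 1, r_rem = 2, d_nrem = -1.5,
                        motion_thr = 1e4, assume_immobile = FALSE) {
  fs <- bundle$meta$fs_hz
  acc <- channel_by_kind(bundle, "ACCEL")
  if (is.null(acc) && !assume_immobile) {
    stop("no accelerometer channel; rerun with `assume_immobile = TRUE` ",
         "(--assume-immobile) if the animal is known to be still")
  }
  hc <- get_channel(bundle, "HC")
  mp <- get_channel(bundle, "MPFC")
  n <- length(hc)
  wlen <- round(window_s * fs)
  nw <- floor(n / wlen)
  idx <- rep(seq_len(nw), each = wlen)
  win_ms <- function(x) {
    unname(tapply(x[seq_len(nw * wlen)]^2, idx, mean))
  }
  hc_th <- bandpass(hc, fs, 5, 8)
  hc_de <- bandpass(hc, fs, 0.5, 4)
  mp_de <- bandpass(mp, fs, 0.5, 4)
  p_th <- win_ms(hc_th)
  p_de <- win_ms(hc_de)
  p_mpde <- win_ms(mp_de)
  lg <- log10(p_mpde + 1e-12)
  # robust z: sessions are typically NREM-dominated, so a mean/SD z-score
  # would centre on (and reject) the NREM windows themselves; the robust
  # scale keeps the rule "delta power not collapsed relative to typical
  # sleep" meaningful regardless of class balance
  mad_lg <- max(1.4826 * stats::mad(lg, constant = 1), 1e-3)
  z_de <- (lg - stats::median(lg)) / mad_lg
  floor_ok <- p_mpde > 25            # absolute noise floor (5 uV RMS)
  lab <- rep("WAKE", nw)
  moving <- if (is.null(acc)) rep(FALSE, nw) else win_ms(acc) > motion_thr
  ratio <- p_th / pmax(p_de, 1e-12)
  lab[!moving & ratio > r_rem] <- "REM"
  lab[!moving & ratio <= r_rem & z_de > d_nrem & floor_ok] <- "NREM"
  # 5-window majority smoothing
  sm <- lab
  for (i in seq_len(nw)) {
    lo <- max(1, i - 2)
    hi <- min(nw, i + 2)
    tb <- table(lab[lo:hi])
    sm[i] <- names(tb)[which.max(tb)]
  }
  r <- rle(sm)
  ends <- cumsum(r$lengths) * window_s
  starts <- c(0, ends[-length(ends)])
  ends[length(ends)] <- n / fs
  state_intervals(starts, ends, r$values)
}

#' Multiunit threshold-crossing detection
#'
#' Bandpasses the channel, finds peaks by the derivative sign change
#' (shift-compare) and keeps peaks whose magnitude exceeds a median-based
#' noise threshold `thr_mult * median(|x|) / 0.6745`.
#'
#' @param bundle Session bundle.
#' @param channel Channel label or region.
#' @param band Filter band (Hz); the upper edge is clipped below Nyquist
#'   with a warning if needed.  Default `c(80, 300)`, a spiking-band proxy
#'   at the 1250 Hz analysis rate.
#' @param thr_mult Threshold multiplier (default 5).
#' @return Numeric vector of spike times (s).
#' @export
detect_mua <- function(bundle, channel, band = c(80, 300), thr_mult = 5) {
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, channel)
  f <- bandpass(x, fs, band[1], band[2], order = 3)
  thr <- thr_mult * stats::median(abs(f)) / 0.6745
  a <- abs(f)
  d <- diff(a)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  pk <- pk[a[pk] > thr]
  (pk - 1) / fs
}

# contiguous runs of TRUE -> start/end indices
runs_true <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect interictal epileptiform discharges
#'
#' Four-step detector: (1) zero-phase 50-85 Hz bandpass and rectification
#' giving the detection envelope; (2) candidate epochs where the envelope
#' exceeds its NREM-baseline median by `k_env` baseline standard deviations
#' (two-pass: candidate epochs are excluded from the baseline before the
#' final threshold); (3) candidates are kept only if the >15 Hz high-passed
#' waveform within +/-50 ms of the envelope peak exceeds the high-pass
#' baseline mean by `k_wave` SD; (4) candidates whose amplitude exceeds the
#' baseline mean by more than `k_artifact` SD are discarded as artifacts.
#' Candidates closer than 100 ms are merged keeping the larger peak.
#'
#' @param bundle Session bundle.
#' @param channel Channel label or region (`"HC"`, `"MPFC"`).
#' @param nrem_only Restrict detection to NREM epochs (default `TRUE`).
#' @param k_env Envelope threshold multiplier (default 5).
#' @param k_wave Waveform-amplitude confirmation multiplier (default 10).
#' @param k_artifact Artifact rejection multiplier (default 100).
#' @param band Detection band (default 50-85 Hz).
#' @param robust_sd Use 1.4826 * MAD instead of SD for the envelope baseline.
#' @return An [event_series()] of kind `"IED"`.
#' @export
detect_ied <- function(bundle, channel, nrem_only = TRUE, k_env = 5,
                       k_wave = 10, k_artifact = 100, band = c(50, 85),
                       robust_sd = FALSE) {
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, channel)
  n <- length(x)
  base_mask <- nrem_baseline_mask(bundle, n, region_guess(bundle, channel))
  if (sum(base_mask) / fs < 60) {
    stop("less than 60 s of NREM available: baseline statistics unreliable")
  }
  env <- abs(bandpass(x, fs, band[1], band[2], order = 4))
  hp <- bandpass(x, fs, 15, NULL, order = 3)
  sd_fun <- if (robust_sd) function(v) 1.4826 * stats::mad(v, constant = 1)
            else stats::sd
  # pass 1: provisional threshold over full NREM baseline
  med1 <- stats::median(env[base_mask])
  thr1 <- med1 + k_env * sd_fun(env[base_mask])
  cand1 <- env > thr1 & base_mask
  # pass 2: exclude +/-100 ms around provisional candidates from baseline
  excl <- cand1
  w <- round(0.1 * fs)
  hits <- which(cand1)
  if (length(hits)) {
    lo <- pmax(1L, hits - w)
    hi <- pmin(n, hits + w)
    for (i in seq_along(hits)) excl[lo[i]:hi[i]] <- TRUE
  }
  bm2 <- base_mask & !excl
  if (sum(bm2) < fs) bm2 <- base_mask
  med <- stats::median(env[bm2])
  thr <- med + k_env * sd_fun(env[bm2])
  hp_mu <- mean(abs(hp[bm2]))
  hp_sd <- stats::sd(abs(hp[bm2]))
  det_mask <- if (nrem_only) base_mask else rep(TRUE, n)
  cand <- runs_true(env > thr & det_mask)
  if (!nrow(cand)) {
    return(event_series(empty_events(), region_guess(bundle, channel), "IED",
                        params = ied_params(k_env, k_wave, k_artifact, band)))
  }
  pk_idx <- mapply(function(a, b) a - 1L + which.max(env[a:b]),
                   cand$start, cand$end)
  # merge candidates closer than 100 ms (chain grouping), keeping the
  # largest envelope peak of each group
  pk_idx <- sort(pk_idx)
  grp <- cumsum(c(1L, as.integer(diff(pk_idx) >= 0.1 * fs)))
  pk_idx <- vapply(split(pk_idx, grp),
                   function(ix) ix[which.max(env[ix])], 0L)
  pk_idx <- unname(pk_idx)
  w50 <- round(0.05 * fs)
  amp <- vapply(pk_idx, function(i) {
    max(abs(hp[max(1, i - w50):min(n, i + w50)]))
  }, 0)
  ok <- amp > hp_mu + k_wave * hp_sd & amp <= hp_mu + k_artifact * hp_sd
  pk_idx <- pk_idx[ok]
  amp <- amp[ok]
  if (!length(pk_idx)) {
    return(event_series(empty_events(), region_guess(bundle, channel), "IED",
                        params = ied_params(k_env, k_wave, k_artifact, band)))
  }
  ev <- data.frame(kind = "IED", channel = channel_label(bundle, channel),
                   start_s = (pk_idx - 1) / fs - 0.05,
                   peak_s = (pk_idx - 1) / fs,
                   end_s = (pk_idx - 1) / fs + 0.05,
                   amplitude_uv = amp, stringsAsFactors = FALSE)
  event_series(ev, region_guess(bundle, channel), "IED",
               params = ied_params(k_env, k_wave, k_artifact, band))
}

ied_params <- function(k_env, k_wave, k_artifact, band) {
  list(detector = "ied", k_env = k_env, k_wave = k_wave,
       k_artifact = k_artifact, band_hz = band)
}

channel_label <- function(bundle, channel) {
  labels <- vapply(bundle$meta$channels, `[[`, "", "label")
  if (channel %in% labels) return(channel)
  regions <- vapply(bundle$meta$channels, `[[`, "", "region")
  kinds <- vapply(bundle$meta$channels, `[[`, "", "kind")
  labels[which(regions == channel & kinds == "LFP")[1]]
}

region_guess <- function(bundle, channel) {
  lab <- channel_label(bundle, channel)
  region_of_channel(bundle$meta$channels, lab)
}

#' Detect sleep spindles
#'
#' 10-20 Hz zero-phase Butterworth (order 4), rectification and
#' analytic-signal envelope; events where the envelope exceeds the NREM
#' baseline mean by 2 SD with an interior peak between 4 and 14 SD above
#' baseline; start/end at the 2 SD crossings; events separated by less than
#' 250 ms merged; duration filter 0.35-3 s applied after merging.  The
#' baseline excludes `ied_excl_s` around each cortical IED.
#'
#' @param bundle Session bundle.
#' @param channel Cortical channel label or region.
#' @param ied_series Cortical IED [event_series()] (may be empty) whose
#'   epochs are excluded from the baseline.
#' @param ied_excl_s Half-width of the IED exclusion window (default 0.2 s).
#' @param band Filter band (default 10-20 Hz).
#' @return An [event_series()] of kind `"SPINDLE"` with a `peak_sd` column
#'   (interior peak height in baseline SD units).
#' @export
detect_spindles <- function(bundle, channel, ied_series = NULL,
                            ied_excl_s = 0.2, band = c(10, 20)) {
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, channel)
  n <- length(x)
  f <- bandpass(x, fs, band[1], band[2], order = 4)
  env <- hilbert_envelope(f)
  bm <- nrem_baseline_mask(bundle, n, region_guess(bundle, channel))
  if (sum(bm) / fs < 60) {
    stop("less than 60 s of NREM available: baseline statistics unreliable")
  }
  if (!is.null(ied_series) && nrow(ied_series$events)) {
    iv <- data.frame(start_s = ied_series$events$peak_s - ied_excl_s,
                     end_s = ied_series$events$peak_s + ied_excl_s)
    bm[interval_mask(iv, n, fs)] <- FALSE
  }
  ied_pk <- if (!is.null(ied_series) && nrow(ied_series$events)) {
    ied_series$events$peak_s
  } else {
    numeric(0)
  }
  # two-pass baseline: provisional supra-2SD epochs (the spindles
  # themselves) are excluded before the final baseline statistics, exactly
  # as for the IED envelope baseline; otherwise the baseline SD is dominated
  # by the events it is meant to measure
  mu1 <- mean(env[bm])
  sd1 <- stats::sd(env[bm])
  excl <- env > mu1 + 2 * sd1
  hits <- which(excl)
  if (length(hits)) {
    w <- round(0.1 * fs)
    lo <- pmax(1L, hits - w)
    hi <- pmin(n, hits + w)
    for (i in seq_along(hits)) excl[lo[i]:hi[i]] <- TRUE
  }
  bm2 <- bm & !excl
  if (sum(bm2) < fs) bm2 <- bm
  mu <- mean(env[bm2])
  sdv <- stats::sd(env[bm2])
  lo_thr <- mu + 2 * sdv
  cand <- runs_true(env > lo_thr & interval_mask(
    slice_by_state(bundle, "NREM"), n, fs))
  if (!nrow(cand)) {
    return(event_series(empty_events(), region_guess(bundle, channel),
                        "SPINDLE"))
  }
  # merge events with gaps < 250 ms
  merged <- list()
  cs <- cand$start[1]; ce <- cand$end[1]
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if ((cand$start[i] - ce) / fs < 0.25) {
        ce <- cand$end[i]
      } else {
        merged[[length(merged) + 1]] <- c(cs, ce)
        cs <- cand$start[i]; ce <- cand$end[i]
      }
    }
  }
  merged[[length(merged) + 1]] <- c(cs, ce)
  rows <- lapply(merged, function(se) {
    a <- se[1]; b <- se[2]
    dur <- (b - a) / fs
    if (dur < 0.35 || dur > 3.0) return(NULL)
    pk <- a - 1L + which.max(env[a:b])
    pk_sd <- (env[pk] - mu) / sdv
    if (pk_sd < 4 || pk_sd > 14) return(NULL)
    # spindle-band leakage of a cortical IED is not a spindle: discard
    # candidates peaking inside an excluded IED epoch
    if (length(ied_pk) && min(abs((pk - 1) / fs - ied_pk)) <= ied_excl_s) {
      return(NULL)
    }
    data.frame(kind = "SPINDLE", channel = channel_label(bundle, channel),
               start_s = (a - 1) / fs, peak_s = (pk - 1) / fs,
               end_s = (b - 1) / fs, amplitude_uv = env[pk],
               peak_sd = pk_sd, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(ev)) ev <- empty_events()
  event_series(ev, region_guess(bundle, channel), "SPINDLE",
               params = list(detector = "spindle", band_hz = band,
                             ied_excl_s = ied_excl_s))
}

#' Detect cortical DOWN states
#'
#' Filters the cortical LFP 0.5-6 Hz, z-scores it over NREM, and takes
#' candidate (start, peak, end) triples from upward-downward-upward
#' zero-crossings of the derivative of Z(t).  Events are accepted when
#' `Z(peak) > 1 & Z(end) < -1.5` or `Z(peak) > 2 & Z(end) < 0`, with
#' durations restricted to 0.15-0.5 s.  Each event is validated against
#' multiunit activity (rate in peak +/- 100 ms below half the session NREM
#' rate) and classified as pathological when a hippocampal IED peak
#' precedes its start by at most `path_window_s`.
#'
#' @param bundle Session bundle.
#' @param lfp_channel Cortical channel label or region.
#' @param mua_times Multiunit spike times (s); `NULL` leaves `mua_validated`
#'   unset with a warning.
#' @param ied_hc Hippocampal IED [event_series()] (may be `NULL`).
#' @param path_window_s Pathological-coupling window before start
#'   (default 0.2 s).
#' @return A data.frame of DOWN states: `t_start`, `t_peak`, `t_end`,
#'   `z_peak`, `z_end`, `mua_validated`, `pathological`.
#' @export
detect_down_states <- function(bundle, lfp_channel, mua_times = NULL,
                               ied_hc = NULL, path_window_s = 0.2) {
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, lfp_channel)
  n <- length(x)
  f <- bandpass(x, fs, 0.5, 6, order = 4)
  bm <- nrem_baseline_mask(bundle, n, region_guess(bundle, lfp_channel))
  z <- (f - mean(f[bm])) / stats::sd(f[bm])
  dz <- diff(z)
  sgn <- sign(dz)
  flips <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  up <- flips[sgn[flips + 1] > 0] + 1L    # local minima of z
  dn <- flips[sgn[flips + 1] < 0] + 1L    # local maxima of z
  nrem_mask <- interval_mask(slice_by_state(bundle, "NREM"), n, fs)
  rows <- list()
  if (length(up) >= 2 && length(dn) >= 1) {
    # for each maximum, bracket with the nearest minima
    prev_up <- findInterval(dn, up)
    ok <- prev_up >= 1 & prev_up < length(up)
    dn_ok <- dn[ok]
    us <- up[prev_up[ok]]
    ue <- up[prev_up[ok] + 1L]
    for (i in seq_along(dn_ok)) {
      s <- us[i]; pkv <- dn_ok[i]; e <- ue[i]
      if (!nrem_mask[pkv]) next
      zp <- z[pkv]; ze <- z[e]
      if (!((zp > 1 && ze < -1.5) || (zp > 2 && ze < 0))) next
      dur <- (e - s) / fs
      if (dur < 0.15 || dur > 0.5) next
      rows[[length(rows) + 1]] <- data.frame(
        t_start = (s - 1) / fs, t_peak = (pkv - 1) / fs, t_end = (e - 1) / fs,
        z_peak = zp, z_end = ze)
    }
  }
  if (!length(rows)) {
    out <- data.frame(t_start = numeric(), t_peak = numeric(),
                      t_end = numeric(), z_peak = numeric(),
                      z_end = numeric(), mua_validated = logical(),
                      pathological = logical())
    return(out)
  }
  out <- do.call(rbind, rows)
  if (is.null(mua_times) || !length(mua_times)) {
    warning("no multiunit activity supplied; mua_validated left unset")
    out$mua_validated <- NA
  } else {
    nrem_iv <- slice_by_state(bundle, "NREM")
    base_rate <- sum(in_intervals(mua_times, nrem_iv)) /
      interval_duration(nrem_iv)
    cnt <- vapply(out$t_peak, function(tp) {
      sum(mua_times >= tp - 0.1 & mua_times < tp + 0.1)
    }, 0)
    out$mua_validated <- (cnt / 0.2) < 0.5 * base_rate
  }
  if (is.null(ied_hc) || !nrow(ied_hc$events)) {
    out$pathological <- FALSE
  } else {
    pk <- ied_hc$events$peak_s
    # the IED must precede the DOWN peak and fall within the coupling
    # window of the (zero-crossing-derived, hence jittery) start
    out$pathological <- vapply(seq_len(nrow(out)), function(i) {
      any(pk >= out$t_start[i] - path_window_s & pk <= out$t_peak[i])
    }, TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Partition DOWN states into pathological and physiological
#'
#' @param downs DOWN-state data.frame from [detect_down_states()].
#' @return List with `pathological`, `physiological` (data.frames) and
#'   `counts`.
#' @export
classify_transitions <- function(downs) {
  pat <- downs[downs$pathological %in% TRUE, , drop = FALSE]
  phy <- downs[!(downs$pathological %in% TRUE), , drop = FALSE]
  list(pathological = pat, physiological = phy,
       counts = c(pathological = nrow(pat), physiological = nrow(phy)))
}

#' Blank stimulation artifacts
#'
#' Replaces samples within `width_s` of each stimulation time by linear
#' interpolation across the gap and records the blanked intervals so that
#' detector baselines exclude them.
#'
#' @param bundle Session bundle.
#' @param stim_times Stimulation times (s); defaults to the bundle's STIM
#'   series if present.
#' @param width_s Half-width of the blanking window (default 0.1 s,
#'   i.e. the 200 ms artifact).
#' @return The bundle with interpolated LFP and a `blank_intervals` field.
#' @export
blank_artifacts <- function(bundle, stim_times = NULL, width_s = 0.1) {
  if (is.null(stim_times)) {
    st <- bundle$event_series[["STIM:mpfc1"]]
    stim_times <- if (is.null(st)) numeric(0) else st$events$peak_s
  }
  if (!length(stim_times)) return(bundle)
  fs <- bundle$meta$fs_hz
  n <- bundle$meta$n_samples
  # stimulation is delivered across cortical layers; only cortical channels
  # carry the artifact
  for (ci in seq_along(bundle$meta$channels)) {
    if (bundle$meta$channels[[ci]]$kind != "LFP" ||
        bundle$meta$channels[[ci]]$region != "MPFC") next
    x <- bundle$lfp[, ci]
    for (t in stim_times) {
      a <- max(1L, floor((t - width_s) * fs))
      b <- min(n, ceiling((t + width_s) * fs))
      if (b > a) {
        x[a:b] <- seq(x[a], x[b], length.out = b - a + 1)
      }
    }
    bundle$lfp[, ci] <- x
  }
  bundle$blank_intervals <- data.frame(start_s = stim_times - width_s,
                                       end_s = stim_times + width_s)
  bundle
}
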