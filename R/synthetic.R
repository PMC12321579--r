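# Seeded synthetic-session generator emulating NREM-dominated recordings
# from a hippocampal kindling model: pink-noise LFP background with
# state-dependent slow-oscillation/theta content, hippocampal IEDs
# (biphasic sharp + slow-wave transients, 0.5-2.5 mV), IED-coupled cortical
# DOWN-state -> spindle sequences, independent cortical IEDs, event-modulated
# spike trains, an accelerometer channel and a day-indexed kindling schedule.
#
# The generator is split into a *plan* (pure event bookkeeping, the ground
# truth) and a *render* (LFP + spike synthesis), so that the closed-loop
# scenario can cancel planned cortical responses after stimulation without
# re-drawing anything else.

#' Synthetic-session generator parameters
#'
#' Returns the default parameter set; any field can be overridden through
#' `...`.  Amplitudes are microvolts relative to the channel baseline, rates
#' are events per minute of NREM sleep.
#'
#' @param ... Named overrides of the defaults.
#' @return A `gen_params` list.
#' @export
gen_params <- function(...) {
  p <- list(
    fs_hz = 1250,
    duration_s = 1200,
    # background
    pink_sd_uv = 90,
    so_amp_uv = 150,         # mPFC slow oscillation (0.5-4 Hz) in NREM
    hc_delta_amp_uv = 80,    # HC delta in NREM
    theta_amp_uv = 120,      # HC theta (5-8 Hz) in REM
    # hippocampal IEDs
    hc_ied_rate_min = 6,
    hc_ied_amp_uv = c(500, 2500),
    ied_sharp_ms = 40,
    ied_slow_ms = 250,
    ied_refractory_s = 1,
    # HC -> mPFC coupling
    p_couple = 0.7,
    couple_lag_mean_s = 0.15,
    couple_lag_sd_s = 0.03,
    down_amp_uv = c(400, 50),        # mean, sd
    down_dur_s = 0.30,
    spindle_delay_s = c(0.05, 0.15), # DOWN peak -> spindle onset (uniform)
    spindle_freq_hz = c(10, 16),
    spindle_dur_s = c(0.5, 1.5),
    spindle_amp_uv = c(105, 165),
    # HC IED propagation into mPFC (hippocampal-dependent cortical IEDs)
    p_propagate = 0.35,
    propagate_lag_s = 0.02,
    propagate_amp_frac = 0.5,
    # independent cortical IEDs
    ind_mpfc_rate_min = 0,
    ind_mpfc_amp_uv = c(400, 2000),
    # physiological background events
    spindle_bg_rate_min = 8,
    down_bg_rate_min = 8,
    down_bg_amp_uv = c(380, 50),
    # detection-free sharpness substrate: kindling progressively roughens
    # the cortical LFP texture -- a continuous high-band (50-150 Hz)
    # component scaled by (sharpness_gain - 1) -- plus sparse
    # millisecond-scale micro-transients
    sharpness_gain = 1,
    rough_uv_per_gain = 12,
    micro_rate_min = 40,
    micro_amp_uv = 25,
    micro_width_ms = 8,
    # spiking
    n_pyr = 20, n_int = 5,
    pyr_rate_hz = 1.5, int_rate_hz = 8,
    ied_gain = 5, ied_gain_dur_s = 0.05,
    down_suppression = 0.1,
    up_gain = 2, up_gain_dur_s = 0.5,
    # motion
    accel_wake_sd = 300, accel_sleep_sd = 15,
    # behavioral-state block schedule (repeating cycle, seconds)
    state_cycle = c(NREM = 270, REM = 45, NREM2 = 270, WAKE = 45)
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown gen_params field(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$p_couple >= 0, p$p_couple <= 1, p$hc_ied_rate_min >= 0,
            p$ind_mpfc_rate_min >= 0)
  structure(p, class = "gen_params")
}

#' Build the block behavioral-state schedule for a session
#' @param params A [gen_params()] list.
#' @return A [state_intervals()] table covering the session.
#' @export
make_state_schedule <- function(params) {
  cyc <- params$state_cycle
  labs <- sub("[0-9]+$", "", names(cyc))
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- 0
  i <- 1
  while (t < params$duration_s) {
    d <- unname(cyc[(i - 1) %% length(cyc) + 1])
    lab <- labs[(i - 1) %% length(labs) + 1]
    e <- min(t + d, params$duration_s)
    starts <- c(starts, t); ends <- c(ends, e); states <- c(states, lab)
    t <- e
    i <- i + 1
  }
  state_intervals(starts, ends, states)
}

# Poisson event times within intervals with a dead-time refractory and an
# edge margin keeping full templates inside the interval.
draw_poisson_times <- function(rate_per_min, intervals, refractory_s = 0,
                               edge_s = 0.5) {
  if (rate_per_min <= 0 || !nrow(intervals)) return(numeric(0))
  rate_hz <- rate_per_min / 60
  out <- numeric(0)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start_s[i] + edge_s
    b <- intervals$end_s[i] - edge_s
    if (b <= a) next
    t <- a
    repeat {
      t <- t + stats::rexp(1, rate_hz)
      if (t >= b) break
      out <- c(out, t)
      t <- t + refractory_s
    }
  }
  out
}

#' Plan a synthetic session (ground-truth events only)
#'
#' Draws every injected event (hippocampal IEDs, coupled DOWN/spindle
#' sequences, propagated and independent cortical IEDs, background spindles
#' and DOWN states) without rendering any signal.  Fully deterministic given
#' `(params, day_index, seed)`.
#'
#' @param params A [gen_params()] list.
#' @param day_index Day index (0 = baseline).
#' @param seed Integer seed.
#' @return A `session_plan` list with `params`, `states`, `events` (the
#'   ground-truth table), `day_index`, `seed`.
#' @export
plan_session <- function(params, day_index = 0, seed = 1) {
  states <- make_state_schedule(params)
  nrem <- states[states$state == "NREM", , drop = FALSE]
  if (interval_duration(nrem) < 120) {
    stop("session too short: need at least 120 s of NREM to place events")
  }
  ev <- with_seed(derive_seed(seed, 1), {
    rows <- list()
    nid <- 0
    add <- function(kind, region, origin, t_start, t_peak, t_end, amp,
                    freq = NA_real_, link = 0L) {
      nid <<- nid + 1
      rows[[length(rows) + 1]] <<- data.frame(
        id = nid, kind = kind, region = region, origin = origin,
        t_start_s = t_start, t_peak_s = t_peak, t_end_s = t_end,
        amplitude_uv = amp, freq_hz = freq, link = as.integer(link),
        cancelled = 0L, stringsAsFactors = FALSE)
      nid
    }
    # hippocampal IEDs
    hc_t <- draw_poisson_times(params$hc_ied_rate_min, nrem,
                               params$ied_refractory_s, edge_s = 1)
    for (t in hc_t) {
      amp <- stats::runif(1, params$hc_ied_amp_uv[1], params$hc_ied_amp_uv[2])
      iid <- add("IED", "HC", "hc_ied", t - 0.05, t, t + 0.3, amp)
      if (stats::runif(1) < params$p_propagate) {
        add("IED", "MPFC", "prop_ied", t + params$propagate_lag_s - 0.05,
            t + params$propagate_lag_s, t + params$propagate_lag_s + 0.3,
            amp * params$propagate_amp_frac, link = iid)
      }
      if (stats::runif(1) < params$p_couple) {
        lag <- stats::rnorm(1, params$couple_lag_mean_s,
                            params$couple_lag_sd_s)
        lag <- max(lag, 0.05)
        dpk <- t + lag
        damp <- stats::rnorm(1, params$down_amp_uv[1], params$down_amp_uv[2])
        dd <- params$down_dur_s
        did <- add("DOWN", "MPFC", "coupled_down", dpk - 0.4 * dd, dpk,
                   dpk + 0.6 * dd, damp, link = iid)
        onset <- dpk + stats::runif(1, params$spindle_delay_s[1],
                                    params$spindle_delay_s[2])
        sdur <- stats::runif(1, params$spindle_dur_s[1],
                             params$spindle_dur_s[2])
        sfrq <- stats::runif(1, params$spindle_freq_hz[1],
                             params$spindle_freq_hz[2])
        samp <- stats::runif(1, params$spindle_amp_uv[1],
                             params$spindle_amp_uv[2])
        add("SPINDLE", "MPFC", "coupled_spindle", onset, onset + sdur / 2,
            onset + sdur, samp, freq = sfrq, link = iid)
      }
    }
    # independent cortical IEDs: kept clear of hippocampal IEDs so the
    # ground-truth independence labelling is unambiguous
    ind_t <- draw_poisson_times(params$ind_mpfc_rate_min, nrem,
                                params$ied_refractory_s, edge_s = 1)
    if (length(hc_t)) {
      keep <- vapply(ind_t, function(t) min(abs(t - hc_t)) > 0.3, TRUE)
      ind_t <- ind_t[keep]
    }
    for (t in ind_t) {
      amp <- stats::runif(1, params$ind_mpfc_amp_uv[1],
                          params$ind_mpfc_amp_uv[2])
      add("IED", "MPFC", "ind_ied", t - 0.05, t, t + 0.3, amp)
    }
    # background (physiological) spindles and DOWN states
    df0 <- do.call(rbind, rows)
    sp_pk <- df0$t_peak_s[df0$kind == "SPINDLE"]
    bg_sp <- draw_poisson_times(params$spindle_bg_rate_min, nrem, 1.5,
                                edge_s = 2)
    for (t in bg_sp) {
      if (length(sp_pk) && min(abs(t - sp_pk)) < 2) next
      sdur <- stats::runif(1, params$spindle_dur_s[1], params$spindle_dur_s[2])
      sfrq <- stats::runif(1, params$spindle_freq_hz[1],
                           params$spindle_freq_hz[2])
      samp <- stats::runif(1, params$spindle_amp_uv[1],
                           params$spindle_amp_uv[2])
      add("SPINDLE", "MPFC", "bg_spindle", t, t + sdur / 2, t + sdur, samp,
          freq = sfrq)
    }
    dn_pk <- df0$t_peak_s[df0$kind == "DOWN"]
    bg_dn <- draw_poisson_times(params$down_bg_rate_min, nrem, 0.8,
                                edge_s = 1)
    for (t in bg_dn) {
      if (length(dn_pk) && min(abs(t - dn_pk)) < 1) next
      damp <- stats::rnorm(1, params$down_bg_amp_uv[1],
                           params$down_bg_amp_uv[2])
      dd <- params$down_dur_s
      add("DOWN", "MPFC", "bg_down", t - 0.4 * dd, t, t + 0.6 * dd, damp)
    }
    df <- do.call(rbind, rows)
    df[order(df$t_peak_s), , drop = FALSE]
  })
  rownames(ev) <- NULL
  structure(list(params = params, day_index = as.integer(day_index),
                 seed = as.integer(seed), states = states, events = ev,
                 stim_times_s = numeric(0)),
            class = "session_plan")
}

#' Apply the network effect of stimulation to a session plan
#'
#' Each stimulation landing within `effect_window_s` after a coupled
#' hippocampal IED cancels, with probability `p_eff`, that IED's planned
#' DOWN + spindle injection (and the associated spike suppression/burst).
#' A 200 ms Gaussian artifact is later rendered on the cortical channel at
#' every stimulation time.  Stimulation at time t only ever affects planned
#' activity after t.
#'
#' @param plan A `session_plan`.
#' @param stim_times Stimulation times (s).
#' @param p_eff Cancellation probability in `[0, 1]`.
#' @param effect_window_s Post-IED window in which stimulation is effective
#'   (default 0.15 s).
#' @return The modified plan (cancelled flags set, `stim_times_s` recorded).
#' @export
attach_stim_effect <- function(plan, stim_times, p_eff,
                               effect_window_s = 0.15) {
  stopifnot(p_eff >= 0, p_eff <= 1)
  dur <- plan$params$duration_s
  if (any(stim_times >= dur)) {
    warning("ignoring stimulation times beyond session end")
    stim_times <- stim_times[stim_times < dur]
  }
  stim_times <- sort(stim_times)
  ev <- plan$events
  hc <- ev[ev$origin == "hc_ied", , drop = FALSE]
  if (nrow(hc) && length(stim_times) && p_eff > 0) {
    draws <- with_seed(derive_seed(plan$seed, 999),
                       stats::runif(nrow(hc)))
    for (i in seq_len(nrow(hc))) {
      tpk <- hc$t_peak_s[i]
      # effective from IED onset (the sharp wave spans ~50 ms before the
      # peak and online detection fires on its rising flank) until
      # effect_window_s after the peak -- always before the coupled DOWN
      hit <- any(stim_times >= tpk - 0.05 &
                   stim_times <= tpk + effect_window_s)
      if (hit && draws[i] < p_eff) {
        dep <- ev$link == hc$id[i] & ev$origin %in%
          c("coupled_down", "coupled_spindle")
        ev$cancelled[dep] <- 1L
      }
    }
  }
  plan$events <- ev
  plan$stim_times_s <- stim_times
  plan
}

# ---- rendering -------------------------------------------------------------

ied_template <- function(fs, sharp_ms, slow_ms, amp) {
  # biphasic: difference-of-Gaussians sharp transient carrying 50-85 Hz
  # content, followed by an opposite-polarity slow wave
  s1 <- 0.0025; s2 <- 0.005                      # seconds, sharp DoG
  s_slow <- slow_ms / 1000 / 6
  tt <- seq(-0.15, 0.45, by = 1 / fs)
  sharp <- exp(-tt^2 / (2 * s1^2)) - 0.6 * exp(-tt^2 / (2 * s2^2))
  sharp <- sharp / max(abs(sharp))
  slow <- -0.4 * exp(-(tt - 0.08)^2 / (2 * s_slow^2))
  w <- amp * (sharp + slow)
  list(w = w, center = which.min(abs(tt)))
}

down_template <- function(fs, dur_s, amp) {
  tt <- seq(-0.4, 0.6, by = 1 / fs)
  pk <- exp(-tt^2 / (2 * 0.06^2))
  tr <- -0.85 * exp(-(tt - 0.6 * dur_s)^2 / (2 * 0.08^2))
  w <- amp * (pk + tr)
  list(w = w, center = which.min(abs(tt)))
}

spindle_template <- function(fs, dur_s, freq_hz, amp, phase = 0) {
  tt <- seq(0, dur_s, by = 1 / fs)
  # tapered-cosine (Tukey) envelope: waxing-waning edges with a sustained
  # core, so the supra-threshold extent tracks the nominal duration
  r <- 0.3
  n <- length(tt)
  env <- rep(1, n)
  ramp <- floor(r * n / 2)
  if (ramp > 0) {
    env[1:ramp] <- 0.5 * (1 - cos(pi * (0:(ramp - 1)) / ramp))
    env[(n - ramp + 1):n] <- rev(env[1:ramp])
  }
  w <- amp * env * sin(2 * pi * freq_hz * tt + phase)
  list(w = w, center = 1L)
}

gauss_artifact <- function(fs, dur_s = 0.2, amp = 400) {
  tt <- seq(-dur_s / 2, dur_s / 2, by = 1 / fs)
  # polarity opposite to the positive DOWN-state deflection
  w <- -amp * exp(-tt^2 / (2 * (dur_s / 6)^2))
  list(w = w, center = which.min(abs(tt)))
}

add_at <- function(signal, fs, t_ref, tpl) {
  i0 <- round(t_ref * fs) + 1L - (tpl$center - 1L)
  idx <- i0:(i0 + length(tpl$w) - 1L)
  keep <- idx >= 1L & idx <= length(signal)
  signal[idx[keep]] <- signal[idx[keep]] + tpl$w[keep]
  signal
}

# band-limited Gaussian background component, per-state amplitude
state_band_noise <- function(n, fs, states, amps, low, high, seed) {
  x <- with_seed(seed, stats::rnorm(n))
  x <- bandpass(x, fs, low, high, order = 2)
  x <- x / stats::sd(x)
  a <- numeric(n)
  for (i in seq_len(nrow(states))) {
    ai <- amps[[states$state[i]]]
    if (is.null(ai)) ai <- 0
    s0 <- max(1L, floor(states$start_s[i] * fs) + 1L)
    s1 <- min(n, ceiling(states$end_s[i] * fs))
    if (s1 >= s0) a[s0:s1] <- ai
  }
  # smooth amplitude switches over ~1 s to avoid step artifacts
  a <- gaussian_smooth(a, 0.5 * fs)
  x * a
}

#' Render a planned session into a full bundle
#'
#' Synthesizes the three channels (HC, MPFC, ACCEL), the spike trains with
#' event-locked modulation, and packages the plan's surviving events as
#' ground truth.
#'
#' @param plan A `session_plan` (possibly after [attach_stim_effect()]).
#' @return A [session_bundle()] with `ground_truth`.
#' @export
render_session <- function(plan) {
  p <- plan$params
  fs <- p$fs_hz
  n <- round(p$duration_s * fs)
  ev <- plan$events
  live <- ev[ev$cancelled == 0L, , drop = FALSE]

  hc <- with_seed(derive_seed(plan$seed, 2), pink_noise(n, p$pink_sd_uv))
  mp <- with_seed(derive_seed(plan$seed, 3), pink_noise(n, p$pink_sd_uv))
  hc <- hc + state_band_noise(n, fs, plan$states,
                              list(NREM = p$hc_delta_amp_uv, REM = 15,
                                   WAKE = 30),
                              0.5, 4, derive_seed(plan$seed, 4))
  hc <- hc + state_band_noise(n, fs, plan$states,
                              list(NREM = 20, REM = p$theta_amp_uv,
                                   WAKE = 60),
                              5, 8, derive_seed(plan$seed, 5))
  mp <- mp + state_band_noise(n, fs, plan$states,
                              list(NREM = p$so_amp_uv, REM = 25, WAKE = 40),
                              0.5, 4, derive_seed(plan$seed, 6))

  for (i in seq_len(nrow(live))) {
    e <- live[i, ]
    if (e$kind == "IED") {
      tpl <- ied_template(fs, p$ied_sharp_ms, p$ied_slow_ms, e$amplitude_uv)
      if (e$region == "HC") hc <- add_at(hc, fs, e$t_peak_s, tpl)
      else mp <- add_at(mp, fs, e$t_peak_s, tpl)
    } else if (e$kind == "DOWN") {
      tpl <- down_template(fs, p$down_dur_s, e$amplitude_uv)
      mp <- add_at(mp, fs, e$t_peak_s, tpl)
    } else if (e$kind == "SPINDLE") {
      tpl <- spindle_template(fs, e$t_end_s - e$t_start_s, e$freq_hz,
                              e$amplitude_uv)
      mp <- add_at(mp, fs, e$t_start_s, tpl)
    }
  }
  # sharpness substrate (mPFC; not part of the event ground truth)
  nrem <- plan$states[plan$states$state == "NREM", , drop = FALSE]
  if (p$sharpness_gain > 1) {
    mp <- mp + state_band_noise(
      n, fs, plan$states,
      list(NREM = p$rough_uv_per_gain * (p$sharpness_gain - 1)),
      50, 150, derive_seed(plan$seed, 10))
  }
  micro <- with_seed(derive_seed(plan$seed, 7), {
    mt <- draw_poisson_times(p$micro_rate_min, nrem, 0.05, edge_s = 0.2)
    list(t = mt, a = stats::runif(length(mt), 0.5, 1.5))
  })
  if (length(micro$t)) {
    wm <- p$micro_width_ms / 1000
    ttm <- seq(-4 * wm, 4 * wm, by = 1 / fs)
    base_w <- exp(-ttm^2 / (2 * wm^2)) - 0.5 * exp(-ttm^2 / (2 * (2 * wm)^2))
    ctr <- which.min(abs(ttm))
    for (j in seq_along(micro$t)) {
      tpl <- list(w = p$micro_amp_uv * p$sharpness_gain * micro$a[j] * base_w,
                  center = ctr)
      mp <- add_at(mp, fs, micro$t[j], tpl)
    }
  }
  # stimulation artifacts
  if (length(plan$stim_times_s)) {
    art <- gauss_artifact(fs)
    for (t in plan$stim_times_s) mp <- add_at(mp, fs, t, art)
  }
  # accelerometer
  acc <- with_seed(derive_seed(plan$seed, 8), stats::rnorm(n))
  sdv <- rep(p$accel_sleep_sd, n)
  wk <- plan$states[plan$states$state == "WAKE", , drop = FALSE]
  if (nrow(wk)) sdv[interval_mask(wk, n, fs)] <- p$accel_wake_sd
  acc <- acc * sdv

  units <- render_spikes(plan, live)

  channels <- list(
    channel_info("hc1", "HC", "LFP", uv_per_bit = 0.2),
    channel_info("mpfc1", "MPFC", "LFP", uv_per_bit = 0.2),
    channel_info("accel", "OTHER", "ACCEL", uv_per_bit = 0.2))
  cond <- if (plan$day_index == 0) "BASELINE" else "KINDLED_ONLY"
  meta <- session_meta(
    sprintf("synth_d%02d_s%d", plan$day_index, plan$seed),
    plan$day_index, cond, fs, n, channels, seed = plan$seed)

  gt_events <- plan$events
  series <- list()
  stim_ev <- NULL
  if (length(plan$stim_times_s)) {
    stim_ev <- data.frame(
      kind = "STIM", channel = "mpfc1", start_s = plan$stim_times_s - 0.1,
      peak_s = plan$stim_times_s, end_s = plan$stim_times_s + 0.1,
      amplitude_uv = 400, stringsAsFactors = FALSE)
    series[["STIM:mpfc1"]] <- event_series(stim_ev, "MPFC", "STIM",
                                           params = list(source = "simulator"))
  }
  gt <- list(
    events = gt_events,
    unit_gains = attr(units, "gains"),
    stim_times_s = plan$stim_times_s,
    seed = plan$seed,
    day_index = plan$day_index,
    snr_peak_over_sd = stats::median(
      gt_events$amplitude_uv[gt_events$origin == "hc_ied"]) / p$pink_sd_uv,
    params = unclass(plan$params))
  lfp <- cbind(hc, mp, acc)
  session_bundle(meta, lfp, plan$states, units, series, ground_truth = gt)
}

# piecewise inhomogeneous-Poisson spike synthesis: baseline train + extra
# event-locked spikes + DOWN-state thinning
render_spikes <- function(plan, live) {
  p <- plan$params
  dur <- p$duration_s
  n_units <- p$n_pyr + p$n_int
  hc_ied_t <- live$t_peak_s[live$origin == "hc_ied"]
  ind_ied_t <- live$t_peak_s[live$origin == "ind_ied"]
  downs <- live[live$kind == "DOWN", , drop = FALSE]
  path_downs <- downs[downs$origin == "coupled_down", , drop = FALSE]
  with_seed(derive_seed(plan$seed, 9), {
    resp <- stats::rlnorm(n_units, 0, 0.4)   # shared per-unit responsiveness
    units <- vector("list", n_units)
    gains <- data.frame(unit_id = character(n_units),
                        cell_class = character(n_units),
                        baseline_hz = numeric(n_units),
                        ied_gain = numeric(n_units),
                        ind_gain = numeric(n_units),
                        stringsAsFactors = FALSE)
    for (u in seq_len(n_units)) {
      is_pyr <- u <= p$n_pyr
      r0 <- (if (is_pyr) p$pyr_rate_hz else p$int_rate_hz) *
        stats::runif(1, 0.7, 1.3)
      g_ied <- 1 + (p$ied_gain - 1) * resp[u]
      g_ind <- 1 + (p$ied_gain - 1) * 0.75 * resp[u]
      ts <- sort(stats::runif(stats::rpois(1, r0 * dur), 0, dur))
      # DOWN suppression: thin baseline spikes inside DOWN states
      if (nrow(downs)) {
        inside <- in_intervals(ts, data.frame(start_s = downs$t_start_s,
                                              end_s = downs$t_end_s))
        drop <- inside & stats::runif(length(ts)) > p$down_suppression
        ts <- ts[!drop]
      }
      # transient gain after hippocampal and independent cortical IEDs
      extra <- numeric(0)
      for (tt in hc_ied_t) {
        k <- stats::rpois(1, (g_ied - 1) * r0 * p$ied_gain_dur_s)
        if (k) extra <- c(extra, tt + 0.005 +
                            stats::runif(k, 0, p$ied_gain_dur_s))
      }
      for (tt in ind_ied_t) {
        k <- stats::rpois(1, (g_ind - 1) * r0 * p$ied_gain_dur_s)
        if (k) extra <- c(extra, tt + 0.005 +
                            stats::runif(k, 0, p$ied_gain_dur_s))
      }
      # rebound UP-state burst after pathological DOWN states
      if (nrow(path_downs)) {
        for (tt in path_downs$t_end_s) {
          k <- stats::rpois(1, (p$up_gain - 1) * r0 * p$up_gain_dur_s)
          if (k) extra <- c(extra, tt + stats::runif(k, 0, p$up_gain_dur_s))
        }
      }
      ts <- sort(unique(c(ts, extra[extra < dur & extra > 0])))
      uid <- sprintf("u%03d", u)
      units[[u]] <- spike_unit(uid, "MPFC",
                               if (is_pyr) "PYR" else "INT", ts)
      gains$unit_id[u] <- uid
      gains$cell_class[u] <- if (is_pyr) "PYR" else "INT"
      gains$baseline_hz[u] <- r0
      gains$ied_gain[u] <- g_ied
      gains$ind_gain[u] <- g_ind
    }
    attr(units, "gains") <- gains
    units
  })
}

#' Generate one synthetic session
#'
#' Convenience wrapper: [plan_session()] followed by [render_session()].
#'
#' @inheritParams plan_session
#' @return A [session_bundle()] with ground truth.
#' @examples
#' b <- generate_session(gen_params(duration_s = 300), seed = 7)
#' @export
generate_session <- function(params, day_index = 0, seed = 1) {
  render_session(plan_session(params, day_index, seed))
}

# ---- kindling schedule and cohorts ----------------------------------------

#' Build a kindling schedule
#'
#' Per-day generator parameters encoding epilepsy progression: hippocampal
#' IED rate rises steeply over days 1-10; hippocampal-to-cortical coupling
#' probability falls from 0.7 to 0.2 over days 10-20 while its temporal
#' jitter doubles (degraded precision); independent cortical IED rate and
#' LFP sharpness gain are *not* fixed here - they are derived, during cohort
#' simulation, from the cumulative load of surviving coupled events, so that
#' interventions that cancel coupling also slow downstream progression.
#' `KINDLED_ONLY`, `SHAM` and `CLOSED_LOOP` schedules share identical event
#' statistics and differ only in the stimulation scenario flag.
#'
#' @param condition One of `"BASELINE"`, `"KINDLED_ONLY"`, `"SHAM"`,
#'   `"CLOSED_LOOP"`.
#' @param n_days Number of kindling days (>= 1).
#' @param seed Master seed.
#' @param duration_s Session duration per day (s).
#' @return A `kindling_schedule` list with one parameter set per day.
#' @export
make_kindling_schedule <- function(condition = "KINDLED_ONLY", n_days = 20,
                                   seed = 1, duration_s = 1200) {
  stopifnot(condition %in% CONDITIONS, n_days >= 1)
  days <- lapply(seq_len(n_days), function(d) {
    if (condition == "BASELINE") {
      list(day_index = d,
           overrides = list(duration_s = duration_s, hc_ied_rate_min = 0.5,
                            p_couple = 0.7))
    } else {
      rate <- 1 + 9 / (1 + exp(-(d - 5) / 2))
      pc <- 0.7 - 0.5 * min(max((d - 10) / 10, 0), 1)
      lag_sd <- 0.03 * (1 + min(max((d - 10) / 10, 0), 1))
      list(day_index = d,
           overrides = list(duration_s = duration_s, hc_ied_rate_min = rate,
                            p_couple = pc, couple_lag_sd_s = lag_sd))
    }
  })
  structure(list(condition = condition, n_days = as.integer(n_days),
                 seed = as.integer(seed), days = days),
            class = "kindling_schedule")
}

# progression rule: cumulative surviving coupled-event load (events per NREM
# minute, summed over previous days) drives the emergence of independent
# cortical IEDs and the rise of LFP sharpness
progression_from_load <- function(cum_load) {
  list(ind_mpfc_rate_min = 3 * stats::plogis((cum_load - 45) / 8),
       sharpness_gain = 1 + min(2 * max(cum_load - 10, 0) / 70, 3))
}

#' Generate a multi-day cohort
#'
#' One session per schedule day, with per-day seeds derived from the master
#' seed.  Independent cortical IED rate and sharpness gain for day `d` are
#' computed from the cumulative surviving coupled-event load of days < d
#' (see [make_kindling_schedule()]).  For stimulated conditions use
#' [run_scenario()] instead, which co-simulates detection and stimulation.
#'
#' @param schedule A `kindling_schedule`.
#' @param seed Master seed (defaults to the schedule's).
#' @return List of [session_bundle()]s.
#' @export
generate_cohort <- function(schedule, seed = schedule$seed) {
  out <- vector("list", schedule$n_days)
  cum_load <- 0
  for (i in seq_len(schedule$n_days)) {
    day <- schedule$days[[i]]
    prog <- progression_from_load(cum_load)
    ov <- c(day$overrides, prog)
    params <- do.call(gen_params, ov)
    pl <- plan_session(params, day$day_index, derive_seed(seed, day$day_index))
    b <- render_session(pl)
    nrem_min <- interval_duration(slice_by_state(b, "NREM")) / 60
    n_coupled <- sum(pl$events$origin == "coupled_down" &
                       pl$events$cancelled == 0L)
    cum_load <- cum_load + n_coupled / nrem_min
    out[[i]] <- b
  }
  out
}
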