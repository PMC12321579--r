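# Causal emulation of the embedded real-time IED detector and stimulation
# scheduler, the sham-stimulation arm, and cohort-level intervention
# evaluation.
#
# The detector is strictly causal: a biquad-cascade bandpass, rectification
# and a causal moving average give the instantaneous band power; the
# threshold is frozen from the first seconds of baseline.  Stimulation is
# gated by a refractory period and vetoed while the accelerometer indicates
# movement.

#' Closed-loop controller configuration
#'
#' @param band_hz Detection band (default 50-85 Hz).
#' @param ma_window_s Moving-average window for instantaneous power
#'   (default 0.02 s).
#' @param k_sd Threshold multiplier over baseline SD (default 6, calibrated
#'   on the generator's baseline so that false triggers stay below 1/min;
#'   per-animal customization is expected in practice).
#' @param baseline_s Baseline duration used to freeze the threshold
#'   (default 10 s).
#' @param refractory_s Stimulation refractory period (default 3 s).
#' @param motion_veto_thr Accelerometer mean-square power above which
#'   detections are vetoed (default 1e4).
#' @param stim_duration_s Gaussian stimulation waveform duration
#'   (default 0.2 s).
#' @param artifact_blank_s Blanking half-width applied before offline
#'   analysis of stimulated sessions (default 0.1 s, i.e. the 200 ms
#'   artifact).
#' @return A `cl_config` list.
#' @export
cl_config <- function(band_hz = c(50, 85), ma_window_s = 0.02, k_sd = 6,
                      baseline_s = 10, refractory_s = 3,
                      motion_veto_thr = 1e4, stim_duration_s = 0.2,
                      artifact_blank_s = 0.1) {
  stopifnot(refractory_s > stim_duration_s, baseline_s > 0)
  structure(list(band_hz = band_hz, ma_window_s = ma_window_s, k_sd = k_sd,
                 baseline_s = baseline_s, refractory_s = refractory_s,
                 motion_veto_thr = motion_veto_thr,
                 stim_duration_s = stim_duration_s,
                 artifact_blank_s = artifact_blank_s),
            class = "cl_config")
}

#' Causal streaming IED detector
#'
#' Emulates the embedded detector sample by sample (vectorized but strictly
#' causal): causal Butterworth bandpass (biquad cascade), rectification,
#' causal moving average, threshold frozen at
#' `mean + k_sd * SD` of the first `baseline_s` seconds of instantaneous
#' power.  Returns threshold-crossing times (upward crossings), with
#' crossings vetoed while accelerometer power exceeds the motion threshold.
#'
#' @param hc_signal Hippocampal LFP (microvolts).
#' @param fs Sampling rate (Hz).
#' @param config A [cl_config()].
#' @param accel Optional accelerometer signal (same length).
#' @return List with `detections_s` (crossing times), `power` (instantaneous
#'   band power), `threshold`, `group_delay_s` (approximate filter +
#'   smoothing delay).
#' @export
stream_detector <- function(hc_signal, fs, config = cl_config(),
                            accel = NULL) {
  coef <- butter_design(2, config$band_hz / (fs / 2), "pass")
  f <- filter_causal(hc_signal, coef)
  nma <- max(1L, round(config$ma_window_s * fs))
  pw <- causal_ma(abs(f), nma)
  nb <- round(config$baseline_s * fs)
  if (nb >= length(pw)) stop("signal shorter than the baseline window")
  thr <- mean(pw[1:nb]) + config$k_sd * stats::sd(pw[1:nb])
  above <- pw > thr
  cross <- which(above[-1] & !above[-length(above)]) + 1L
  if (!is.null(accel)) {
    apw <- causal_ma(accel^2, max(1L, round(0.5 * fs)))
    cross <- cross[apw[cross] <= config$motion_veto_thr]
  }
  list(detections_s = (cross - 1) / fs, power = pw, threshold = thr,
       group_delay_s = (nma / 2) / fs + 2 / mean(config$band_hz))
}

causal_ma <- function(x, n) {
  cs <- cumsum(x)
  out <- cs
  out[(n + 1):length(x)] <- (cs[(n + 1):length(x)] -
                               cs[1:(length(x) - n)]) / n
  out[1:n] <- cs[1:n] / seq_len(n)
  out
}

# refractory gating of a detection stream
apply_refractory <- function(det_times, refractory_s) {
  out <- numeric(0)
  last <- -Inf
  for (t in det_times) {
    if (t - last >= refractory_s) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

match_detections <- function(stim_times, truth_times, tol_s = 0.1) {
  if (!length(truth_times)) {
    return(list(sensitivity = NA_real_, latencies_s = numeric(0),
                n_matched = 0L, n_false = length(stim_times)))
  }
  matched <- logical(length(truth_times))
  lat <- rep(NA_real_, length(truth_times))
  false_ct <- 0L
  for (t in stim_times) {
    d <- t - truth_times
    cand <- which(!matched & d >= -tol_s & d <= tol_s + 0.05)
    if (length(cand)) {
      i <- cand[which.min(abs(d[cand]))]
      matched[i] <- TRUE
      lat[i] <- d[i]
    } else {
      false_ct <- false_ct + 1L
    }
  }
  list(sensitivity = mean(matched), latencies_s = lat[matched],
       n_matched = sum(matched), n_false = false_ct)
}

#' Run one closed-loop stimulation session
#'
#' Co-simulates generation and detection: the session plan is drawn, the
#' hippocampal channel (unaffected by cortical stimulation) is rendered and
#' streamed through the causal detector; detections gated by the refractory
#' period become stimulation times, which cancel subsequent planned
#' cortical responses via [attach_stim_effect()] before the cortical
#' channel is rendered.
#'
#' @param params A [gen_params()] list.
#' @param day_index Day index.
#' @param config A [cl_config()].
#' @param p_eff Stimulation efficacy (probability a timely stimulation
#'   cancels the coupled cortical response).
#' @param seed Session seed.
#' @return List with `bundle` (stimulated session) and `result`
#'   (a `cl_run_result`: stimulation times, latencies, sensitivity,
#'   false positives per minute).
#' @export
run_closed_loop <- function(params, day_index, config = cl_config(),
                            p_eff = 1, seed = 1) {
  plan <- plan_session(params, day_index, seed)
  hc_only <- render_hc_channel(plan)
  det <- stream_detector(hc_only$hc, params$fs_hz, config,
                         accel = hc_only$accel)
  stim <- apply_refractory(det$detections_s, config$refractory_s)
  plan <- attach_stim_effect(plan, stim, p_eff)
  bundle <- render_session(plan)
  truth <- plan$events$t_peak_s[plan$events$origin == "hc_ied"]
  mt <- match_detections(stim, truth, tol_s = 0.1)
  dur_min <- params$duration_s / 60
  res <- structure(list(
    stim_times_s = stim,
    latencies_s = mt$latencies_s,
    sensitivity = mt$sensitivity,
    false_positives_per_min = mt$n_false / dur_min,
    refractory_suppressed_count = length(det$detections_s) - length(stim),
    threshold = det$threshold,
    group_delay_s = det$group_delay_s,
    p_eff = p_eff), class = "cl_run_result")
  list(bundle = bundle, result = res)
}

# render HC + accelerometer only (for causal detection before the cortical
# channel exists); must match render_session's HC stream exactly
render_hc_channel <- function(plan) {
  p <- plan$params
  fs <- p$fs_hz
  n <- round(p$duration_s * fs)
  hc <- with_seed(derive_seed(plan$seed, 2), pink_noise(n, p$pink_sd_uv))
  hc <- hc + state_band_noise(n, fs, plan$states,
                              list(NREM = p$hc_delta_amp_uv, REM = 15,
                                   WAKE = 30),
                              0.5, 4, derive_seed(plan$seed, 4))
  hc <- hc + state_band_noise(n, fs, plan$states,
                              list(NREM = 20, REM = p$theta_amp_uv,
                                   WAKE = 60),
                              5, 8, derive_seed(plan$seed, 5))
  live <- plan$events[plan$events$cancelled == 0L, , drop = FALSE]
  hcev <- live[live$kind == "IED" & live$region == "HC", , drop = FALSE]
  for (i in seq_len(nrow(hcev))) {
    tpl <- ied_template(fs, p$ied_sharp_ms, p$ied_slow_ms,
                        hcev$amplitude_uv[i])
    hc <- add_at(hc, fs, hcev$t_peak_s[i], tpl)
  }
  acc <- with_seed(derive_seed(plan$seed, 8), stats::rnorm(n))
  sdv <- rep(p$accel_sleep_sd, n)
  wk <- plan$states[plan$states$state == "WAKE", , drop = FALSE]
  if (nrow(wk)) sdv[interval_mask(wk, n, fs)] <- p$accel_wake_sd
  list(hc = hc, accel = acc * sdv)
}

#' Run one sham-stimulation session
#'
#' Stimulation times are drawn uniformly over the session (respecting the
#' refractory period), decoupled from IED timing; stimulations that happen
#' to land within the effective post-IED window still cancel coupled
#' responses (chance efficacy).
#'
#' @param params A [gen_params()] list.
#' @param day_index Day index.
#' @param config A [cl_config()].
#' @param stim_count_target Number of stimulations (matched to a
#'   closed-loop run).
#' @param p_eff Efficacy given a chance hit.
#' @param seed Session seed.
#' @return As [run_closed_loop()].
#' @export
run_sham <- function(params, day_index, config = cl_config(),
                     stim_count_target, p_eff = 1, seed = 1) {
  dur <- params$duration_s
  if (stim_count_target * config$refractory_s >= dur) {
    stop("target stimulation count unachievable under the refractory period")
  }
  stim <- with_seed(derive_seed(seed, 777), {
    out <- numeric(0)
    guard <- 0
    while (length(out) < stim_count_target && guard < 10000) {
      cand <- stats::runif(1, 1, dur - 1)
      if (!length(out) || all(abs(cand - out) >= config$refractory_s)) {
        out <- c(out, cand)
      }
      guard <- guard + 1
    }
    sort(out)
  })
  if (length(stim) < stim_count_target) {
    stop("could not place ", stim_count_target, " stimulations")
  }
  plan <- plan_session(params, day_index, seed)
  plan <- attach_stim_effect(plan, stim, p_eff)
  bundle <- render_session(plan)
  truth <- plan$events$t_peak_s[plan$events$origin == "hc_ied"]
  mt <- match_detections(stim, truth, tol_s = 0.1)
  res <- structure(list(
    stim_times_s = stim, latencies_s = mt$latencies_s,
    sensitivity = mt$sensitivity,
    false_positives_per_min = mt$n_false / (dur / 60),
    refractory_suppressed_count = 0L, threshold = NA_real_,
    group_delay_s = NA_real_, p_eff = p_eff), class = "cl_run_result")
  list(bundle = bundle, result = res)
}

#' Simulate a full cohort under a stimulation scenario
#'
#' Runs a kindling schedule day by day under one of the three arms,
#' propagating the cumulative surviving-coupling load that drives the
#' emergence of independent cortical IEDs and sharpness progression (see
#' [make_kindling_schedule()]).  In the `"cl"` arm effective stimulation
#' reduces the load; in `"sham"` only chance hits do; `"none"` reproduces
#' [generate_cohort()].
#'
#' @param schedule A `kindling_schedule`.
#' @param mode `"none"`, `"cl"` or `"sham"`.
#' @param config A [cl_config()].
#' @param p_eff Stimulation efficacy.
#' @param seed Master seed.
#' @param sham_counts Per-day stimulation counts for sham (defaults to the
#'   expected closed-loop counts, i.e. the detected IED numbers).
#' @return List of per-day lists with `bundle` and (for stimulated arms)
#'   `result`.
#' @export
run_scenario <- function(schedule, mode = c("none", "cl", "sham"),
                         config = cl_config(), p_eff = 1,
                         seed = schedule$seed, sham_counts = NULL) {
  mode <- match.arg(mode)
  out <- vector("list", schedule$n_days)
  cum_load <- 0
  for (i in seq_len(schedule$n_days)) {
    day <- schedule$days[[i]]
    prog <- progression_from_load(cum_load)
    params <- do.call(gen_params, c(day$overrides, prog))
    dseed <- derive_seed(seed, day$day_index)
    rec <- if (mode == "none") {
      list(bundle = render_session(plan_session(params, day$day_index,
                                                dseed)),
           result = NULL)
    } else if (mode == "cl") {
      run_closed_loop(params, day$day_index, config, p_eff, dseed)
    } else {
      n_st <- if (!is.null(sham_counts)) sham_counts[i] else {
        max(1L, round(params$hc_ied_rate_min *
                        interval_duration(make_state_schedule(params)[
                          make_state_schedule(params)$state == "NREM", ]) /
                        60))
      }
      run_sham(params, day$day_index, config, n_st, p_eff, dseed)
    }
    ev <- rec$bundle$ground_truth$events
    nrem_min <- interval_duration(slice_by_state(rec$bundle, "NREM")) / 60
    n_surv <- sum(ev$origin == "coupled_down" & ev$cancelled == 0L)
    cum_load <- cum_load + n_surv / nrem_min
    rec$load_after <- cum_load
    out[[i]] <- rec
  }
  out
}

#' Cohort-level intervention contrasts
#'
#' For each cohort computes, per day: post-IED (500 ms) spindle-band
#' z-power, hippocampal-IED-to-spindle coupling modulation M, independent
#' cortical IED occurrence (per NREM minute) and the sharpness statistic;
#' then contrasts the closed-loop cohort against each comparison cohort
#' with one-sided Wilcoxon rank tests in the direction the intervention is
#' expected to act (CL lower).
#'
#' @param cl_sessions,sham_sessions,kindled_sessions Lists of
#'   [session_bundle()]s (sham may be `NULL`).
#' @param late_days Day range defining "late kindling" for the
#'   independent-IED contrast (default >= 15).
#' @param seed Seed for the analysis (segment draws).
#' @param precomputed Optional named list of per-day metric tables (from
#'   [session_coupling_metrics()]) keyed `cl`, `kindled`, `sham`; when
#'   supplied the corresponding session lists may be `NULL`.
#' @return List with `per_day` metric table and `tests` (data.frame of
#'   contrasts: metric, cohorts, W, p).
#' @export
evaluate_intervention <- function(cl_sessions, sham_sessions = NULL,
                                  kindled_sessions, late_days = 15,
                                  seed = 1, precomputed = NULL) {
  cohorts <- list(cl = cl_sessions, kindled = kindled_sessions)
  if (!is.null(sham_sessions)) cohorts$sham <- sham_sessions
  per <- lapply(names(cohorts), function(nm) {
    if (!is.null(precomputed[[nm]])) {
      df <- precomputed[[nm]]
      df$cohort <- nm
      return(df)
    }
    rows <- lapply(cohorts[[nm]], function(b) {
      m <- session_coupling_metrics(b, seed = seed)
      m$cohort <- nm
      m
    })
    do.call(rbind, rows)
  })
  per <- do.call(rbind, per)
  tests <- list()
  add_test <- function(metric, a, b, df_a, df_b, alternative = "less") {
    va <- df_a[[metric]]
    vb <- df_b[[metric]]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 3 || length(vb) < 3) return()
    wt <- suppressWarnings(stats::wilcox.test(va, vb,
                                              alternative = alternative))
    tests[[length(tests) + 1]] <<- data.frame(
      metric = metric, cohort_a = a, cohort_b = b, W = unname(wt$statistic),
      p = wt$p.value, stringsAsFactors = FALSE)
  }
  cl_df <- per[per$cohort == "cl", ]
  for (other in setdiff(unique(per$cohort), "cl")) {
    o_df <- per[per$cohort == other, ]
    add_test("post_ied_spindle_z", "cl", other, cl_df, o_df)
    add_test("m_spindle", "cl", other, cl_df, o_df)
    late_cl <- cl_df[cl_df$day >= late_days, ]
    late_o <- o_df[o_df$day >= late_days, ]
    add_test("ind_ied_rate", "cl", other, late_cl, late_o)
  }
  list(per_day = per, tests = do.call(rbind, tests))
}

#' Per-session coupling metrics
#'
#' Detection-based summary used by cohort analyses: hippocampal and
#' cortical IEDs are detected, spindles detected, and the session yields
#' the IED-to-spindle coupling modulation M (spindle onsets, lag window
#' 0-0.6 s), IED-to-DOWN M, post-IED 500 ms spindle-band z-power, the
#' independent cortical IED rate and fraction, and occurrence rates.
#'
#' @param bundle Session bundle (artifact-blanked automatically when STIM
#'   events are present).
#' @param seed Seed for windows/draws.
#' @return One-row data.frame of metrics.
#' @export
session_coupling_metrics <- function(bundle, seed = 1) {
  if (!is.null(bundle$event_series[["STIM:mpfc1"]])) {
    bundle <- blank_artifacts(bundle)
  }
  day <- bundle$meta$day_index
  nrem <- slice_by_state(bundle, "NREM")
  nrem_min <- interval_duration(nrem) / 60
  ied_hc <- detect_ied(bundle, "HC")
  ied_mp <- detect_ied(bundle, "MPFC")
  sp <- detect_spindles(bundle, "MPFC", ied_series = ied_mp)
  mua <- sort(unlist(lapply(bundle$units, `[[`, "spike_times_s")))
  downs <- detect_down_states(bundle, "MPFC", mua_times = mua,
                              ied_hc = ied_hc)
  hc_t <- ied_hc$events$peak_s
  m_sp <- m_dn <- NA_real_
  if (length(hc_t) >= 20 && nrow(sp$events) >= 5) {
    # coarse bins + wide hollow kernel: per-session event counts are small,
    # so the peak statistic must integrate the coupled mass (spindle onsets
    # lag the IED by ~0.2-0.5 s) rather than rely on a single narrow bin
    cc <- ccg_convolution(hc_t, sp$events$start_s, bin_s = 0.2,
                          window_s = 2, kernel_sd_s = 1)
    m_sp <- coupling_modulation(cc, c(0, 0.6))$M
  }
  if (length(hc_t) >= 20 && nrow(downs) >= 5) {
    cc <- ccg_convolution(hc_t, downs$t_peak, bin_s = 0.05, window_s = 1,
                          kernel_sd_s = 0.3)
    m_dn <- coupling_modulation(cc, c(0, 0.5))$M
  }
  psz <- NA_real_
  if (length(hc_t) >= 5) {
    # 500 ms window placed after the stimulation-artifact blanking epoch
    # (and after the immediate IED waveform) in all arms
    wins <- data.frame(start_s = hc_t + 0.2, end_s = hc_t + 0.7)
    dur <- session_duration(bundle)
    wins <- wins[wins$end_s < dur, , drop = FALSE]
    psz <- mean(spindle_band_power(bundle, "MPFC", wins))
  }
  ind <- classify_independent(ied_mp, ied_hc)
  ind_rate <- if (nrem_min > 0 && nrow(ied_mp$events)) {
    sum(ind$independent) / nrem_min
  } else {
    0
  }
  data.frame(
    session_id = bundle$meta$session_id, day = day,
    hc_ied_rate = length(hc_t) / nrem_min,
    mpfc_ied_rate = nrow(ied_mp$events) / nrem_min,
    ind_ied_rate = ind_rate,
    ind_fraction = if (nrow(ied_mp$events)) ind$fraction else NA_real_,
    spindle_rate = nrow(sp$events) / nrem_min,
    m_spindle = m_sp, m_down = m_dn,
    post_ied_spindle_z = psz,
    n_downs = nrow(downs),
    stringsAsFactors = FALSE)
}
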