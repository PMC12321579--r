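# Detection-free LFP "epileptogenicity": a gradient-sharpness statistic on
# randomly sampled NREM segments, z-scored against baseline sessions and
# tracked longitudinally (regression slope + Mann-Kendall trend).

#' Sample random non-overlapping NREM segments
#'
#' @param bundle Session bundle with scored states.
#' @param n Number of segments (default 10).
#' @param seg_s Segment duration (default 5 s).
#' @param seed Seed for the draw.
#' @param channel Channel label or region to extract (default `"MPFC"`).
#' @return List of numeric vectors (microvolt samples of the cortical
#'   channel), with attributes `start_s`.
#' @export
sample_nrem_segments <- function(bundle, n = 10, seg_s = 5, seed = 1,
                                 channel = "MPFC") {
  nrem <- slice_by_state(bundle, "NREM")
  if (interval_duration(nrem) < n * seg_s) {
    stop("insufficient NREM: need ", n * seg_s, " s, have ",
         interval_duration(nrem), " s")
  }
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, channel)
  # candidate non-overlapping slots, seeded draw
  slots <- numeric(0)
  for (i in seq_len(nrow(nrem))) {
    s0 <- seq(nrem$start_s[i], nrem$end_s[i] - seg_s, by = seg_s)
    slots <- c(slots, s0)
  }
  if (length(slots) < n) stop("insufficient NREM slots for ", n, " segments")
  pick <- with_seed(seed, sort(sample(slots, n)))
  segs <- lapply(pick, function(s0) {
    i0 <- floor(s0 * fs) + 1L
    x[i0:(i0 + round(seg_s * fs) - 1L)]
  })
  attr(segs, "start_s") <- pick
  segs
}

#' Gradient-sharpness statistic of one LFP segment
#'
#' The segment is Savitzky-Golay filtered (equalizing high-frequency
#' content), its discrete gradient taken, artifact samples
#' (`|g| > 20 * median(|g|)`) removed, and the statistic returned is the
#' median-based threshold itself: `median(|g|) + k_mad * 1.4826 * MAD(|g|)`
#' (microvolts per sample).  Sharp, unpredictable waveforms raise the tail
#' of the gradient distribution and hence the threshold.
#'
#' @param segment Numeric LFP segment (microvolts).
#' @param savgol_window Filter window in samples (odd, default 11).
#' @param savgol_order Polynomial order (default 3).
#' @param k_mad Tail multiplier (default 5).
#' @param variant `"threshold"` (the statistic above) or `"survivors_rms"`
#'   (RMS of surviving gradient values; alternative reading).
#' @return Sharpness value (microvolts/sample).
#' @export
segment_sharpness <- function(segment, savgol_window = 11, savgol_order = 3,
                              k_mad = 5,
                              variant = c("threshold", "survivors_rms")) {
  variant <- match.arg(variant)
  if (length(segment) < savgol_window) stop("segment shorter than window")
  sm <- savgol_smooth(segment, savgol_window, savgol_order)
  g <- abs(diff(sm))
  med <- stats::median(g)
  a_bound <- 20 * med
  g <- g[g <= a_bound]
  if (!length(g)) stop("all gradient samples removed as artifact")
  if (variant == "survivors_rms") return(sqrt(mean(g^2)))
  stats::median(g) + k_mad * 1.4826 * stats::mad(g, constant = 1)
}

#' Session-level epileptogenicity and cohort trend
#'
#' Computes per-session mean sharpness over sampled NREM segments, z-scores
#' sessions against the pooled segment values of the baseline sessions, and
#' summarizes the longitudinal trend by the OLS slope of session z on day
#' index and the Mann-Kendall test.
#'
#' @param cohort List of [session_bundle()]s (one per day).
#' @param baseline_days Day indices considered baseline (default: the
#'   smallest day present).
#' @param n_segments,seg_s Segment sampling parameters (defaults 10 and 5 s).
#' @param seed Master seed (per-session seeds derived from it).
#' @param channel Channel to analyse (default the cortical one).
#' @param ... Passed to [segment_sharpness()].
#' @return List with `per_session` (data.frame: session_id, day, sharpness,
#'   session_z), `slope`, `slope_p`, `mk_tau`, `mk_p`.
#' @export
epi_trend <- function(cohort, baseline_days = NULL, n_segments = 10,
                      seg_s = 5, seed = 1, channel = "MPFC", ...) {
  days <- vapply(cohort, function(b) b$meta$day_index, 0L)
  if (is.null(baseline_days)) baseline_days <- min(days)
  seg_vals <- lapply(seq_along(cohort), function(i) {
    segs <- sample_nrem_segments(cohort[[i]], n = n_segments, seg_s = seg_s,
                                 seed = derive_seed(seed, i),
                                 channel = channel)
    vapply(segs, segment_sharpness, 0, ...)
  })
  base_pool <- unlist(seg_vals[days %in% baseline_days])
  if (length(base_pool) < 2 || stats::sd(base_pool) == 0) {
    stop("degenerate baseline segment distribution")
  }
  mu <- mean(base_pool)
  sdv <- stats::sd(base_pool)
  per <- data.frame(
    session_id = vapply(cohort, function(b) b$meta$session_id, ""),
    day = days,
    sharpness = vapply(seg_vals, mean, 0),
    stringsAsFactors = FALSE)
  per$session_z <- (per$sharpness - mu) / sdv
  fm <- stats::lm(session_z ~ day, data = per)
  sl <- summary(fm)$coefficients
  mk <- mann_kendall(per$session_z[order(per$day)])
  list(per_session = per,
       slope = unname(sl["day", "Estimate"]),
       slope_p = unname(sl["day", "Pr(>|t|)"]),
       mk_tau = mk$tau, mk_p = mk$p,
       params = list(n_segments = n_segments, seg_s = seg_s, seed = seed))
}
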