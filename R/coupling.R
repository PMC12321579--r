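# Event-coupling and spectral statistics: convolution-baseline
# cross-correlograms with Poisson confidence bounds, the coupling-modulation
# statistic M = (a - b)/b, IED independence classification, occurrence-rate
# trajectories and their cubic-fit comparison, multitaper coherence,
# spindle-band power and the Mann-Kendall trend test.

#' Cross-correlogram with convolution baseline
#'
#' Bins target-event lags relative to each reference event, estimates the
#' expected baseline by convolving the raw counts with a hollow Gaussian
#' kernel (centre bin zeroed, kernel renormalized), and attaches pointwise
#' 95% Poisson bounds.
#'
#' @param ref,tgt Sorted event-time vectors (s).
#' @param bin_s Bin width (default 0.01 s).
#' @param window_s Half-width of the lag window (default 1 s).
#' @param kernel_sd_s Hollow-Gaussian kernel SD (default 0.1 s).
#' @param min_ref Below this reference count the result is flagged
#'   `low_n = TRUE` (default 20, mirroring session-exclusion practice).
#' @return A `ccg_result` list: `lags_s`, `counts`, `baseline_b`, `ci_low`,
#'   `ci_high`, `bin_s`, `n_ref`, `n_tgt`, `low_n`.
#' @export
ccg_convolution <- function(ref, tgt, bin_s = 0.01, window_s = 1.0,
                            kernel_sd_s = 0.1, min_ref = 20) {
  if (!length(ref) || !length(tgt)) stop("empty event series")
  if (is.unsorted(ref) || is.unsorted(tgt)) stop("event times must be sorted")
  low_n <- length(ref) < min_ref
  if (low_n) warning("fewer than ", min_ref, " reference events")
  half <- round(window_s / bin_s)
  nb <- 2L * half + 1L
  lo <- findInterval(ref - window_s - bin_s / 2, tgt) + 1L
  hi <- findInterval(ref + window_s + bin_s / 2, tgt)
  all_k <- vector("list", length(ref))
  for (i in seq_along(ref)) {
    if (hi[i] < lo[i]) next
    lag <- tgt[lo[i]:hi[i]] - ref[i]
    k <- round(lag / bin_s) + half + 1L
    all_k[[i]] <- k[k >= 1L & k <= nb]
  }
  all_k <- unlist(all_k)
  counts <- if (length(all_k)) tabulate(all_k, nb) else numeric(nb)
  kr <- ceiling(3 * kernel_sd_s / bin_s)
  kern <- stats::dnorm(seq(-kr, kr) * bin_s, sd = kernel_sd_s)
  kern[kr + 1] <- 0                    # hollow centre
  kern <- kern / sum(kern)
  ext <- c(rep(counts[1], kr), counts, rep(counts[nb], kr))
  base <- as.numeric(stats::filter(ext, kern, method = "convolution",
                                   sides = 2))[(kr + 1):(kr + nb)]
  base <- pmax(base, 0)
  structure(list(
    lags_s = seq(-half, half) * bin_s, counts = counts, baseline_b = base,
    ci_low = stats::qpois(0.025, base), ci_high = stats::qpois(0.975, base),
    bin_s = bin_s, window_s = window_s, kernel_sd_s = kernel_sd_s,
    n_ref = length(ref), n_tgt = length(tgt), low_n = low_n),
    class = "ccg_result")
}

#' Coupling modulation M = (a - b)/b
#'
#' `a` is the largest CCG count inside the test window among bins exceeding
#' the upper Poisson bound; `b` the convolution baseline at that bin.  When
#' no bin in the window is significant the coupling is deemed absent and
#' `M = 0`.
#'
#' @param ccg A [ccg_convolution()] result.
#' @param test_window_s Either a half-width (scalar, window centred on zero
#'   lag; default 0.05) or a length-2 `c(lo, hi)` lag range.
#' @return List with `M`, `a`, `b`, `lag_s` (lag of the significant peak,
#'   `NA` when none), `significant`.
#' @export
coupling_modulation <- function(ccg, test_window_s = 0.05) {
  rng <- if (length(test_window_s) == 1) {
    c(-abs(test_window_s), abs(test_window_s))
  } else {
    test_window_s
  }
  sel <- which(ccg$lags_s >= rng[1] & ccg$lags_s <= rng[2])
  if (!length(sel)) stop("empty test window")
  sig <- sel[ccg$counts[sel] > ccg$ci_high[sel]]
  if (length(sig)) {
    i <- sig[which.max(ccg$counts[sig])]
    a <- ccg$counts[i]
    b <- ccg$baseline_b[i]
    if (b <= 0) stop("degenerate baseline (b = 0) at significant peak")
    list(M = (a - b) / b, a = a, b = b, lag_s = ccg$lags_s[i],
         significant = TRUE)
  } else {
    i0 <- sel[which.max(ccg$counts[sel])]
    b <- ccg$baseline_b[i0]
    if (b <= 0) stop("degenerate baseline (b = 0) in test window")
    list(M = 0, a = b, b = b, lag_s = NA_real_, significant = FALSE)
  }
}

#' Flag events independent of a reference series
#'
#' An event is independent when no reference event lies within
#' `radius_s` of it.
#'
#' @param tgt,ref Event-time vectors or [event_series()] objects (peak
#'   times are used).
#' @param radius_s Independence radius (default 0.1 s).
#' @return List with logical `independent` flags (per target event) and the
#'   independent `fraction`.
#' @export
classify_independent <- function(tgt, ref, radius_s = 0.1) {
  tt <- event_times(tgt)
  rt <- event_times(ref)
  if (!length(tt)) return(list(independent = logical(0), fraction = NaN))
  if (!length(rt)) {
    return(list(independent = rep(TRUE, length(tt)), fraction = 1))
  }
  idx <- findInterval(tt, rt)
  d_lo <- ifelse(idx >= 1, tt - rt[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(rt), rt[pmin(idx + 1, length(rt))] - tt, Inf)
  ind <- pmin(d_lo, d_hi) > radius_s
  list(independent = ind, fraction = mean(ind))
}

event_times <- function(x) {
  if (inherits(x, "event_series")) return(x$events$peak_s)
  sort(as.numeric(x))
}

#' Independent-IED ratio of every focus against the seizure-onset zone
#'
#' @param foci Named list of [event_series()] (or time vectors), one per
#'   IED focus.
#' @param soz_key Name of the seizure-onset-zone focus.
#' @param radius_s Independence radius (default 0.1 s).
#' @return data.frame with `focus`, `n_events`, `independent_ratio`
#'   (the SOZ row is 0 by definition).
#' @export
independence_matrix <- function(foci, soz_key, radius_s = 0.1) {
  if (length(foci) < 2) stop("need at least two foci")
  if (!soz_key %in% names(foci)) stop("unknown soz_key: ", soz_key)
  soz <- foci[[soz_key]]
  rows <- lapply(names(foci), function(nm) {
    tt <- event_times(foci[[nm]])
    ratio <- if (nm == soz_key) 0 else
      classify_independent(tt, soz, radius_s)$fraction
    data.frame(focus = nm, n_events = length(tt),
               independent_ratio = ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Event occurrence rate within a behavioral state
#'
#' @param series [event_series()] or time vector.
#' @param states [state_intervals()] table.
#' @param state State to count within (default `"NREM"`).
#' @return Events per minute of the state.
#' @export
occurrence_rate <- function(series, states, state = "NREM") {
  iv <- states[states$state == state, , drop = FALSE]
  mins <- interval_duration(iv) / 60
  if (mins <= 0) stop("zero time scored as ", state)
  tt <- event_times(series)
  sum(in_intervals(tt, iv)) / mins
}

#' Cubic occurrence-trajectory fits with pairwise curve comparison
#'
#' Fits a cubic polynomial to each per-day rate series and compares every
#' pair by the extra-sum-of-squares F test of a shared versus separate
#' curves (df 4, n - 8).
#'
#' @param day_rates Named list of numeric vectors (rate per day); all series
#'   must share the same day grid, at least 8 days.
#' @param days Day indices (defaults to `seq_along` of the first series).
#' @return List with `fits` (per-series coefficients and R^2) and
#'   `comparisons` (data.frame of pairwise F and p).
#' @export
fit_occurrence_trajectories <- function(day_rates, days = NULL) {
  ns <- lengths(day_rates)
  if (length(unique(ns)) != 1) stop("series must share a common day grid")
  n <- ns[1]
  if (n < 8) stop("need at least 8 days to fit and compare cubics")
  if (is.null(days)) days <- seq_len(n)
  x <- (days - mean(days)) / stats::sd(days)      # conditioning
  fit1 <- function(y, xx) {
    fm <- stats::lm(y ~ poly(xx, 3, raw = TRUE))
    list(coef = unname(stats::coef(fm)), sse = sum(stats::resid(fm)^2),
         r2 = summary(fm)$r.squared)
  }
  fits <- lapply(day_rates, fit1, xx = x)
  nm <- names(day_rates)
  comps <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      yi <- day_rates[[i]]; yj <- day_rates[[j]]
      sse_sep <- fits[[i]]$sse + fits[[j]]$sse
      pooled <- fit1(c(yi, yj), c(x, x))
      df2 <- 2 * n - 8
      Fv <- ((pooled$sse - sse_sep) / 4) / (sse_sep / df2)
      Fv <- max(Fv, 0)
      comps[[length(comps) + 1]] <- data.frame(
        series_a = nm[i], series_b = nm[j], F = Fv,
        p = stats::pf(Fv, 4, df2, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, comparisons = do.call(rbind, comps))
}

#' Composite responsiveness score
#'
#' Z-scores each coupling measure across sessions and averages them; a
#' session-level summary of how strongly the cortex responds to
#' hippocampal IEDs.
#'
#' @param metrics data.frame with one row per session and the measure
#'   columns (default `M_spindle`, `M_down`, `mua_modulation`).
#' @param columns Measure columns to combine.
#' @return Numeric composite score per session.
#' @export
composite_responsiveness <- function(metrics,
                                     columns = c("M_spindle", "M_down",
                                                 "mua_modulation")) {
  if (nrow(metrics) < 3) stop("need at least 3 sessions to define z-scales")
  zs <- list()
  for (cn in columns) {
    v <- metrics[[cn]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("dropping zero-variance measure: ", cn)
      next
    }
    zs[[cn]] <- (v - mean(v)) / s
  }
  if (!length(zs)) stop("no usable measures")
  rowMeans(do.call(cbind, zs))
}

#' Mann-Kendall trend test
#'
#' Computes the S statistic, tie-corrected variance and two-sided p-value
#' (normal approximation with continuity correction; exact enumeration of
#' the null S distribution for n <= 10 without ties).
#'
#' @param values Ordered series (length >= 4).
#' @return List with `tau`, `s`, `p`.
#' @export
mann_kendall <- function(values) {
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  d <- outer(values, values, `-`)      # d[i, j] = x_i - x_j
  s <- sum(sign(d[lower.tri(d)]))      # sum over j < i of sign(x_i - x_j)
  tau <- s / (n * (n - 1) / 2)
  ties <- table(values)
  has_ties <- any(ties > 1)
  if (n <= 10 && !has_ties) {
    tab <- mk_s_distribution(n)
    p <- min(1, 2 * sum(tab$prob[tab$s >= abs(s)]))
  } else {
    varS <- (n * (n - 1) * (2 * n + 5) -
               sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (s > 0) (s - 1) / sqrt(varS) else if (s < 0) (s + 1) / sqrt(varS)
         else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, s = s, p = min(p, 1))
}

# exact null distribution of S for untied series via the inversion-number
# generating function prod_{i=1}^{n-1} (1 + x + ... + x^i)
mk_s_distribution <- function(n) {
  counts <- c(1)
  for (i in 1:(n - 1)) {
    new_len <- length(counts) + i
    nc <- numeric(new_len)
    for (k in 0:i) nc[(1 + k):(length(counts) + k)] <-
        nc[(1 + k):(length(counts) + k)] + counts
    counts <- nc
  }
  q <- seq_along(counts) - 1                 # inversion count
  smax <- n * (n - 1) / 2
  data.frame(s = smax - 2 * q, prob = counts / sum(counts))
}

#' Z-scored spindle-band power in time windows
#'
#' Mean 10-20 Hz power per window, z-scored against the distribution of
#' equal-length windows tiled over NREM sleep in the same session.
#'
#' @param bundle Session bundle.
#' @param channel Cortical channel.
#' @param windows data.frame (or 2-column matrix) of `start_s`, `end_s`.
#' @param band Band (default 10-20 Hz).
#' @return Numeric z-scored band power per window.
#' @export
spindle_band_power <- function(bundle, channel, windows, band = c(10, 20)) {
  windows <- as.data.frame(windows)
  names(windows)[1:2] <- c("start_s", "end_s")
  len <- windows$end_s - windows$start_s
  if (any(len < 0.25)) stop("windows must be at least 0.25 s long")
  fs <- bundle$meta$fs_hz
  x <- get_channel(bundle, channel)
  f <- bandpass(x, fs, band[1], band[2], order = 4)
  p2 <- f^2
  csum <- cumsum(p2)
  win_power <- function(a, b) {
    ia <- max(1L, floor(a * fs) + 1L)
    ib <- min(length(p2), ceiling(b * fs))
    (csum[ib] - csum[ia]) / (ib - ia)
  }
  obs <- mapply(win_power, windows$start_s, windows$end_s)
  wlen <- stats::median(len)
  nrem <- slice_by_state(bundle, "NREM")
  refs <- numeric(0)
  for (i in seq_len(nrow(nrem))) {
    starts <- seq(nrem$start_s[i], nrem$end_s[i] - wlen, by = wlen)
    if (length(starts)) {
      refs <- c(refs, mapply(win_power, starts, starts + wlen))
    }
  }
  if (length(refs) < 10) stop("too little NREM for a reference distribution")
  (obs - mean(refs)) / stats::sd(refs)
}

#' Multitaper coherence between two channels
#'
#' Randomly selects disjoint segments from the requested behavioral states,
#' computes multitaper cross- and auto-spectra (time-bandwidth 3, 5 Slepian
#' tapers) averaged over tapers and segments, and returns
#' `|C(f)| = |S12| / sqrt(S11 S22)` on the 1-100 Hz grid.
#'
#' @param bundle Session bundle.
#' @param ch_a,ch_b Channel labels or regions.
#' @param states Character vector of states to draw from (default NREM).
#' @param seg_s Segment length (default 10 s).
#' @param n_segments Number of segments (default 100; reduced with a warning
#'   when fewer are available, error below 5).
#' @param seed Seed for the segment draw.
#' @param normalize `"NONE"` or `"MEAN_1_100"` (divide by the 1-100 Hz mean).
#' @param nw,k Multitaper time-bandwidth product and taper count.
#' @return A `coherence_result` list: `freqs_hz`, `coherence`,
#'   `n_segments`, `normalization`.
#' @export
multitaper_coherence <- function(bundle, ch_a, ch_b, states = "NREM",
                                 seg_s = 10, n_segments = 100, seed = 1,
                                 normalize = c("NONE", "MEAN_1_100"),
                                 nw = 3, k = 5) {
  normalize <- match.arg(normalize)
  fs <- bundle$meta$fs_hz
  xa <- get_channel(bundle, ch_a)
  xb <- get_channel(bundle, ch_b)
  iv <- bundle$states[bundle$states$state %in% states, , drop = FALSE]
  slots <- list()
  for (i in seq_len(nrow(iv))) {
    starts <- seq(iv$start_s[i], iv$end_s[i] - seg_s, by = seg_s)
    for (s0 in starts) slots[[length(slots) + 1]] <- s0
  }
  slots <- unlist(slots)
  if (length(slots) < 5) stop("fewer than 5 disjoint segments available")
  if (length(slots) < n_segments) {
    warning("only ", length(slots), " segments available (requested ",
            n_segments, ")")
    n_segments <- length(slots)
  }
  pick <- with_seed(seed, sample(slots, n_segments))
  nseg <- round(seg_s * fs)
  tap <- dpss_cached(nseg, nw, k)
  nf <- nseg
  freqs <- (0:(nf - 1)) * fs / nf
  sel <- which(freqs >= 1 & freqs <= 100)
  s11 <- numeric(length(sel))
  s22 <- numeric(length(sel))
  s12 <- complex(length(sel))
  for (s0 in pick) {
    i0 <- floor(s0 * fs) + 1L
    seg_a <- xa[i0:(i0 + nseg - 1L)]
    seg_b <- xb[i0:(i0 + nseg - 1L)]
    seg_a <- seg_a - mean(seg_a)
    seg_b <- seg_b - mean(seg_b)
    for (j in seq_len(k)) {
      A <- stats::fft(seg_a * tap[, j])[sel]
      B <- stats::fft(seg_b * tap[, j])[sel]
      s11 <- s11 + Mod(A)^2
      s22 <- s22 + Mod(B)^2
      s12 <- s12 + A * Conj(B)
    }
  }
  coh <- Mod(s12) / sqrt(s11 * s22)
  if (normalize == "MEAN_1_100") coh <- coh / mean(coh)
  structure(list(freqs_hz = freqs[sel], coherence = coh,
                 n_segments = n_segments, normalization = normalize),
            class = "coherence_result")
}

.dpss_cache <- new.env(parent = emptyenv())

dpss_cached <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.dpss_cache[[key]])) {
    .dpss_cache[[key]] <- dpss_tapers(n, nw, k)
  }
  .dpss_cache[[key]]
}
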