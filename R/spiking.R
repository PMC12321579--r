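# Population-rate construction and peri-event single-unit modulation.
#
# The significance gate is a jittered-permutation maximum-deviation test on
# the event-locked cumulative spike density (the same binning-free family of
# temporal-anomaly statistic popularized for peri-event significance
# testing), with instantaneous firing rate (IFR) amplitude and latency
# extracted from a 10 ms Gaussian-kernel event-averaged rate.

#' Smoothed population rate
#'
#' Sums all unit spikes at 1 ms resolution and smooths with a 50 ms-SD
#' Gaussian window; optionally normalized by the session's NREM mean rate.
#'
#' @param units List of [spike_unit()] objects (at least one).
#' @param duration_s Session duration (s).
#' @param normalize Divide by the NREM mean rate (requires `states`).
#' @param states [state_intervals()] table (needed when `normalize = TRUE`).
#' @param bin_s Resolution (default 0.001 s).
#' @param smooth_sd_s Gaussian SD (default 0.05 s).
#' @return List with `rate_hz` (vector, possibly normalized), `times_s`,
#'   `bin_s`, `baseline_hz`.
#' @export
population_rate <- function(units, duration_s, normalize = FALSE,
                            states = NULL, bin_s = 0.001,
                            smooth_sd_s = 0.05) {
  if (!length(units)) stop("need at least one unit")
  spikes <- sort(unlist(lapply(units, `[[`, "spike_times_s")))
  nb <- ceiling(duration_s / bin_s)
  counts <- if (length(spikes)) {
    tabulate(pmin(floor(spikes / bin_s) + 1L, nb), nb)
  } else {
    warning("no spikes in any unit; returning all-zero rate")
    numeric(nb)
  }
  rate <- gaussian_smooth(counts / bin_s, smooth_sd_s / bin_s)
  times <- (seq_len(nb) - 0.5) * bin_s
  base <- NA_real_
  if (!is.null(states)) {
    nrem <- states[states$state == "NREM", , drop = FALSE]
    if (nrow(nrem)) base <- mean(rate[in_intervals(times, nrem)])
  }
  if (normalize) {
    if (!is.finite(base) || base <= 0) {
      stop("normalization requires NREM states with nonzero rate")
    }
    rate <- rate / base
  }
  list(rate_hz = rate, times_s = times, bin_s = bin_s, baseline_hz = base)
}

# deviation statistic: max |difference| between the event-locked cumulative
# spike-time distribution and the uniform (linear) baseline over the window
peri_event_stat <- function(rel_times, window_s) {
  if (!length(rel_times)) return(0)
  u <- sort(rel_times + window_s) / (2 * window_s)   # map to [0, 1]
  n <- length(u)
  emp <- seq_len(n) / n
  max(pmax(abs(emp - u), abs(u - (emp - 1 / n))))
}

collect_rel_times <- function(spikes, events, window_s) {
  lo <- findInterval(events - window_s, spikes) + 1L
  hi <- findInterval(events + window_s, spikes)
  out <- vector("list", length(events))
  for (i in seq_along(events)) {
    if (hi[i] >= lo[i]) out[[i]] <- spikes[lo[i]:hi[i]] - events[i]
  }
  unlist(out)
}

#' Peri-event modulation of a single unit
#'
#' Tests for time-locked firing-rate modulation around events with a
#' jittered-permutation maximum-deviation test, and quantifies the
#' modulation as the peak event-averaged IFR divided by the unit's baseline
#' rate, plus its latency.  Sessions with fewer than 20 events are excluded
#' (flagged, not tested).
#'
#' @param unit A [spike_unit()].
#' @param events Sorted event times (s).
#' @param duration_s Session duration (used to drop edge events).
#' @param states Optional [state_intervals()] for the NREM baseline rate.
#' @param window_s Peri-event half window (default 1 s).
#' @param n_perm Number of jitter permutations (default 500).
#' @param jitter_s Uniform jitter half-range (default 2 s).
#' @param ifr_sd_s IFR Gaussian kernel SD (default 0.01 s).
#' @param seed RNG seed.
#' @return A `modulation_result` list: `unit_id`, `p_value`,
#'   `ifr_peak_norm`, `latency_s`, `n_events`, `significant`, `excluded`,
#'   `baseline_hz`.
#' @export
peri_event_modulation <- function(unit, events, duration_s, states = NULL,
                                  window_s = 1, n_perm = 500, jitter_s = 2,
                                  ifr_sd_s = 0.01, seed = 1) {
  events <- sort(events)
  ok <- events - window_s - jitter_s > 0 &
    events + window_s + jitter_s < duration_s
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the session edge dropped")
    events <- events[ok]
  }
  res <- list(unit_id = unit$unit_id, n_events = length(events),
              p_value = NA_real_, ifr_peak_norm = NA_real_,
              latency_s = NA_real_, significant = NA, excluded = FALSE,
              baseline_hz = NA_real_)
  class(res) <- "modulation_result"
  if (length(events) < 20) {
    res$excluded <- TRUE
    return(res)
  }
  spikes <- unit$spike_times_s
  # baseline rate: NREM (or whole-session) time excluding +/-1 s around events
  base_iv <- if (!is.null(states)) {
    states[states$state == "NREM", c("start_s", "end_s"), drop = FALSE]
  } else {
    data.frame(start_s = 0, end_s = duration_s)
  }
  ev_iv <- data.frame(start_s = events - 1, end_s = events + 1)
  base_t <- interval_duration(base_iv)
  in_base <- in_intervals(spikes, base_iv) & !in_intervals(spikes, ev_iv)
  denom <- max(base_t - overlap_duration(base_iv, ev_iv), 1e-6)
  base_rate <- sum(in_base) / denom
  res$baseline_hz <- base_rate
  obs_rel <- collect_rel_times(spikes, events, window_s)
  obs <- peri_event_stat(obs_rel, window_s)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      jit <- events + stats::runif(length(events), -jitter_s, jitter_s)
      peri_event_stat(collect_rel_times(spikes, sort(jit), window_s),
                      window_s)
    }, 0)
  })
  res$p_value <- (1 + sum(null >= obs)) / (1 + n_perm)
  res$significant <- res$p_value < 0.05
  # IFR: Gaussian-kernel event-averaged rate
  grid_bin <- 0.002
  nb <- round(2 * window_s / grid_bin)
  cnt <- tabulate(pmin(pmax(floor((obs_rel + window_s) / grid_bin), 0) + 1L,
                       nb), nb)
  ifr <- gaussian_smooth(cnt / (grid_bin * length(events)),
                         ifr_sd_s / grid_bin)
  pk <- which.max(ifr)
  res$ifr_peak_norm <- if (base_rate > 0) ifr[pk] / base_rate else Inf
  res$latency_s <- (pk - 0.5) * grid_bin - window_s
  res
}

# total overlap between a set of base intervals and (possibly overlapping)
# event exclusion windows
overlap_duration <- function(base_iv, ev_iv) {
  if (!nrow(ev_iv) || !nrow(base_iv)) return(0)
  ev_iv <- ev_iv[order(ev_iv$start_s), , drop = FALSE]
  merged <- list()
  cs <- ev_iv$start_s[1]; ce <- ev_iv$end_s[1]
  for (i in seq_len(nrow(ev_iv))[-1]) {
    if (ev_iv$start_s[i] <= ce) {
      ce <- max(ce, ev_iv$end_s[i])
    } else {
      merged[[length(merged) + 1]] <- c(cs, ce)
      cs <- ev_iv$start_s[i]; ce <- ev_iv$end_s[i]
    }
  }
  merged[[length(merged) + 1]] <- c(cs, ce)
  tot <- 0
  for (m in merged) {
    tot <- tot + sum(pmax(0, pmin(base_iv$end_s, m[2]) -
                            pmax(base_iv$start_s, m[1])))
  }
  tot
}

#' Categorize units by their pathological-event modulation profile
#'
#' Assigns each unit to exactly one of `IED only`, `IED+DOWN`,
#' `IED+DOWN+UP`, `DOWN+UP only` or `unmodulated`, from the significance
#' flags of three modulation-result sets computed over the same units.
#'
#' @param ied,down,up Named lists (by unit id) or lists of
#'   `modulation_result`s for the IED, DOWN and post-DOWN UP events.
#' @return List with `categories` (per-unit), `proportions` (over modulated
#'   units) and `n_modulated`.
#' @export
categorize_modulation <- function(ied, down, up) {
  idx <- function(rs) {
    nm <- vapply(rs, `[[`, "", "unit_id")
    stats::setNames(rs, nm)
  }
  ied <- idx(ied); down <- idx(down); up <- idx(up)
  ids <- names(ied)
  if (!setequal(ids, names(down)) || !setequal(ids, names(up))) {
    stop("the three result sets must cover the same units")
  }
  sig <- function(r) isTRUE(r$significant) && !isTRUE(r$excluded)
  cat_of <- vapply(ids, function(id) {
    i <- sig(ied[[id]]); d <- sig(down[[id]]); u <- sig(up[[id]])
    if (i && d && u) "IED+DOWN+UP"
    else if (i && d) "IED+DOWN"
    else if (i) "IED only"
    else if (d && u) "DOWN+UP only"
    else if (d || u) "DOWN+UP only"
    else "unmodulated"
  }, "")
  mod <- cat_of[cat_of != "unmodulated"]
  props <- if (length(mod)) table(mod) / length(mod) else table(character())
  list(categories = cat_of, proportions = props, n_modulated = length(mod))
}

#' Percentage of units modulated by pathological events
#'
#' @param n_modulated Number of units significantly modulated by any
#'   pathological event class.
#' @param n_total Total clustered units.
#' @return Percentage `100 * n_modulated / n_total`.
#' @export
modulated_percentage <- function(n_modulated, n_total) {
  stopifnot(n_total > 0, n_modulated >= 0, n_modulated <= n_total)
  100 * n_modulated / n_total
}

#' Population firing in DOWN/UP transition windows
#'
#' For each DOWN-state transition, extracts the mean normalized population
#' rate in the 100 ms before the DOWN start (`up_pre`), the minimum in the
#' 200 ms after the DOWN onset (`down_min`), and the mean in the 500 ms
#' after the DOWN peak (`up_post`); aggregated separately for pathological
#' and physiological transitions.
#'
#' @param pop A normalized [population_rate()] result.
#' @param downs DOWN-state data.frame from [detect_down_states()].
#' @return data.frame with one row per retained transition: `up_pre`,
#'   `down_min`, `up_post`, `pathological`.
#' @export
transition_firing_windows <- function(pop, downs) {
  if (!nrow(downs)) {
    return(data.frame(up_pre = numeric(), down_min = numeric(),
                      up_post = numeric(), pathological = logical()))
  }
  dur <- max(pop$times_s) + pop$bin_s / 2
  keep <- downs$t_peak + 0.5 <= dur & downs$t_start - 0.1 >= 0
  downs <- downs[keep, , drop = FALSE]
  seg_mean <- function(a, b) {
    ia <- max(1L, floor(a / pop$bin_s) + 1L)
    ib <- min(length(pop$rate_hz), ceiling(b / pop$bin_s))
    mean(pop$rate_hz[ia:ib])
  }
  seg_min <- function(a, b) {
    ia <- max(1L, floor(a / pop$bin_s) + 1L)
    ib <- min(length(pop$rate_hz), ceiling(b / pop$bin_s))
    min(pop$rate_hz[ia:ib])
  }
  data.frame(
    up_pre = mapply(function(s) seg_mean(s - 0.1, s), downs$t_start),
    down_min = mapply(function(s) seg_min(s, s + 0.2), downs$t_start),
    up_post = mapply(function(p) seg_mean(p, p + 0.5), downs$t_peak),
    pathological = downs$pathological %in% TRUE)
}

#' Rank correlation between two sets of modulation strengths
#'
#' Spearman correlation of `ifr_peak_norm` between two event kinds over the
#' shared, non-excluded units.
#'
#' @param results_a,results_b Lists of `modulation_result`s.
#' @return List with `rho`, `p`, `n`.
#' @export
modulation_correlation <- function(results_a, results_b) {
  ids_a <- vapply(results_a, `[[`, "", "unit_id")
  ids_b <- vapply(results_b, `[[`, "", "unit_id")
  shared <- intersect(ids_a, ids_b)
  va <- vb <- numeric(0)
  for (id in shared) {
    ra <- results_a[[match(id, ids_a)]]
    rb <- results_b[[match(id, ids_b)]]
    if (isTRUE(ra$excluded) || isTRUE(rb$excluded)) next
    va <- c(va, ra$ifr_peak_norm)
    vb <- c(vb, rb$ifr_peak_norm)
  }
  if (length(va) < 5) stop("fewer than 5 shared non-excluded units")
  ct <- suppressWarnings(stats::cor.test(va, vb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(va))
}
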