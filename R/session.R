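# Session data model and Neuroscope-style flat-binary I/O.
#
# A recording session is a directory:
#   session.dat    interleaved little-endian int16, channel-major per frame
#   session.json   sidecar: fs_hz, channels (label/region/kind/uv_per_bit),
#                  day_index, condition, session_id, seed, n_samples
#   states.tsv     start_s  end_s  state          (optional)
#   events.tsv     kind  channel  start_s  peak_s  end_s  amplitude_uv (opt.)
#   units.tsv      unit_id  region  cell_class    (optional)
#   spikes/<unit_id>.tsv   spike_time_s           (one per unit)
#   ground_truth.json      generator ground truth (optional)
#
# All event and spike times are seconds from session start; intervals are
# half-open [start, end); amplitudes are microvolts.

REGIONS <- c("HC", "MPFC", "OTHER")
CHANNEL_KINDS <- c("LFP", "ACCEL", "STIM")
STATES <- c("NREM", "REM", "WAKE")
EVENT_KINDS <- c("IED", "SPINDLE", "DOWN", "STIM", "AIED")
CELL_CLASSES <- c("PYR", "INT", "UNCLASSIFIED")
CONDITIONS <- c("BASELINE", "KINDLED_ONLY", "SHAM", "CLOSED_LOOP", "AIED")

#' Channel metadata
#'
#' @param label Unique channel label.
#' @param region One of `"HC"`, `"MPFC"`, `"OTHER"`.
#' @param kind One of `"LFP"`, `"ACCEL"`, `"STIM"`.
#' @param uv_per_bit Microvolts per integer unit of the 16-bit payload.
#' @return A `channel_info` list.
#' @export
channel_info <- function(label, region = "OTHER", kind = "LFP",
                         uv_per_bit = 0.2) {
  stopifnot(region %in% REGIONS, kind %in% CHANNEL_KINDS, uv_per_bit > 0)
  structure(list(label = label, region = region, kind = kind,
                 uv_per_bit = uv_per_bit), class = "channel_info")
}

#' Session metadata
#'
#' @param session_id Character id.
#' @param day_index Integer day (0 = baseline).
#' @param condition Experimental arm (`"BASELINE"`, `"KINDLED_ONLY"`,
#'   `"SHAM"`, `"CLOSED_LOOP"`, `"AIED"`).
#' @param fs_hz Sampling rate (Hz).
#' @param n_samples Number of sample frames.
#' @param channels List of [channel_info()] records.
#' @param seed Generator seed or `NULL`.
#' @return A `session_meta` list.
#' @export
session_meta <- function(session_id, day_index, condition, fs_hz, n_samples,
                         channels, seed = NULL) {
  stopifnot(fs_hz > 0, n_samples >= 0, condition %in% CONDITIONS,
            day_index >= 0)
  labels <- vapply(channels, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(list(session_id = session_id, day_index = as.integer(day_index),
                 condition = condition, fs_hz = fs_hz,
                 n_samples = as.integer(n_samples), channels = channels,
                 seed = seed), class = "session_meta")
}

#' Behavioral-state intervals
#'
#' @param start_s,end_s Numeric vectors of half-open interval bounds (s).
#' @param state Character vector of states (`"NREM"`, `"REM"`, `"WAKE"`).
#' @return A data.frame of class `state_intervals`, sorted by start.
#' @export
state_intervals <- function(start_s = numeric(), end_s = numeric(),
                            state = character()) {
  if (length(state) && !all(state %in% STATES)) {
    stop("unknown state label: ",
         paste(setdiff(unique(state), STATES), collapse = ", "))
  }
  df <- data.frame(start_s = start_s, end_s = end_s, state = state,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("state_intervals", "data.frame")
  df
}

#' Event series container
#'
#' A sorted table of detected or injected transient events of one kind.
#'
#' @param events data.frame with columns `kind`, `channel`, `start_s`,
#'   `peak_s`, `end_s`, `amplitude_uv` (extra columns are kept).
#' @param region Region the events belong to.
#' @param kind Shared event kind.
#' @param params Provenance list of detector/generator settings.
#' @return An `event_series` object.
#' @export
event_series <- function(events = empty_events(), region = "OTHER",
                         kind = "IED", params = list()) {
  stopifnot(kind %in% EVENT_KINDS)
  if (nrow(events)) {
    events <- events[order(events$peak_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, region = region, kind = kind,
                 params = params), class = "event_series")
}

#' Empty event table with the canonical columns
#' @return A zero-row events data.frame.
#' @export
empty_events <- function() {
  data.frame(kind = character(), channel = character(), start_s = numeric(),
             peak_s = numeric(), end_s = numeric(), amplitude_uv = numeric(),
             stringsAsFactors = FALSE)
}

#' Single-unit spike train
#'
#' @param unit_id Unit identifier.
#' @param region Recording region.
#' @param cell_class `"PYR"`, `"INT"` or `"UNCLASSIFIED"`.
#' @param spike_times_s Strictly increasing spike times (s).
#' @return A `spike_unit` object.
#' @export
spike_unit <- function(unit_id, region = "MPFC", cell_class = "UNCLASSIFIED",
                       spike_times_s = numeric()) {
  stopifnot(cell_class %in% CELL_CLASSES)
  structure(list(unit_id = unit_id, region = region, cell_class = cell_class,
                 spike_times_s = as.numeric(spike_times_s)),
            class = "spike_unit")
}

#' Assemble a session bundle
#'
#' The central in-memory container: LFP matrix (microvolts, samples x
#' channels), metadata, behavioral states, spike units, event series and
#' optional generator ground truth.
#'
#' @param meta A [session_meta()].
#' @param lfp Numeric matrix `n_samples x n_channels`.
#' @param states A [state_intervals()] table.
#' @param units List of [spike_unit()] objects.
#' @param event_series Named list of [event_series()] objects.
#' @param ground_truth Optional ground-truth list (see the generator).
#' @return A `session_bundle`.
#' @export
session_bundle <- function(meta, lfp, states = state_intervals(),
                           units = list(), event_series = list(),
                           ground_truth = NULL) {
  lfp <- as.matrix(lfp)
  if (nrow(lfp) != meta$n_samples || ncol(lfp) != length(meta$channels)) {
    stop(sprintf("LFP matrix is %d x %d but metadata declares %d x %d",
                 nrow(lfp), ncol(lfp), meta$n_samples, length(meta$channels)))
  }
  colnames(lfp) <- vapply(meta$channels, `[[`, "", "label")
  structure(list(meta = meta, lfp = lfp, states = states, units = units,
                 event_series = event_series, ground_truth = ground_truth),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle %s> day %d, %s, %.4g Hz, %.1f s, %d ch, %d units, %d event series\n",
              x$meta$session_id, x$meta$day_index, x$meta$condition,
              x$meta$fs_hz, x$meta$n_samples / x$meta$fs_hz,
              length(x$meta$channels), length(x$units),
              length(x$event_series)))
  invisible(x)
}

session_duration <- function(bundle) bundle$meta$n_samples / bundle$meta$fs_hz

#' Get one channel's signal
#'
#' @param bundle A session bundle.
#' @param channel Channel label, or a region name (first LFP channel of the
#'   region is used).
#' @return Numeric vector of microvolt samples.
#' @export
get_channel <- function(bundle, channel) {
  labels <- vapply(bundle$meta$channels, `[[`, "", "label")
  if (channel %in% labels) return(bundle$lfp[, match(channel, labels)])
  regions <- vapply(bundle$meta$channels, `[[`, "", "region")
  kinds <- vapply(bundle$meta$channels, `[[`, "", "kind")
  hit <- which(regions == channel & kinds == "LFP")
  if (!length(hit)) stop("no channel labelled or in region: ", channel)
  bundle$lfp[, hit[1]]
}

channel_by_kind <- function(bundle, kind) {
  kinds <- vapply(bundle$meta$channels, `[[`, "", "kind")
  hit <- which(kinds == kind)
  if (!length(hit)) return(NULL)
  bundle$lfp[, hit[1]]
}

# ---- interval helpers ------------------------------------------------------

#' Which times fall inside a set of half-open intervals?
#' @param times Numeric vector of times (s).
#' @param intervals data.frame with `start_s`, `end_s`.
#' @return Logical vector.
#' @export
in_intervals <- function(times, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(times)))
  idx <- findInterval(times, intervals$start_s)
  ok <- idx >= 1
  ok[ok] <- times[ok] < intervals$end_s[idx[ok]]
  ok
}

interval_duration <- function(intervals) {
  if (!nrow(intervals)) return(0)
  sum(intervals$end_s - intervals$start_s)
}

# logical mask over samples for a set of intervals
interval_mask <- function(intervals, n, fs) {
  m <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(intervals$end_s[i] * fs))
    if (b >= a) m[a:b] <- TRUE
  }
  m
}

# ---- operations ------------------------------------------------------------

#' Intervals of one behavioral state
#'
#' @param bundle Session bundle with scored states.
#' @param state `"NREM"`, `"REM"` or `"WAKE"`.
#' @return data.frame of sorted, non-overlapping `start_s`/`end_s` intervals.
#' @export
slice_by_state <- function(bundle, state) {
  if (!state %in% STATES) stop("unknown state: ", state)
  st <- bundle$states
  out <- st[st$state == state, c("start_s", "end_s"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cheeseboard memory performance percentage
#'
#' @param retrieved Number of retrieved rewards.
#' @param available Number of available rewards (> 0).
#' @return `100 * retrieved / available`.
#' @export
memory_performance <- function(retrieved, available) {
  if (length(available) != 1 || available <= 0) {
    stop("available rewards must be a positive count")
  }
  if (retrieved < 0 || retrieved > available) {
    stop("retrieved must lie in [0, available]")
  }
  100 * retrieved / available
}

#' Validate a session bundle against the data-model invariants
#'
#' Checks every structural invariant (shape consistency, sorted
#' non-overlapping states, event ordering within series, strictly increasing
#' spike times, event times inside the session) and reports violations
#' without throwing.
#'
#' @param bundle Session bundle.
#' @return A character vector of violation descriptions (empty if valid).
#' @export
validate_session <- function(bundle) {
  v <- character()
  meta <- bundle$meta
  if (nrow(bundle$lfp) != meta$n_samples ||
      ncol(bundle$lfp) != length(meta$channels)) {
    v <- c(v, "LFP matrix shape inconsistent with metadata")
  }
  upb <- vapply(meta$channels, `[[`, 0, "uv_per_bit")
  if (any(upb <= 0)) v <- c(v, "non-positive uv_per_bit")
  labels <- vapply(meta$channels, `[[`, "", "label")
  if (anyDuplicated(labels)) v <- c(v, "duplicate channel labels")
  st <- bundle$states
  if (nrow(st)) {
    if (is.unsorted(st$start_s)) v <- c(v, "state intervals not sorted")
    if (any(st$end_s <= st$start_s)) {
      v <- c(v, "state interval with end_s <= start_s")
    }
    if (nrow(st) > 1 && any(st$start_s[-1] < st$end_s[-nrow(st)])) {
      v <- c(v, "overlapping state intervals")
    }
    if (!all(st$state %in% STATES)) v <- c(v, "unknown state label")
  }
  dur <- session_duration(bundle)
  for (u in bundle$units) {
    ts <- u$spike_times_s
    if (length(ts) > 1 && any(diff(ts) <= 0)) {
      v <- c(v, sprintf("unit %s: spike times not strictly increasing",
                        u$unit_id))
    }
    if (length(ts) && (min(ts) < 0 || max(ts) >= dur + 1 / meta$fs_hz)) {
      v <- c(v, sprintf("unit %s: spike times outside session", u$unit_id))
    }
  }
  for (nm in names(bundle$event_series)) {
    es <- bundle$event_series[[nm]]
    ev <- es$events
    if (!nrow(ev)) next
    if (is.unsorted(ev$peak_s)) {
      v <- c(v, sprintf("series %s: events not sorted by peak_s", nm))
    }
    if (any(ev$start_s > ev$peak_s | ev$peak_s > ev$end_s)) {
      v <- c(v, sprintf("series %s: start_s <= peak_s <= end_s violated", nm))
    }
    if (any(ev$peak_s >= dur)) {
      v <- c(v, sprintf("series %s: event beyond session end", nm))
    }
    if (length(unique(ev$kind)) > 1) {
      v <- c(v, sprintf("series %s: mixed event kinds", nm))
    }
    if (!is.null(ev$amplitude_uv) &&
        any(ev$amplitude_uv < 0, na.rm = TRUE)) {
      v <- c(v, sprintf("series %s: negative amplitude", nm))
    }
  }
  v
}

# ---- disk I/O --------------------------------------------------------------

#' Write a session directory
#'
#' Emits the flat binary payload, JSON sidecar and TSV tables.  Output is
#' deterministic for a fixed bundle.
#'
#' @param bundle Session bundle.
#' @param path Directory to create/populate.
#' @return Invisibly, `path`.
#' @export
write_session <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- bundle$meta
  upb <- vapply(meta$channels, `[[`, 0, "uv_per_bit")
  scaled <- sweep(bundle$lfp, 2, upb, `/`)
  if (any(abs(scaled) > 32767)) {
    bad <- which(apply(abs(scaled), 2, max) > 32767)
    stop(sprintf(
      "channel(s) %s exceed int16 range after scaling; increase uv_per_bit",
      paste(vapply(meta$channels[bad], `[[`, "", "label"), collapse = ", ")))
  }
  con <- file(file.path(path, "session.dat"), "wb")
  writeBin(as.integer(round(t(scaled))), con, size = 2, endian = "little")
  close(con)
  side <- list(
    session_id = meta$session_id, day_index = meta$day_index,
    condition = meta$condition, fs_hz = meta$fs_hz,
    n_samples = meta$n_samples, seed = meta$seed,
    channels = lapply(meta$channels, function(ch) {
      ch_l <- unclass(ch)
      ch_l
    }))
  jsonlite::write_json(side, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (nrow(bundle$states)) {
    utils::write.table(bundle$states, file.path(path, "states.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  all_ev <- do.call(rbind, lapply(bundle$event_series, function(es) {
    es$events[, intersect(names(empty_events()), names(es$events)),
              drop = FALSE]
  }))
  if (!is.null(all_ev) && nrow(all_ev)) {
    all_ev <- all_ev[order(all_ev$peak_s), , drop = FALSE]
    utils::write.table(all_ev, file.path(path, "events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (length(bundle$units)) {
    dir.create(file.path(path, "spikes"), showWarnings = FALSE)
    ut <- data.frame(
      unit_id = vapply(bundle$units, `[[`, "", "unit_id"),
      region = vapply(bundle$units, `[[`, "", "region"),
      cell_class = vapply(bundle$units, `[[`, "", "cell_class"),
      stringsAsFactors = FALSE)
    utils::write.table(ut, file.path(path, "units.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (u in bundle$units) {
      utils::write.table(
        data.frame(spike_time_s = u$spike_times_s),
        file.path(path, "spikes", paste0(u$unit_id, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(bundle$ground_truth)) {
    jsonlite::write_json(
      bundle$ground_truth, file.path(path, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, null = "null", dataframe = "columns")
  }
  invisible(path)
}

#' Read a session directory
#'
#' Reads the payload and sidecar, scales to microvolts, loads any optional
#' state/event/spike tables and resamples the LFP to the canonical analysis
#' rate if the sidecar declares a different one.
#'
#' @param path Session directory.
#' @param target_fs_hz Canonical analysis rate (default 1250 Hz).
#' @return A [session_bundle()].
#' @export
read_session <- function(path, target_fs_hz = 1250) {
  side <- jsonlite::read_json(file.path(path, "session.json"))
  channels <- lapply(side$channels, function(ch) {
    channel_info(ch$label, ch$region, ch$kind, ch$uv_per_bit)
  })
  n_ch <- length(channels)
  n_samples <- as.integer(side$n_samples)
  datf <- file.path(path, "session.dat")
  expected <- 2 * n_ch * n_samples
  actual <- file.info(datf)$size
  if (is.na(actual) || actual != expected) {
    stop(sprintf("payload size mismatch: expected %d bytes (%d x %d int16), found %s",
                 expected, n_samples, n_ch,
                 ifelse(is.na(actual), "missing file", actual)))
  }
  con <- file(datf, "rb")
  raw_i <- readBin(con, "integer", n = n_ch * n_samples, size = 2,
                   endian = "little", signed = TRUE)
  close(con)
  lfp <- t(matrix(as.numeric(raw_i), nrow = n_ch))
  upb <- vapply(channels, `[[`, 0, "uv_per_bit")
  lfp <- sweep(lfp, 2, upb, `*`)
  fs <- side$fs_hz
  if (!isTRUE(all.equal(fs, target_fs_hz))) {
    lfp <- apply(lfp, 2, resample_signal, fs_in = fs, fs_out = target_fs_hz)
    fs <- target_fs_hz
    n_samples <- nrow(lfp)
  }
  meta <- session_meta(side$session_id, side$day_index, side$condition,
                       fs, n_samples, channels,
                       seed = if (is.null(side$seed)) NULL else side$seed)
  states <- state_intervals()
  sf <- file.path(path, "states.tsv")
  if (file.exists(sf)) {
    st <- utils::read.delim(sf, stringsAsFactors = FALSE)
    states <- state_intervals(st$start_s, st$end_s, st$state)
  }
  series <- list()
  ef <- file.path(path, "events.tsv")
  if (file.exists(ef)) {
    ev <- utils::read.delim(ef, stringsAsFactors = FALSE)
    for (k in unique(ev$kind)) {
      for (chn in unique(ev$channel[ev$kind == k])) {
        sub <- ev[ev$kind == k & ev$channel == chn, , drop = FALSE]
        reg <- region_of_channel(channels, chn)
        series[[paste(k, chn, sep = ":")]] <-
          event_series(sub, region = reg, kind = k)
      }
    }
  }
  units <- list()
  uf <- file.path(path, "units.tsv")
  if (file.exists(uf)) {
    ut <- utils::read.delim(uf, stringsAsFactors = FALSE)
    units <- lapply(seq_len(nrow(ut)), function(i) {
      ts <- utils::read.delim(
        file.path(path, "spikes", paste0(ut$unit_id[i], ".tsv")))$spike_time_s
      spike_unit(ut$unit_id[i], ut$region[i], ut$cell_class[i], ts)
    })
  }
  gt <- NULL
  gf <- file.path(path, "ground_truth.json")
  if (file.exists(gf)) gt <- deserialize_ground_truth(jsonlite::read_json(gf))
  session_bundle(meta, lfp, states, units, series, gt)
}

region_of_channel <- function(channels, label) {
  for (ch in channels) if (ch$label == label) return(ch$region)
  "OTHER"
}

deserialize_ground_truth <- function(x) {
  fix_df <- function(d) as.data.frame(lapply(d, unlist),
                                      stringsAsFactors = FALSE)
  for (nm in c("events", "unit_gains")) {
    if (!is.null(x[[nm]]) && length(x[[nm]])) x[[nm]] <- fix_df(x[[nm]])
  }
  x
}
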