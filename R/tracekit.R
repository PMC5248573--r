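# Per-cell geminin trace analysis: smoothing, S/G2 phase calling, event
# detection, phase lengths, minimum doubling time and fate classification.

#' Moving-average smoothing of a geminin trace
#'
#' Centered moving average with a 40-frame default window. At the series
#' edges the window shrinks symmetrically (half-width `min(k, i-1, n-i)`),
#' which keeps onset times unbiased and preserves the series mean exactly
#' whenever the first and last `2k` frames are constant (the usual case for
#' reporter traces, which start and end in the flat G0/G1 baseline); for
#' other series the edge-induced mean error is bounded by
#' `2k * max(abs(x)) / n`.
#'
#' @param trace A [cell_trace()] or a numeric vector.
#' @param window_frames Window width in frames (>= 1, <= series length).
#' @return Numeric vector, same length as the input series.
#' @export
smooth_geminin <- function(trace, window_frames = 40) {
  x <- if (inherits(trace, "cell_trace")) trace$geminin else as.numeric(trace)
  n <- length(x)
  if (window_frames < 1) stop("window_frames must be >= 1")
  if (window_frames > n) stop("window longer than trace")
  if (window_frames == 1 || n == 1) return(x)
  k <- floor(window_frames / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  h <- pmin(k, i - 1, n - i)
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

# sustained threshold crossing: first index of a run of >= min_run frames all
# satisfying `cond`, searching from `from`
first_sustained <- function(cond, from, min_run) {
  n <- length(cond)
  if (from > n) return(NA_integer_)
  r <- rle(cond[from:n])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_run)
  if (!length(ok)) return(NA_integer_)
  from + starts[ok[1]] - 1
}

#' Segment a trace into G0/G1 and S/G2 phases
#'
#' S/G2 onset is the first frame at which the windowed moving average of the
#' geminin signal exceeds `threshold` (2.0 for COLO858, 1.5 for MMACSF) for at
#' least `min_run` consecutive frames, after a G0/G1 interval; the S/G2
#' interval ends when the smoothed signal falls back below threshold (at a
#' division, the sharp drop pulls it down) or at the end of the observed
#' lifetime. The segmentation is contiguous, covers the observed lifetime and
#' alternates phases.
#'
#' @param trace A [cell_trace()].
#' @param threshold Intensity threshold (> 0).
#' @param window_frames Moving-average window (frames).
#' @param min_run Minimum frames above/below threshold to accept a crossing
#'   (rejects single-frame noise excursions).
#' @return Object of class `phase_segmentation`: data.frame `intervals`
#'   (`start_h`, `end_h`, `phase`) plus `threshold_used`, `window_frames`,
#'   `censored` (TRUE if the terminal interval is cut by the observation end).
#' @export
call_phases <- function(trace, threshold, window_frames = 40, min_run = 5) {
  stopifnot(inherits(trace, "cell_trace"))
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(trace$times)
  if (n == 0) stop("empty trace")
  sm <- smooth_geminin(trace, min(window_frames, n))
  above <- sm > threshold
  bounds <- numeric(0)  # phase switch times
  phases <- character(0)
  i <- 1L
  state <- "G0G1"
  start_t <- trace$times[1]
  repeat {
    j <- if (state == "G0G1") first_sustained(above, i, min_run)
         else first_sustained(!above, i, min_run)
    if (is.na(j)) break
    bounds <- c(bounds, trace$times[j])
    phases <- c(phases, state)
    state <- if (state == "G0G1") "SG2" else "G0G1"
    i <- j
  }
  end_t <- trace$times[n]
  intervals <- data.frame(
    start_h = c(start_t, bounds),
    end_h = c(bounds, end_t),
    phase = c(phases, state)
  )
  intervals <- intervals[intervals$end_h > intervals$start_h, , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, threshold_used = threshold,
                 window_frames = window_frames, censored = TRUE,
                 trace_end_h = end_t),
            class = "phase_segmentation")
}

#' S/G2 onset times of a segmentation
#' @param seg A `phase_segmentation`.
#' @return Numeric vector of S/G2 interval start times (h).
#' @export
sg2_onsets <- function(seg) {
  seg$intervals$start_h[seg$intervals$phase == "SG2"]
}

#' Detect division and death events in a trace
#'
#' Division: each S/G2 interval called by [call_phases()] that terminates
#' before the end of the observation is scanned around its falling threshold
#' crossing for the steepest drop of the raw signal over `drop_frames`
#' consecutive frames; a division is called there if the drop is at least
#' `drop_fraction` of the interval's peak signal. Death: the first frame at
#' which the `alive` series becomes `FALSE`. When `use_annotations = TRUE`
#' (default) and the trace carries annotated events, those take precedence
#' over signal-derived calls.
#'
#' @param trace A [cell_trace()].
#' @param threshold Intensity threshold used for the underlying segmentation.
#' @param window_frames Moving-average window (frames).
#' @param drop_fraction Minimum drop, as a fraction of the S/G2 peak.
#' @param drop_frames Frames over which the drop must occur.
#' @param min_run Passed to [call_phases()].
#' @param use_annotations Honor `trace$annotated_events` when present.
#' @return Object of class `event_record`: `divisions` (hours), `death`
#'   (hour or `NA`), `censored_at` (hour).
#' @export
detect_events <- function(trace, threshold = 2.0, window_frames = 40,
                          drop_fraction = 0.5, drop_frames = 2, min_run = 5,
                          use_annotations = TRUE) {
  stopifnot(inherits(trace, "cell_trace"))
  n <- length(trace$times)
  censored_at <- trace$times[n]
  dead_idx <- which(!trace$alive)
  death <- if (length(dead_idx)) trace$times[dead_idx[1]] else NA_real_

  ev <- trace$annotated_events
  if (use_annotations && !is.null(ev) && nrow(ev) > 0) {
    divisions <- sort(ev$time[ev$kind == "division"])
    ann_death <- ev$time[ev$kind == "death"]
    if (length(ann_death)) death <- min(ann_death)
    return(event_record(divisions, death, censored_at))
  }

  seg <- call_phases(trace, threshold, window_frames, min_run)
  iv <- seg$intervals
  sg2 <- iv[iv$phase == "SG2", , drop = FALSE]
  dt <- if (n > 1) trace$times[2] - trace$times[1] else 1
  divisions <- numeric(0)
  for (r in seq_len(nrow(sg2))) {
    term <- sg2$end_h[r]
    if (term >= censored_at - 1e-9) next  # censored S/G2: no division observed
    peak_win <- trace$geminin[trace$times >= sg2$start_h[r] &
                                trace$times <= term + 1e-9]
    peak <- max(peak_win)
    # search the raw signal near the falling crossing for the steepest drop;
    # the division frame is the end of the largest single-step decrease
    half <- ceiling(window_frames / 2) + drop_frames
    term_i <- which.min(abs(trace$times - term))
    lo <- max(2, term_i - half)
    hi <- min(n, term_i + half)
    if (hi < lo) next
    idx <- lo:hi
    steps <- trace$geminin[idx - 1] - trace$geminin[idx]
    j <- idx[which.max(steps)]
    jend <- min(j - 1 + drop_frames, n)
    if (trace$geminin[j - 1] - min(trace$geminin[j:jend]) >=
          drop_fraction * peak) {
      divisions <- c(divisions, trace$times[j])
    }
  }
  event_record(sort(unique(divisions)), death, censored_at)
}

#' Construct an event record
#' @param divisions Division times (h). @param death Death time (h) or `NA`.
#' @param censored_at End of observation (h).
#' @export
event_record <- function(divisions = numeric(0), death = NA_real_,
                         censored_at) {
  if (!is.na(death)) divisions <- divisions[divisions < death]
  if (any(divisions > censored_at + 1e-9))
    stop("events must lie within [0, censored_at]")
  structure(list(divisions = as.numeric(divisions), death = death,
                 censored_at = censored_at),
            class = "event_record")
}

#' Per-phase durations of a segmentation
#'
#' @param seg A `phase_segmentation`.
#' @return data.frame (`phase`, `start_h`, `end_h`, `duration_h`, `censored`);
#'   durations sum to the observed lifetime, and the terminal interval is
#'   flagged as censored by the observation end.
#' @export
phase_lengths <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  iv <- seg$intervals
  data.frame(phase = iv$phase, start_h = iv$start_h, end_h = iv$end_h,
             duration_h = iv$end_h - iv$start_h,
             censored = seq_len(nrow(iv)) == nrow(iv))
}

#' Minimum doubling time from division events in a window
#'
#' The longest time interval before or after (or, with multiple divisions,
#' between) divisions inside the observation window: with divisions
#' `t1 < ... < tk` in `[a, b]` this is `max(t1 - a, b - tk)` for `k = 1` and
#' the maximum over `(t1 - a, t2 - t1, ..., b - tk)` for `k >= 2`. With no
#' division the window length is returned, flagged as a lower bound (the cell
#' demonstrably did not double within the window).
#'
#' @param events An [event_record()].
#' @param observation_window Length-2 numeric `(start_h, end_h)`.
#' @return Hours, with attribute `lower_bound` (TRUE when no division fell in
#'   the window).
#' @export
min_doubling_time <- function(events, observation_window) {
  a <- observation_window[1]; b <- observation_window[2]
  if (!(b > a)) stop("empty observation window")
  d <- sort(events$divisions[events$divisions >= a & events$divisions <= b])
  if (length(d) == 0)
    return(structure(b - a, lower_bound = TRUE))
  gaps <- c(d[1] - a, diff(d), b - d[length(d)])
  structure(max(gaps), lower_bound = FALSE)
}

#' Classify a cell's fate from its events and segmentation
#'
#' `dead` if a death event is present; otherwise `adapted` if an S/G2 onset or
#' a division occurs after `arrest_min_h` (separating the initial drug-induced
#' arrest, complete within ~24 h, from adaptive S-phase re-entry at 48-84 h);
#' otherwise `arrested`.
#'
#' @param events An [event_record()].
#' @param seg A `phase_segmentation` for the same cell.
#' @param movie_length_h Total tracked time (h).
#' @param arrest_min_h Earliest time an S/G2 onset or division counts as
#'   adaptive re-entry.
#' @return Object of class `fate_call`: `fate` in
#'   `{"dead", "arrested", "adapted"}` and `support` (death time or first
#'   re-entry time, h; `NA` for arrested).
#' @export
classify_fate <- function(events, seg, movie_length_h, arrest_min_h = 36) {
  if (!is.na(events$death)) {
    return(structure(list(fate = "dead", support = events$death),
                     class = "fate_call"))
  }
  cand <- c(sg2_onsets(seg), events$divisions)
  cand <- cand[cand > arrest_min_h & cand <= movie_length_h]
  if (length(cand)) {
    structure(list(fate = "adapted", support = min(cand)), class = "fate_call")
  } else {
    structure(list(fate = "arrested", support = NA_real_), class = "fate_call")
  }
}

#' Run the full per-cell trace pipeline over a panel
#'
#' Smoothing, phase calling, event detection and fate classification for every
#' trace in a panel, with one row of calls per cell.
#'
#' @param panel A `trace_panel` (or list of `cell_trace`).
#' @param threshold S/G2 calling threshold (2.0 COLO858, 1.5 MMACSF); default
#'   taken from the panel preset when available.
#' @param window_frames Moving-average window.
#' @param arrest_min_h Passed to [classify_fate()].
#' @param use_annotations Passed to [detect_events()]; set `FALSE` to force
#'   signal-based event detection.
#' @return data.frame (`cell_id`, `fate`, `n_divisions`, `death_h`,
#'   `first_reentry_h`, `min_doubling_h`) with the per-cell `event_record`s
#'   attached as attribute `events`.
#' @export
analyze_traces <- function(panel, threshold = NULL, window_frames = 40,
                           arrest_min_h = 36, use_annotations = FALSE) {
  traces <- if (inherits(panel, "trace_panel")) panel$traces else panel
  if (is.null(threshold)) {
    meta <- attr(panel, "meta")
    preset <- if (!is.null(meta)) meta$preset else NULL
    threshold <- if (identical(preset, "mmacsf_vem")) 1.5 else 2.0
  }
  rows <- vector("list", length(traces))
  all_events <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    seg <- call_phases(tr, threshold, window_frames)
    ev <- detect_events(tr, threshold, window_frames,
                        use_annotations = use_annotations)
    movie <- tr$times[length(tr$times)]
    fc <- classify_fate(ev, seg, movie, arrest_min_h)
    mdt <- min_doubling_time(ev, c(0, ev$censored_at))
    rows[[i]] <- data.frame(
      cell_id = tr$cell_id, fate = fc$fate,
      n_divisions = length(ev$divisions), death_h = ev$death,
      first_reentry_h = if (fc$fate == "adapted") fc$support else NA_real_,
      min_doubling_h = as.numeric(mdt)
    )
    all_events[[i]] <- ev
  }
  out <- do.call(rbind, rows)
  attr(out, "events") <- all_events
  out
}
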