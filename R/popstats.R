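# Cohort-level summaries: grouped fate fractions, division-event percentages
# per interval, growth curves and log-linear doubling-time fits.

#' Round-robin group assignment
#'
#' Mirrors the pooling of imaged wells into 3-4 groups of ~50-70 cells for
#' mean +/- SD reporting: cells are dealt round-robin into `n_groups` groups.
#'
#' @param n Number of cells.
#' @param n_groups Number of groups; chosen automatically (3-4, targeting
#'   50-70 cells per group) when `NULL`.
#' @return Integer group labels of length `n`.
#' @export
assign_groups <- function(n, n_groups = NULL) {
  if (is.null(n_groups)) {
    n_groups <- max(3, min(4, round(n / 60)))
    if (n < 3) n_groups <- 1
  }
  rep_len(seq_len(n_groups), n)
}

#' Grouped fate fractions (mean +/- SD across groups)
#'
#' Computes per-group fractions of dead, surviving, arrested and adapted
#' cells, and reports the across-group mean and sample SD (n-1 denominator),
#' as in the grouped-well reporting of live-cell fate data.
#'
#' @param calls A data.frame with a `fate` column (from [analyze_traces()]),
#'   or a character vector of fates.
#' @param grouping Group labels (recycled logic not applied; must match
#'   length), or `NULL` for automatic round-robin assignment.
#' @return Object of class `fate_summary`: `per_group` (fraction matrix,
#'   groups x classes), `mean`, `sd`, `group_sizes`.
#' @export
fate_fractions <- function(calls, grouping = NULL) {
  fate <- if (is.data.frame(calls)) calls$fate else as.character(calls)
  n <- length(fate)
  if (n == 0) stop("no cells")
  if (is.null(grouping)) grouping <- assign_groups(n)
  if (length(grouping) != n) stop("grouping must match the number of cells")
  groups <- split(fate, grouping)
  if (any(lengths(groups) == 0)) stop("empty group")
  frac <- t(vapply(groups, function(f) {
    c(dead = mean(f == "dead"),
      surviving = mean(f != "dead"),
      arrested = mean(f == "arrested"),
      adapted = mean(f == "adapted"))
  }, numeric(4)))
  structure(list(
    per_group = frac,
    mean = colMeans(frac),
    sd = apply(frac, 2, stats::sd),
    group_sizes = lengths(groups)
  ), class = "fate_summary")
}

#' @export
print.fate_summary <- function(x, ...) {
  cat("Fate fractions over", nrow(x$per_group), "groups (mean +/- SD):\n")
  for (cl in colnames(x$per_group)) {
    cat(sprintf("  %-9s %5.1f%% +/- %4.1f%%\n", cl,
                100 * x$mean[cl], 100 * x$sd[cl]))
  }
  invisible(x)
}

#' Percentage of cells dividing within time intervals
#'
#' A cell counts toward an interval if at least one of its divisions falls in
#' `[start, end)`. Percentages are computed per group and reported as
#' across-group mean +/- SD.
#'
#' @param events List of [event_record()]s.
#' @param intervals List (or 2-column matrix) of `(start_h, end_h)` pairs;
#'   must be non-overlapping.
#' @param grouping Optional group labels; round-robin by default.
#' @return data.frame (`start_h`, `end_h`, `mean_pct`, `sd_pct`).
#' @export
division_events_per_interval <- function(events, intervals, grouping = NULL) {
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  iv <- do.call(rbind, lapply(intervals, as.numeric))
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)] - 1e-12))
    stop("overlapping intervals")
  n <- length(events)
  if (is.null(grouping)) grouping <- assign_groups(n)
  out <- vector("list", nrow(iv))
  for (r in seq_len(nrow(iv))) {
    hit <- vapply(events, function(e) {
      any(e$divisions >= iv[r, 1] & e$divisions < iv[r, 2])
    }, logical(1))
    per_group <- vapply(split(hit, grouping), mean, numeric(1)) * 100
    out[[r]] <- data.frame(start_h = iv[r, 1], end_h = iv[r, 2],
                           mean_pct = mean(per_group),
                           sd_pct = stats::sd(per_group))
  }
  do.call(rbind, out)
}

#' Live-cell growth curve from a trace panel or count table
#'
#' Live-cell count per time point (dead cells excluded), normalized to the
#' count at `t = 0`, sampled every `interval_min` minutes.
#'
#' @param x A `trace_panel`, or a data.frame with `time_h` and `count`
#'   columns (replicates averaged if a `replicate` column is present).
#' @param interval_min Sampling cadence of the output grid (minutes).
#' @return Object of class `growth_curve`: data.frame (`time_h`, `count`,
#'   `normalized`).
#' @export
growth_curve <- function(x, interval_min = 45) {
  if (inherits(x, "trace_panel")) {
    end <- max(vapply(x$traces, function(tr) tr$times[length(tr$times)],
                      numeric(1)))
    grid <- seq(0, end, by = interval_min / 60)
    count <- vapply(grid, function(t) {
      sum(vapply(x$traces, function(tr) {
        i <- findInterval(t + 1e-9, tr$times)
        i >= 1 && i <= length(tr$times) && tr$alive[i] &&
          t <= tr$times[length(tr$times)] + 1e-9
      }, logical(1)))
    }, numeric(1))
    curve <- data.frame(time_h = grid, count = count)
  } else {
    stopifnot(all(c("time_h", "count") %in% names(x)))
    curve <- stats::aggregate(count ~ time_h, data = x, FUN = mean)
  }
  if (nrow(curve) == 0) stop("empty input")
  curve <- curve[order(curve$time_h), ]
  if (any(curve$count < 0)) stop("counts must be >= 0")
  curve$normalized <- curve$count / curve$count[1]
  structure(curve, class = c("growth_curve", "data.frame"))
}

#' Doubling time from a log-linear fit of a growth curve
#'
#' Least-squares fit of `log(count)` against time inside `fit_window`;
#' doubling time is `log(2) / slope`. Non-positive slopes return `Inf` with a
#' `no_growth` flag.
#'
#' @param curve A [growth_curve()] or data.frame with `time_h`, `count`.
#' @param fit_window Length-2 numeric `(start_h, end_h)`.
#' @return Doubling time in hours, with attributes `slope_per_h` and
#'   `no_growth`.
#' @export
doubling_time_from_counts <- function(curve, fit_window) {
  d <- curve[curve$time_h >= fit_window[1] & curve$time_h <= fit_window[2], ]
  if (nrow(d) < 3) stop("need at least 3 points in the fit window")
  if (any(d$count <= 0)) stop("all counts in the fit window must be > 0")
  fit <- stats::lm(log(d$count) ~ d$time_h)
  k <- unname(stats::coef(fit)[2])
  if (k <= 1e-10) {  # non-positive up to numeric noise on exact-flat input
    return(structure(Inf, slope_per_h = k, no_growth = TRUE))
  }
  structure(log(2) / k, slope_per_h = k, no_growth = FALSE)
}
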