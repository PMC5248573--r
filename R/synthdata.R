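# Seeded synthetic-data generators. Every generator takes an explicit seed,
# records it (with the preset) in a `meta` attribute, and is bit-reproducible.
# Event times are snapped to the imaging grid so that noiseless traces are
# exactly reconstructible from their event schedules.

GEMININ_AMP <- 10  # waveform amplitude, arbitrary intensity units

snap_to_grid <- function(t, dt) round(t / dt) * dt

#' Construct a single-cell geminin trace
#'
#' @param cell_id Identifier.
#' @param times Hours, uniform strictly increasing grid.
#' @param geminin Intensity series (same length as `times`).
#' @param alive Logical series, monotone non-increasing (no resurrection).
#' @param annotated_events Optional data.frame with columns `time`, `kind`
#'   (`"division"` or `"death"`).
#' @param schedule Optional generator schedule (used as ground-truth oracle).
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, times, geminin, alive = rep(TRUE, length(times)),
                       annotated_events = NULL, schedule = NULL) {
  n <- length(times)
  if (n < 1) stop("empty trace")
  if (length(geminin) != n || length(alive) != n)
    stop("times, geminin, alive must have equal length")
  if (n > 1) {
    steps <- diff(times)
    if (any(steps <= 0) || diff(range(steps)) > 1e-8)
      stop("times must be strictly increasing with constant step")
  }
  if (any(diff(alive) > 0)) stop("alive must be monotone non-increasing")
  structure(list(cell_id = cell_id, times = times, geminin = geminin,
                 alive = alive, annotated_events = annotated_events,
                 schedule = schedule),
            class = "cell_trace")
}

# draw a death time within [lo, hi]; lognormal mode at the window midpoint
draw_death_time <- function(window, dist) {
  lo <- window[1]; hi <- window[2]
  if (dist == "uniform") return(stats::runif(1, lo, hi))
  sdlog <- 0.18
  mode <- (lo + hi) / 2
  meanlog <- log(mode) + sdlog^2
  for (i in 1:200) {
    t <- stats::rlnorm(1, meanlog, sdlog)
    if (t >= lo && t <= hi) return(t)
  }
  stats::runif(1, lo, hi)  # numerically degenerate window: fall back
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# Piecewise-linear geminin waveform: zero in G0/G1, linear rise over the S/G2
# ramp to GEMININ_AMP, instantaneous drop to zero at division. `ramps` is a
# data.frame(start, end); `end` is the division time (signal is zero at `end`).
geminin_from_ramps <- function(times, ramps, s_g2) {
  g <- numeric(length(times))
  if (is.null(ramps) || nrow(ramps) == 0) return(g)
  for (i in seq_len(nrow(ramps))) {
    idx <- times >= ramps$start[i] - 1e-9 & times < ramps$end[i] - 1e-9
    g[idx] <- GEMININ_AMP * (times[idx] - ramps$start[i]) / s_g2
  }
  g
}

# Build one cell's event schedule under the fate-mixture model.
# Returns list(ramps, divisions, onsets, death, censored_at, reentry).
build_schedule <- function(fate, params, dt) {
  movie <- params$movie_length_h
  s_g2 <- params$s_g2_duration_h
  ramps <- data.frame(start = numeric(0), end = numeric(0))
  divisions <- numeric(0)
  death <- NA_real_
  reentry <- NA_real_

  # cells in S/G2 when drug is added (or at movie start) finish that cycle;
  # a division inside the first hour happens in the pre-imaging gap between
  # dosing and acquisition start and is not recorded
  age <- stats::runif(1, 0, params$untreated_doubling_h)
  if (age > params$untreated_doubling_h - s_g2) {
    d0 <- snap_to_grid(params$untreated_doubling_h - age, dt)
    if (d0 > 1) {
      ramps <- rbind(ramps, data.frame(start = d0 - s_g2, end = d0))
      divisions <- c(divisions, d0)
    }
  }

  if (fate == "dead") {
    death <- snap_to_grid(
      draw_death_time(params$death_window_h, params$death_time_dist), dt)
    death <- max(death, dt)  # death strictly after movie start
    keep <- divisions < death
    divisions <- divisions[keep]
    ramps <- ramps[ramps$end <= death + 1e-9 | ramps$start < death, , drop = FALSE]
  } else if (fate == "adapted") {
    reentry <- snap_to_grid(stats::runif(1, params$reentry_window_h[1],
                                         params$reentry_window_h[2]), dt)
    d <- snap_to_grid(reentry + s_g2, dt)
    repeat {
      start <- d - s_g2
      if (start >= movie) break
      ramps <- rbind(ramps, data.frame(start = start, end = min(d, movie + dt)))
      if (d <= movie + 1e-9) divisions <- c(divisions, d) else break
      d <- snap_to_grid(d + rlnorm_mean_cv(1, params$intermitotic_mean_h,
                                           params$intermitotic_cv), dt)
    }
  }
  censored_at <- if (is.na(death)) movie else death
  onsets <- pmax(ramps$start, 0)
  list(ramps = ramps, divisions = divisions, onsets = onsets,
       death = death, censored_at = censored_at, reentry = reentry)
}

build_untreated_schedule <- function(params, dt) {
  movie <- params$movie_length_h
  s_g2 <- params$s_g2_duration_h
  D0 <- params$untreated_doubling_h
  ramps <- data.frame(start = numeric(0), end = numeric(0))
  divisions <- numeric(0)
  age <- stats::runif(1, 0, D0)
  d <- snap_to_grid(D0 - age, dt)
  while (d <= 1) {  # divisions in the pre-imaging first hour are not recorded
    d <- snap_to_grid(d + rlnorm_mean_cv(1, D0, params$intermitotic_cv), dt)
  }
  repeat {
    start <- d - s_g2
    if (start >= movie) break
    ramps <- rbind(ramps, data.frame(start = start, end = min(d, movie + dt)))
    if (d <= movie + 1e-9) divisions <- c(divisions, d) else break
    d <- snap_to_grid(d + rlnorm_mean_cv(1, D0, params$intermitotic_cv), dt)
  }
  list(ramps = ramps, divisions = divisions, onsets = pmax(ramps$start, 0),
       death = NA_real_, censored_at = movie, reentry = NA_real_)
}

schedule_to_trace <- function(cell_id, sched, params, annotate = TRUE) {
  dt <- params$sampling_interval_min / 60
  end <- sched$censored_at
  times <- seq(0, snap_to_grid(end, dt) + 1e-9, by = dt)
  g <- geminin_from_ramps(times, sched$ramps, params$s_g2_duration_h)
  if (params$noise_sd > 0) g <- g + stats::rnorm(length(g), 0, params$noise_sd)
  alive <- rep(TRUE, length(times))
  if (!is.na(sched$death)) alive[length(alive)] <- FALSE
  events <- NULL
  if (annotate) {
    events <- data.frame(time = numeric(0), kind = character(0))
    if (length(sched$divisions))
      events <- rbind(events, data.frame(time = sched$divisions,
                                         kind = "division"))
    if (!is.na(sched$death))
      events <- rbind(events, data.frame(time = sched$death, kind = "death"))
    events <- events[order(events$time), , drop = FALSE]
  }
  cell_trace(cell_id, times, g, alive, annotated_events = events,
             schedule = sched)
}

panel_meta <- function(params, seed, extra = list()) {
  c(list(preset = attr(params, "preset"),
         params = unclass(params), seed = seed), extra)
}

#' Simulate a drug-treated fate cohort of geminin traces
#'
#' Each cell draws a fate from `(p_death, p_arrest, p_adapt)`. Dead cells carry
#' a death time inside `death_window_h` (truncated lognormal by default) and a
#' trace truncated at death; arrested cells emit near-zero geminin throughout;
#' adapted cells stay arrested until a re-entry time drawn uniformly in
#' `reentry_window_h`, then cycle with lognormal inter-division times
#' (mean `intermitotic_mean_h`, CV `intermitotic_cv`), the geminin signal
#' rising linearly over the final `s_g2_duration_h` hours of each cycle and
#' dropping sharply at division. Cells that happen to be in S/G2 at drug
#' addition finish that cycle first. Gaussian noise of SD `noise_sd` is added
#' pointwise. Event times are snapped to the imaging grid.
#'
#' @param params A [fate_model_params()] object (see [fate_preset()]).
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; a fixed seed gives a bit-identical panel.
#' @param annotate Attach ground-truth division/death annotations to traces.
#' @return An object of class `trace_panel`: list of `cell_trace` plus a
#'   `truth` data.frame (`cell_id`, `fate`, `death_h`, `reentry_h`,
#'   `n_divisions`) and a `meta` attribute recording preset and seed.
#' @export
simulate_fate_cohort <- function(params, n_cells, seed, annotate = TRUE) {
  stopifnot(inherits(params, "fate_model_params"), n_cells >= 1)
  if (params$p_death > 0 && params$movie_length_h < params$death_window_h[1])
    stop("movie shorter than the death window")
  set.seed(seed)
  dt <- params$sampling_interval_min / 60
  fates <- sample(c("dead", "arrested", "adapted"), n_cells, replace = TRUE,
                  prob = c(params$p_death, params$p_arrest, params$p_adapt))
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sched <- build_schedule(fates[i], params, dt)
    id <- sprintf("cell%04d", i)
    traces[[i]] <- schedule_to_trace(id, sched, params, annotate)
    truth[[i]] <- data.frame(cell_id = id, fate = fates[i],
                             death_h = sched$death, reentry_h = sched$reentry,
                             n_divisions = length(sched$divisions))
  }
  structure(list(traces = traces, truth = do.call(rbind, truth)),
            class = "trace_panel",
            meta = panel_meta(params, seed, list(kind = "fate_cohort")))
}

#' Simulate an untreated (DMSO) cycling cohort
#'
#' All cells cycle continuously with lognormal inter-division times of mean
#' `untreated_doubling_h`; no deaths occur. Cells start at a uniformly random
#' phase of the cycle.
#'
#' @inheritParams simulate_fate_cohort
#' @return A `trace_panel` (see [simulate_fate_cohort()]); `truth$fate` is
#'   `"cycling"` for every cell.
#' @export
simulate_untreated_cohort <- function(params, n_cells, seed, annotate = TRUE) {
  stopifnot(inherits(params, "fate_model_params"), n_cells >= 1)
  set.seed(seed)
  dt <- params$sampling_interval_min / 60
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sched <- build_untreated_schedule(params, dt)
    id <- sprintf("cell%04d", i)
    traces[[i]] <- schedule_to_trace(id, sched, params, annotate)
    truth[[i]] <- data.frame(cell_id = id, fate = "cycling",
                             death_h = NA_real_, reentry_h = NA_real_,
                             n_divisions = length(sched$divisions))
  }
  structure(list(traces = traces, truth = do.call(rbind, truth)),
            class = "trace_panel",
            meta = panel_meta(params, seed, list(kind = "untreated_cohort")))
}

# bell-shaped (log10 dose) protection factor from a pre-treatment dose
protection_factor <- function(preset, pretreat_dose) {
  if (is.null(pretreat_dose) || length(pretreat_dose) == 0) return(1)
  ifelse(pretreat_dose <= 0, 1,
         1 + (preset$protection_amp - 1) *
           exp(-(log10(pretreat_dose / preset$protection_peak_uM))^2 /
                 (2 * preset$protection_width_log10^2)))
}

hill_survival <- function(dose, emax, ec50, hill) {
  ifelse(dose <= 0, 1, emax + (1 - emax) / (1 + (dose / ec50)^hill))
}

#' Simulate an endpoint viability/apoptosis plate
#'
#' Expected viable counts per well follow a descending Hill curve between
#' untreated outgrowth (`initial_count * 2^control_doublings`) and the
#' residual fraction `true_emax`. A non-null `pretreat_dose` multiplies
#' survival by the bell-shaped protection factor (capped at the untreated
#' count), emulating adaptive protection from a sub-IC50 first bolus.
#' Replicate noise is multiplicative lognormal with CV `replicate_cv`.
#'
#' @param preset A [plate_preset()].
#' @param pretreat_dose Pre-treatment dose in uM, or `NULL` for none.
#' @param seed Integer seed.
#' @return A data.frame (`well`, `dose`, `pretreat_dose`, `total_cells`,
#'   `viable_count`, `apoptotic_count`) with a `meta` attribute.
#' @export
simulate_endpoint_plate <- function(preset, pretreat_dose = NULL, seed) {
  stopifnot(inherits(preset, "plate_preset"))
  if (!is.null(pretreat_dose) && pretreat_dose < 0) stop("negative dose")
  set.seed(seed)
  prot <- protection_factor(preset, pretreat_dose)
  # adaptation shifts the curve parameters: residual survival at saturating
  # dose rises by the protection factor and the transition becomes shallower
  emax_eff <- min(1, preset$true_emax * prot)
  hill_eff <- preset$true_hill / (1 + (prot - 1) / 2)
  n_ctrl <- preset$initial_count * 2^preset$control_doublings
  rows <- expand.grid(replicate = seq_len(preset$n_replicates),
                      dose = preset$doses)
  surv <- hill_survival(rows$dose, emax_eff, preset$true_ec50, hill_eff)
  noise <- exp(stats::rnorm(nrow(rows), 0, preset$replicate_cv))
  viable <- round(n_ctrl * surv * noise)
  bg <- preset$apoptosis_background
  apop_frac <- bg + (1 - bg) * (1 - surv)
  apop <- round(preset$initial_count * apop_frac *
                  exp(stats::rnorm(nrow(rows), 0, preset$replicate_cv)))
  out <- data.frame(
    well = sprintf("W%03d", seq_len(nrow(rows))),
    dose = rows$dose,
    pretreat_dose = if (is.null(pretreat_dose)) 0 else pretreat_dose,
    total_cells = viable + apop,
    viable_count = viable,
    apoptotic_count = apop
  )
  attr(out, "meta") <- list(preset = unclass(preset), seed = seed,
                            pretreat_dose = pretreat_dose,
                            kind = "endpoint_plate")
  out
}

#' Simulate a two-stage (sequential dosing) plate
#'
#' One arm per pre-treatment dose (0 = DMSO control arm), all receiving the
#' same second bolus. Surviving counts scale with the protection factor of the
#' pre-treatment dose, so the fold-change versus the DMSO arm peaks at the
#' protection peak (2.5-fold at 0.1 uM under the `colo858_seq` preset).
#'
#' @param preset A [plate_preset()].
#' @param pretreat_doses Pre-treatment doses in uM; must include 0.
#' @param second_dose Second-stage dose in uM.
#' @param seed Integer seed.
#' @return A data.frame (`well`, `pretreat_dose`, `second_dose`,
#'   `viable_count`, `apoptotic_count`, `total_cells`).
#' @export
simulate_sequential_plate <- function(preset,
                                      pretreat_doses = c(0, 0.01, 0.032, 0.1,
                                                         0.32, 1),
                                      second_dose = 1, seed) {
  stopifnot(inherits(preset, "plate_preset"))
  if (any(pretreat_doses < 0) || second_dose < 0) stop("negative dose")
  if (!any(pretreat_doses == 0)) stop("a DMSO (0) pre-treatment arm is required")
  set.seed(seed)
  n_ctrl <- preset$initial_count * 2^preset$control_doublings
  rows <- expand.grid(replicate = seq_len(preset$n_replicates),
                      pretreat_dose = pretreat_doses)
  base_surv <- hill_survival(second_dose + rows$pretreat_dose,
                             preset$true_emax, preset$true_ec50,
                             preset$true_hill)
  prot <- protection_factor(preset, rows$pretreat_dose)
  if (preset$protection_amp > 1) {
    # protection_amp is the target peak fold-change in surviving cells; the
    # extra Hill attenuation from the pre-treatment dose itself is compensated
    # so the realized peak ratio equals protection_amp.
    comp <- hill_survival(second_dose, preset$true_emax, preset$true_ec50,
                          preset$true_hill) /
      hill_survival(second_dose + preset$protection_peak_uM,
                    preset$true_emax, preset$true_ec50, preset$true_hill)
    prot <- 1 + (prot - 1) * (preset$protection_amp * comp - 1) /
      (preset$protection_amp - 1)
  }
  surv <- pmin(1, base_surv * prot)
  noise <- exp(stats::rnorm(nrow(rows), 0, preset$replicate_cv))
  viable <- round(n_ctrl * surv * noise)
  bg <- preset$apoptosis_background
  apop <- round(preset$initial_count * (bg + (1 - bg) * (1 - surv)) *
                  exp(stats::rnorm(nrow(rows), 0, preset$replicate_cv)))
  out <- data.frame(
    well = sprintf("W%03d", seq_len(nrow(rows))),
    pretreat_dose = rows$pretreat_dose,
    second_dose = second_dose,
    viable_count = viable,
    apoptotic_count = apop,
    total_cells = viable + apop
  )
  attr(out, "meta") <- list(preset = unclass(preset), seed = seed,
                            second_dose = second_dose,
                            kind = "sequential_plate")
  out
}

#' Simulate per-cell apoptosis spot records for one well
#'
#' Per-cell NucView-style spot intensities and nucleus areas: apoptotic cells
#' have intensity/area ratios well above non-apoptotic cells, so a separating
#' threshold on intensity/area recovers the planted apoptotic set.
#'
#' @param n_cells Cells in the well. @param frac_apoptotic Planted fraction.
#' @param seed Integer seed.
#' @return data.frame (`cell`, `spot_intensity`, `nucleus_area`,
#'   `is_apoptotic`).
#' @export
simulate_well_cells <- function(n_cells = 500, frac_apoptotic = 0.2, seed) {
  set.seed(seed)
  apo <- stats::runif(n_cells) < frac_apoptotic
  area <- stats::rlnorm(n_cells, log(80), 0.2)
  ratio <- ifelse(apo, stats::rlnorm(n_cells, log(8), 0.3),
                  stats::rlnorm(n_cells, log(0.5), 0.4))
  data.frame(cell = seq_len(n_cells), spot_intensity = ratio * area,
             nucleus_area = area, is_apoptotic = apo)
}

#' Simulate replicate exponential growth trajectories
#'
#' Count trajectories for outgrowth assays: `n0 * 2^(t / doubling_h)` with
#' multiplicative lognormal noise of CV `cv` at each sampled time.
#'
#' @param doubling_h True doubling time (h), or a [pool_preset()].
#' @param times_h Sampling times (h).
#' @param n_replicates Replicate trajectories.
#' @param cv Multiplicative noise CV.
#' @param n0 Initial count.
#' @param seed Integer seed.
#' @return data.frame (`replicate`, `time_h`, `count`).
#' @export
simulate_growth_trajectories <- function(doubling_h, times_h = seq(48, 120, 12),
                                         n_replicates = 4, cv = 0.05,
                                         n0 = 1000, seed) {
  if (inherits(doubling_h, "pool_preset")) {
    n0 <- doubling_h$initial_count
    doubling_h <- doubling_h$doubling_h
  }
  set.seed(seed)
  out <- expand.grid(time_h = times_h, replicate = seq_len(n_replicates))
  sdlog <- sqrt(log(1 + cv^2))
  out$count <- n0 * 2^(out$time_h / doubling_h) *
    stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog)
  out[, c("replicate", "time_h", "count")]
}

#' Simulate a two-line, three-condition expression table
#'
#' Gene-level FPKM and q-values for lines A and B under DMSO and drug at 24
#' and 48 h. Planted up/down genes carry an A:B fold-change ratio of
#' `2^(+/- planted_log2ratio)` with `q = q_signal` in line A; null genes have
#' log2 ratios drawn from `N(0, dispersion)` and q-values uniform on
#' `[q_null, 1]`.
#'
#' @param preset An [expression_preset()].
#' @param seed Integer seed.
#' @return data.frame (`gene`, `line`, `condition`, `fpkm`, `q`) with a
#'   `planted` attribute (data.frame `gene`, `direction`).
#' @export
simulate_expression_table <- function(preset, seed) {
  stopifnot(inherits(preset, "expression_preset"))
  set.seed(seed)
  n <- preset$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  direction <- rep("null", n)
  if (preset$n_planted_up > 0)
    direction[seq_len(preset$n_planted_up)] <- "up"
  if (preset$n_planted_down > 0)
    direction[preset$n_planted_up + seq_len(preset$n_planted_down)] <- "down"
  baseline <- pmax(preset$fpkm_floor, stats::rlnorm(n, log(20), 1))
  # planted differential genes are drawn from the well-expressed range so the
  # selection contract exercises the rule logic, not detectability limits
  # (stabilized fold-changes of near-floor genes shrink toward 1)
  baseline[direction != "null"] <- pmax(baseline[direction != "null"], 10)
  # per-line log2 fold changes; the planted A:B ratio is concentrated in A
  null_ratio <- stats::rnorm(n, 0, preset$dispersion)
  l2fc_a <- ifelse(direction == "up", preset$planted_log2ratio,
                   ifelse(direction == "down", -preset$planted_log2ratio,
                          null_ratio / 2))
  l2fc_b <- ifelse(direction == "null", -null_ratio / 2, 0)
  q_a <- ifelse(direction == "null", stats::runif(n, preset$q_null, 1),
                preset$q_signal)
  q_b <- stats::runif(n, preset$q_null, 1)
  conditions <- c("DMSO", "drug24h", "drug48h")
  build_line <- function(line, l2fc, q) {
    do.call(rbind, lapply(conditions, function(cond) {
      fc <- if (cond == "DMSO") 1 else 2^l2fc
      data.frame(gene = genes, line = line, condition = cond,
                 fpkm = baseline * fc,
                 q = if (cond == "DMSO") 1 else q)
    }))
  }
  out <- rbind(build_line("A", l2fc_a, q_a), build_line("B", l2fc_b, q_b))
  rownames(out) <- NULL
  attr(out, "planted") <- data.frame(gene = genes,
                                     direction = direction)[direction != "null", ]
  attr(out, "meta") <- list(preset = unclass(preset), seed = seed,
                            kind = "expression_table")
  out
}

#' Simulate a chromatin-compound screen plate
#'
#' NGFR readouts (log2 scale) per compound x dose x line x replicate. Planted
#' suppressors reduce the mean readout by `suppression_log2` in every line;
#' all other compounds are centred on the line baseline. Line baselines
#' differ, so hit selection must z-score within line.
#'
#' @param preset A [screen_preset()].
#' @param seed Integer seed.
#' @return data.frame (`compound`, `dose_uM`, `line`, `replicate`, `ngfr`)
#'   with a `suppressors` attribute.
#' @export
simulate_screen <- function(preset, seed) {
  stopifnot(inherits(preset, "screen_preset"))
  set.seed(seed)
  ids <- sprintf("cmpd%02d", seq_len(preset$n_compounds))
  lines <- sprintf("line%d", seq_len(preset$n_lines))
  base <- stats::setNames(seq_along(lines) * 0.7, lines)
  grid <- expand.grid(replicate = seq_len(preset$n_replicates),
                      dose_uM = preset$doses_uM, compound = ids,
                      line = lines, stringsAsFactors = FALSE)
  eff <- ifelse(grid$compound %in% preset$suppressor_ids,
                -preset$suppression_log2, 0)
  grid$ngfr <- base[grid$line] + eff +
    stats::rnorm(nrow(grid), 0, preset$noise_sd)
  out <- grid[, c("compound", "dose_uM", "line", "replicate", "ngfr")]
  attr(out, "suppressors") <- preset$suppressor_ids
  attr(out, "meta") <- list(preset = unclass(preset), seed = seed,
                            kind = "screen_plate")
  out
}

#' Simulate a biopsy-like per-cell marker table
#'
#' Log-intensities of NGFR and Ki-67 per cell from a two-component normal
#' mixture (separation `high_low_separation`, within-component SD
#' `within_sd`), with a `background_frac` subpopulation flagged as lying in
#' high-background tissue regions: their marker and pre-stain intensities are
#' inflated by `background_boost`.
#'
#' @param preset A [biopsy_preset()] (see [biopsy_preset_named()]).
#' @param seed Integer seed.
#' @return data.frame (`cell`, `ngfr`, `ki67`, `prestain`,
#'   `is_background_region`); log-intensity units. The suggested background
#'   threshold (`background_boost / 2`) is attached as attribute
#'   `bg_threshold`.
#' @export
simulate_biopsy_table <- function(preset, seed) {
  stopifnot(inherits(preset, "biopsy_preset"))
  set.seed(seed)
  n <- preset$n_cells
  draw_marker <- function(frac_high) {
    hi <- stats::runif(n) < frac_high
    stats::rnorm(n, ifelse(hi, preset$high_low_separation, 0),
                 preset$within_sd)
  }
  ngfr <- draw_marker(preset$frac_ngfr_high)
  ki67 <- draw_marker(preset$frac_ki67_high)
  bg <- stats::runif(n) < preset$background_frac
  ngfr[bg] <- ngfr[bg] + preset$background_boost
  ki67[bg] <- ki67[bg] + preset$background_boost
  prestain <- stats::rnorm(n, ifelse(bg, preset$background_boost, 0), 0.2)
  out <- data.frame(cell = seq_len(n), ngfr = ngfr, ki67 = ki67,
                    prestain = prestain, is_background_region = bg)
  attr(out, "bg_threshold") <- preset$background_boost / 2
  attr(out, "meta") <- list(preset = unclass(preset), seed = seed,
                            kind = "biopsy_table")
  out
}
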