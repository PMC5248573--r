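# Preset objects describing the generative "stated world" of each assay.
# All constructors validate their invariants and return plain lists with a
# class tag, so presets can be serialized to JSON sidecars verbatim.

#' Generative parameters for a single-cell fate cohort
#'
#' Parameter set for the three-fate mixture model (apoptosis / G0-G1 arrest /
#' adaptive re-entry into slow cycling) used by [simulate_fate_cohort()] and
#' [simulate_untreated_cohort()]. Defaults correspond to COLO858 cells treated
#' with 1 uM vemurafenib: ~60% of cells die (concentrated between 24 and 48 h),
#' ~20% stay arrested, ~20% re-enter S phase between 48 and 84 h and then
#' divide roughly every 65 h, versus a ~24 h doubling time without drug.
#'
#' @param p_death,p_arrest,p_adapt Fate probabilities; must sum to 1.
#' @param death_window_h Length-2 numeric, (lo, hi) hours bounding death times.
#' @param reentry_window_h Length-2 numeric, (lo, hi) hours bounding the first
#'   S-phase re-entry of adapted cells.
#' @param intermitotic_mean_h Mean inter-division time of adapted cells (h).
#' @param intermitotic_cv Coefficient of variation of inter-division times.
#' @param s_g2_duration_h Duration of the S/G2 geminin ramp (h).
#' @param untreated_doubling_h Mean inter-division time without drug (h).
#' @param noise_sd Pointwise Gaussian noise added to the geminin signal, in the
#'   same arbitrary units as the waveform (amplitude 10).
#' @param sampling_interval_min Imaging cadence in minutes (6 min frames).
#' @param movie_length_h Total tracked time (h).
#' @param death_time_dist `"lognormal"` (truncated within `death_window_h`,
#'   mode near 36 h) or `"uniform"` over the window.
#' @return An object of class `fate_model_params`.
#' @export
fate_model_params <- function(p_death = 0.60, p_arrest = 0.20, p_adapt = 0.20,
                              death_window_h = c(24, 48),
                              reentry_window_h = c(48, 84),
                              intermitotic_mean_h = 65,
                              intermitotic_cv = 0.15,
                              s_g2_duration_h = 10,
                              untreated_doubling_h = 24,
                              noise_sd = 0.5,
                              sampling_interval_min = 6,
                              movie_length_h = 84,
                              death_time_dist = c("lognormal", "uniform")) {
  death_time_dist <- match.arg(death_time_dist)
  p <- c(p_death, p_arrest, p_adapt)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("fate probabilities must be non-negative and sum to 1")
  durs <- c(intermitotic_mean_h, s_g2_duration_h, untreated_doubling_h,
            sampling_interval_min, movie_length_h)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (intermitotic_cv < 0) stop("intermitotic_cv must be >= 0")
  check_window <- function(w, name) {
    if (length(w) != 2 || w[1] >= w[2] || w[2] > movie_length_h + 1e-9) {
      # windows must fit the movie only when the corresponding fate can occur
      stop(sprintf("%s must satisfy lo < hi <= movie_length_h", name))
    }
  }
  if (p_death > 0) check_window(death_window_h, "death_window_h")
  if (p_adapt > 0 && (length(reentry_window_h) != 2 ||
                      reentry_window_h[1] >= reentry_window_h[2]))
    stop("reentry_window_h must satisfy lo < hi")
  structure(list(
    p_death = p_death, p_arrest = p_arrest, p_adapt = p_adapt,
    death_window_h = death_window_h, reentry_window_h = reentry_window_h,
    intermitotic_mean_h = intermitotic_mean_h,
    intermitotic_cv = intermitotic_cv,
    s_g2_duration_h = s_g2_duration_h,
    untreated_doubling_h = untreated_doubling_h,
    noise_sd = noise_sd,
    sampling_interval_min = sampling_interval_min,
    movie_length_h = movie_length_h,
    death_time_dist = death_time_dist
  ), class = "fate_model_params")
}

#' Named fate-model presets
#'
#' Returns the stated-world parameter set for a named experimental condition:
#' * `"colo858_vem"`: 1 uM vemurafenib on COLO858; 60/20/20 dead/arrested/
#'   adapted, deaths in 24-48 h, re-entry in 48-84 h, ~65 h inter-division
#'   time, S/G2 phase-calling threshold 2.0.
#' * `"mmacsf_vem"`: 1 uM vemurafenib on MMACSF; ~40% apoptosis in 24-48 h,
#'   the rest arrest, no adapted subpopulation, threshold 1.5.
#' * `"colo858_dmso"`: untreated COLO858; all cells cycle with ~24 h doubling.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [fate_model_params()] (e.g. `movie_length_h`).
#' @return A `fate_model_params` object with a `geminin_threshold` attribute
#'   giving the line-specific S/G2 calling threshold.
#' @export
fate_preset <- function(name = c("colo858_vem", "mmacsf_vem", "colo858_dmso"),
                        ...) {
  name <- match.arg(name)
  params <- switch(name,
    colo858_vem = fate_model_params(...),
    mmacsf_vem = fate_model_params(p_death = 0.40, p_arrest = 0.60,
                                   p_adapt = 0.0, ...),
    colo858_dmso = fate_model_params(p_death = 0, p_arrest = 0, p_adapt = 1,
                                     reentry_window_h = c(0, 1e-6), ...)
  )
  attr(params, "preset") <- name
  attr(params, "geminin_threshold") <- if (name == "mmacsf_vem") 1.5 else 2.0
  params
}

#' Endpoint-plate generative preset
#'
#' Parameterizes the 72 h viability/apoptosis endpoint assay: cell counts per
#' well follow a descending Hill curve between untreated outgrowth and the
#' residual fraction `true_emax`, with multiplicative replicate noise. The
#' `protection_*` fields describe the adaptive protection conferred by a
#' sub-IC50 pre-treatment: a bell-shaped (in log10 dose) multiplicative
#' survival factor peaking at `protection_peak_uM` with maximal fold-change
#' `protection_amp`. `protection_amp = 1` disables adaptation (MMACSF-like).
#'
#' @param doses Treatment doses in uM, non-negative, sorted ascending.
#' @param true_ec50 uM. @param true_hill Hill slope (positive).
#' @param true_emax Residual viable fraction at saturating dose, in `[0, 1]`.
#' @param initial_count Seeded cells per well.
#' @param control_doublings Population doublings of the untreated control over
#'   the assay.
#' @param apoptosis_background Apoptotic fraction in untreated wells.
#' @param replicate_cv CV of multiplicative well-to-well noise.
#' @param n_replicates Wells per dose.
#' @param protection_amp,protection_peak_uM,protection_width_log10 Adaptation
#'   rule parameters (see above).
#' @return An object of class `plate_preset`.
#' @export
plate_preset <- function(doses = c(0, 0.01, 0.032, 0.1, 0.32, 1, 3.2),
                         true_ec50 = 0.3, true_hill = 2, true_emax = 0.1,
                         initial_count = 2500, control_doublings = 3,
                         apoptosis_background = 0.05, replicate_cv = 0.05,
                         n_replicates = 4,
                         protection_amp = 2.5, protection_peak_uM = 0.1,
                         protection_width_log10 = 0.5) {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (is.unsorted(doses)) stop("doses must be sorted ascending")
  if (true_emax < 0 || true_emax > 1) stop("true_emax must be in [0, 1]")
  if (initial_count <= 0) stop("initial_count must be > 0")
  if (protection_amp < 1) stop("protection_amp must be >= 1")
  structure(list(
    doses = doses, true_ec50 = true_ec50, true_hill = true_hill,
    true_emax = true_emax, initial_count = initial_count,
    control_doublings = control_doublings,
    apoptosis_background = apoptosis_background,
    replicate_cv = replicate_cv, n_replicates = n_replicates,
    protection_amp = protection_amp,
    protection_peak_uM = protection_peak_uM,
    protection_width_log10 = protection_width_log10
  ), class = "plate_preset")
}

#' Named plate presets
#'
#' `"colo858_seq"` carries the adaptive protection term calibrated so that
#' 0.1 uM pre-treatment yields a maximal 2.5-fold increase in surviving cells;
#' `"mmacsf_seq"` has no protection (viability falls monotonically with total
#' dose).
#' @param name Preset name. @param ... Overrides for [plate_preset()].
#' @export
plate_preset_named <- function(name = c("colo858_seq", "mmacsf_seq"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    colo858_seq = plate_preset(...),
    mmacsf_seq = plate_preset(protection_amp = 1, ...)
  )
  attr(preset, "preset") <- name
  preset
}

#' Two-line expression-table preset
#'
#' Emulates a Cuffdiff-style gene table for two cell lines (A = adapting,
#' B = non-adapting) across DMSO / 24 h / 48 h drug conditions, with planted
#' differential genes whose cross-line fold-change ratio exceeds
#' `planted_log2ratio` and whose q-values are significant in line A.
#'
#' @param n_genes Total genes. @param n_planted_up,n_planted_down Planted
#'   differential genes (up / down in line A relative to line B).
#' @param planted_log2ratio Planted |log2| of the A:B fold-change ratio.
#' @param fpkm_floor Minimum baseline FPKM of expressed genes.
#' @param q_signal q-value given to planted genes in line A (< 0.01).
#' @param q_null Lower bound of the null q-value range (>= 0.01).
#' @param dispersion SD of null log2 fold-change ratios.
#' @export
expression_preset <- function(n_genes = 1000, n_planted_up = 50,
                              n_planted_down = 50, planted_log2ratio = 2,
                              fpkm_floor = 1, q_signal = 1e-3, q_null = 0.01,
                              dispersion = 0.1) {
  if (n_planted_up + n_planted_down > n_genes)
    stop("planted counts must not exceed n_genes")
  if (!(q_signal < 0.01 && 0.01 <= q_null))
    stop("need q_signal < 0.01 <= q_null")
  structure(list(
    n_genes = n_genes, n_planted_up = n_planted_up,
    n_planted_down = n_planted_down, planted_log2ratio = planted_log2ratio,
    fpkm_floor = fpkm_floor, q_signal = q_signal, q_null = q_null,
    dispersion = dispersion
  ), class = "expression_preset")
}

#' Chromatin-compound screen preset
#'
#' 41 compounds at three doses in two replicates across three cell lines,
#' with `suppressor_ids` lowering the mean NGFR readout by `suppression_log2`
#' in every line (the three BET-inhibitor-like planted hits by default).
#'
#' @param n_compounds,n_doses,n_lines Design size.
#' @param suppressor_ids Character ids of planted suppressors (subset of
#'   `sprintf("cmpd%02d", 1:n_compounds)`).
#' @param suppression_log2 Mean NGFR reduction (log2 units) for suppressors.
#' @param noise_sd SD of per-well noise (log2 units).
#' @param n_replicates Replicates per compound x dose x line.
#' @export
screen_preset <- function(n_compounds = 41, n_doses = 3, n_lines = 3,
                          suppressor_ids = c("cmpd07", "cmpd19", "cmpd33"),
                          suppression_log2 = 1.5, noise_sd = 0.3,
                          n_replicates = 2) {
  if (n_doses < 1) stop("n_doses must be >= 1")
  ids <- sprintf("cmpd%02d", seq_len(n_compounds))
  if (!all(suppressor_ids %in% ids))
    stop("suppressor_ids must be a subset of the compound ids")
  structure(list(
    n_compounds = n_compounds, n_doses = n_doses, n_lines = n_lines,
    doses_uM = c(0.11, 0.53, 2.67)[seq_len(min(n_doses, 3))],
    suppressor_ids = suppressor_ids, suppression_log2 = suppression_log2,
    noise_sd = noise_sd, n_replicates = n_replicates
  ), class = "screen_preset")
}

#' Biopsy-like per-cell marker table preset
#'
#' Two-component log-normal mixture per marker (NGFR, Ki-67) with a planted
#' marker-high fraction, plus a flagged high-background subpopulation whose
#' intensities (and pre-stain signal) are inflated by `background_boost`.
#'
#' @param n_cells Cells in the section.
#' @param frac_ngfr_high,frac_ki67_high Planted marker-high fractions.
#' @param high_low_separation Distance between component means (log units).
#' @param within_sd Within-component SD (log units).
#' @param background_frac Fraction of cells in high-background regions.
#' @param background_boost Log-intensity inflation of background cells.
#' @export
biopsy_preset <- function(n_cells = 10000, frac_ngfr_high = 0.30,
                          frac_ki67_high = 0.04, high_low_separation = 2.5,
                          within_sd = 0.45, background_frac = 0.05,
                          background_boost = 3) {
  fr <- c(frac_ngfr_high, frac_ki67_high, background_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  structure(list(
    n_cells = n_cells, frac_ngfr_high = frac_ngfr_high,
    frac_ki67_high = frac_ki67_high,
    high_low_separation = high_low_separation, within_sd = within_sd,
    background_frac = background_frac, background_boost = background_boost
  ), class = "biopsy_preset")
}

#' Named biopsy presets
#'
#' `"ontreat"` matches the on-treatment biopsy (~30% NGFR-high, ~4% Ki-67-high);
#' `"pretreat"` the pre-treatment biopsy (~7% NGFR-high, ~23% Ki-67-high).
#' @param name Preset name. @param ... Overrides for [biopsy_preset()].
#' @export
biopsy_preset_named <- function(name = c("ontreat", "pretreat"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    ontreat = biopsy_preset(...),
    pretreat = biopsy_preset(frac_ngfr_high = 0.07, frac_ki67_high = 0.23, ...)
  )
  attr(preset, "preset") <- name
  preset
}

#' Sorted-pool outgrowth presets
#'
#' Doubling-time presets for FACS-sorted NGFR-high (~32 h) and NGFR-low
#' (~18 h) pools during days 2-5 of drug-free outgrowth.
#' @param name Pool name.
#' @return List with `doubling_h`, `initial_count`.
#' @export
pool_preset <- function(name = c("ngfr_high_pool", "ngfr_low_pool")) {
  name <- match.arg(name)
  structure(list(
    doubling_h = if (name == "ngfr_high_pool") 32 else 18,
    initial_count = 1000
  ), class = "pool_preset", preset = name)
}
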