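# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops and direct definitions, not the package's
# vectorized code paths.

# centered moving average with symmetric shrinking edge windows, direct loop
oracle_smooth <- function(x, window_frames) {
  n <- length(x)
  k <- floor(window_frames / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(k, i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

# brute-force threshold segmentation: walk the smoothed series frame by frame,
# flipping state only when min_run consecutive frames are on the other side
oracle_segment <- function(times, smoothed, threshold, min_run) {
  above <- smoothed > threshold
  n <- length(above)
  state <- "G0G1"
  bounds <- numeric(0)
  phases <- character(0)
  i <- 1L
  while (i + min_run - 1L <= n) {
    want <- if (state == "G0G1") TRUE else FALSE
    if (all(above[i:(i + min_run - 1L)] == want)) {
      bounds <- c(bounds, times[i])
      phases <- c(phases, state)
      state <- if (state == "G0G1") "SG2" else "G0G1"
    }
    i <- i + 1L
  }
  df <- data.frame(start_h = c(times[1], bounds),
                   end_h = c(bounds, times[n]),
                   phase = c(phases, state))
  df[df$end_h > df$start_h, , drop = FALSE]
}

# rebuild a noiseless geminin waveform from a generator schedule by direct
# per-frame evaluation
oracle_waveform <- function(times, schedule, s_g2, amp = 10) {
  g <- numeric(length(times))
  ramps <- schedule$ramps
  for (t_i in seq_along(times)) {
    t <- times[t_i]
    for (r in seq_len(nrow(ramps))) {
      if (t >= ramps$start[r] - 1e-9 && t < ramps$end[r] - 1e-9) {
        g[t_i] <- amp * (t - ramps$start[r]) / s_g2
      }
    }
  }
  g
}

# per-gene loop implementing the three-rule differential filter directly
oracle_de_filter <- function(table, q_cut = 0.01, fpkm_min = 1,
                             log2ratio_min = 1) {
  conds <- setdiff(unique(table$condition), "DMSO")
  out <- list()
  for (cond in conds) {
    up <- character(0); down <- character(0)
    for (g in unique(table$gene)) {
      row <- function(line, condition, col) {
        table[[col]][table$gene == g & table$line == line &
                       table$condition == condition]
      }
      fa <- (row("A", cond, "fpkm") + 1) / (row("A", "DMSO", "fpkm") + 1)
      fb <- (row("B", cond, "fpkm") + 1) / (row("B", "DMSO", "fpkm") + 1)
      qa <- row("A", cond, "q"); qb <- row("B", cond, "q")
      l2r <- log2(fa / fb)
      elig_a <- qa < q_cut; elig_b <- qb < q_cut
      fpkm_ok <- (elig_a && row("A", cond, "fpkm") >= fpkm_min) ||
        (elig_b && row("B", cond, "fpkm") >= fpkm_min)
      if ((elig_a || elig_b) && fpkm_ok && abs(l2r) >= log2ratio_min) {
        if (l2r > 0) up <- c(up, g) else down <- c(down, g)
      }
    }
    out[[cond]] <- list(up = up, down = down)
  }
  out
}

# random fate-model parameter draw for property tests (noiseless by default)
random_fate_params <- function(noise_sd = 0) {
  movie <- 192
  fate_model_params(
    p_death = 0.3, p_arrest = 0.2, p_adapt = 0.5,
    death_window_h = c(24, 48),
    reentry_window_h = c(48, 84),
    intermitotic_mean_h = runif(1, 40, 80),
    intermitotic_cv = runif(1, 0, 0.2),
    s_g2_duration_h = runif(1, 8, 12),
    untreated_doubling_h = runif(1, 18, 30),
    noise_sd = noise_sd,
    sampling_interval_min = 6,
    movie_length_h = movie
  )
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_true(setequal(a, b),
                        label = paste("sets equal:", paste(sort(a), collapse = ","),
                                      "vs", paste(sort(b), collapse = ",")))
}
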