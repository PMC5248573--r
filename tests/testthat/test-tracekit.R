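# Trace analysis: smoothing conventions, phase calling against a brute-force
# oracle, event detection, minimum doubling time and fate classification.

test_that("smooth_geminin matches the direct-loop oracle and its conventions", {
  set.seed(21)
  x <- rnorm(300)
  for (w in c(1, 5, 40)) {
    expect_equal(smooth_geminin(x, w), oracle_smooth(x, w), tolerance = 1e-12)
  }
  expect_identical(smooth_geminin(x, 1), x)                   # identity
  expect_equal(smooth_geminin(rep(3.2, 100), 40), rep(3.2, 100))  # constants
  # interior unit impulse -> plateau of height 1/(2k+1) spanning the window
  imp <- numeric(200); imp[100] <- 1
  sm <- smooth_geminin(imp, 40)
  expect_equal(sm[80:120], rep(1 / 41, 41), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # interior impulse: mean kept
  expect_error(smooth_geminin(x[1:10], 40), "longer")
})

test_that("smoothing preserves the series mean (exactly for linear edges)", {
  # exact whenever the first/last 2k frames are constant (the usual case:
  # traces start and end in the G0/G1 baseline); otherwise the edge error is
  # bounded by 2k * max|x| / n
  p <- fate_preset("colo858_vem", noise_sd = 0)
  panel <- simulate_fate_cohort(p, 20, seed = 22)
  is_const <- function(x) length(x) < 2 || max(abs(diff(x))) < 1e-9
  n_exact <- 0
  for (tr in panel$traces) {
    sm <- smooth_geminin(tr, 40)
    n <- length(tr$geminin)
    edge_const <- is_const(tr$geminin[1:min(41, n)]) &&
      is_const(tr$geminin[max(1, n - 40):n])
    if (edge_const) {
      expect_equal(mean(sm), mean(tr$geminin), tolerance = 1e-10)
      n_exact <- n_exact + 1
    } else {
      expect_lt(abs(mean(sm) - mean(tr$geminin)), 2 * 20 * 10 / n)
    }
  }
  expect_gt(n_exact, 5)  # the linear-edge case is the common one
  # noisy trace: edge error is bounded by 2k * max|x| / n
  pn <- fate_preset("colo858_vem")
  tr <- simulate_fate_cohort(pn, 1, seed = 23)$traces[[1]]
  bound <- 2 * 20 * max(abs(tr$geminin)) / length(tr$geminin)
  expect_lt(abs(mean(smooth_geminin(tr, 40)) - mean(tr$geminin)), bound)
})

test_that("call_phases matches the brute-force segmentation oracle", {
  p <- fate_preset("colo858_vem", noise_sd = 0, movie_length_h = 192)
  panel <- simulate_fate_cohort(p, 30, seed = 24)
  for (tr in panel$traces) {
    seg <- call_phases(tr, 2.0, 40)
    orc <- oracle_segment(tr$times, oracle_smooth(tr$geminin, 40), 2.0, 5)
    # boundaries agree to one frame (cumsum vs mean() float ties at the
    # threshold on exact ramp values can flip a single comparison)
    expect_identical(nrow(seg$intervals), nrow(orc))
    expect_true(max(abs(seg$intervals$start_h - orc$start_h)) <= 0.1 + 1e-9)
    expect_equal(seg$intervals$phase, orc$phase)
    # contiguity, coverage, alternation
    iv <- seg$intervals
    expect_equal(iv$start_h[-1], iv$end_h[-nrow(iv)])
    expect_equal(iv$start_h[1], tr$times[1])
    expect_equal(iv$end_h[nrow(iv)], tr$times[length(tr$times)])
    if (nrow(iv) > 1) expect_true(all(iv$phase[-1] != iv$phase[-nrow(iv)]))
  }
  # arrested cell: single G0/G1 interval
  flat <- cell_trace("c", seq(0, 84, 0.1), numeric(841))
  seg <- call_phases(flat, 2.0)
  expect_identical(nrow(seg$intervals), 1L)
  expect_identical(seg$intervals$phase, "G0G1")
  # threshold above waveform amplitude: no S/G2 ever
  cyc <- simulate_untreated_cohort(fate_preset("colo858_dmso", noise_sd = 0),
                                   1, seed = 1)$traces[[1]]
  seg2 <- call_phases(cyc, 50)
  expect_false(any(seg2$intervals$phase == "SG2"))
})

test_that("detect_events: annotations take precedence, signal calls are exact noiseless", {
  tms <- seq(0, 84, 0.1)
  tr <- cell_trace("c", tms, numeric(841),
                   annotated_events = data.frame(time = 60, kind = "division"))
  ev <- detect_events(tr)
  expect_equal(ev$divisions, 60)
  # death from the alive series, no division
  tr2 <- cell_trace("c", seq(0, 30, 0.1), numeric(301),
                    alive = c(rep(TRUE, 300), FALSE))
  ev2 <- detect_events(tr2, use_annotations = FALSE)
  expect_equal(ev2$death, 30)
  expect_length(ev2$divisions, 0)
})

test_that("segmentation + event detection reproduce noiseless schedules (100 draws)", {
  set.seed(25)
  n_mismatch <- 0
  for (rep in 1:100) {
    params <- random_fate_params(noise_sd = 0)
    panel <- simulate_fate_cohort(params, 1, seed = 10000 + rep)
    tr <- panel$traces[[1]]
    ev <- detect_events(tr, threshold = 2.0, use_annotations = FALSE)
    sch <- tr$schedule
    div_ok <- isTRUE(all.equal(sort(ev$divisions), sort(sch$divisions),
                               tolerance = 1e-9))
    death_ok <- identical(is.na(ev$death), is.na(sch$death)) &&
      (is.na(sch$death) || abs(ev$death - sch$death) < 1e-9)
    if (!div_ok || !death_ok) n_mismatch <- n_mismatch + 1
  }
  expect_identical(n_mismatch, 0)
})

test_that("phase_lengths sums to lifetime and flags censoring", {
  seg <- structure(list(
    intervals = data.frame(start_h = c(0, 14), end_h = c(14, 24),
                           phase = c("G0G1", "SG2")),
    threshold_used = 2, window_frames = 40, censored = TRUE,
    trace_end_h = 24), class = "phase_segmentation")
  pl <- phase_lengths(seg)
  expect_equal(pl$duration_h, c(14, 10))
  expect_equal(sum(pl$duration_h), 24)
  expect_identical(pl$censored, c(FALSE, TRUE))

  one <- structure(list(
    intervals = data.frame(start_h = 0, end_h = 84, phase = "G0G1"),
    threshold_used = 2, window_frames = 40, censored = TRUE,
    trace_end_h = 84), class = "phase_segmentation")
  pl1 <- phase_lengths(one)
  expect_equal(pl1$duration_h, 84)
  expect_true(pl1$censored)
})

test_that("adapted cells spend extra cycle time in G0/G1, not S/G2", {
  drug <- simulate_fate_cohort(
    fate_preset("colo858_vem", p_death = 0, p_arrest = 0, p_adapt = 1,
                movie_length_h = 192, noise_sd = 0), 25, seed = 26)
  dmso <- simulate_untreated_cohort(
    fate_preset("colo858_dmso", movie_length_h = 192, noise_sd = 0),
    25, seed = 26)
  mean_phase <- function(panel, phase) {
    d <- do.call(rbind, lapply(panel$traces, function(tr) {
      pl <- phase_lengths(call_phases(tr, 2.0))
      pl[!pl$censored & pl$start_h > 0, ]  # complete interior intervals
    }))
    mean(d$duration_h[d$phase == phase])
  }
  expect_gt(mean_phase(drug, "G0G1"), mean_phase(dmso, "G0G1") + 20)
  expect_lt(abs(mean_phase(drug, "SG2") - mean_phase(dmso, "SG2")), 2)
})

test_that("min_doubling_time implements the longest-interval rule", {
  ev1 <- event_record(60, censored_at = 96)
  expect_equal(as.numeric(min_doubling_time(ev1, c(0, 96))), 60)
  ev2 <- event_record(48, censored_at = 96)
  expect_equal(as.numeric(min_doubling_time(ev2, c(0, 96))), 48)
  ev0 <- event_record(numeric(0), censored_at = 96)
  m0 <- min_doubling_time(ev0, c(0, 96))
  expect_equal(as.numeric(m0), 96)
  expect_true(attr(m0, "lower_bound"))
  # k >= 2: inter-division gaps included
  ev3 <- event_record(c(20, 70), censored_at = 100)
  expect_equal(as.numeric(min_doubling_time(ev3, c(0, 100))), 50)
  expect_error(min_doubling_time(ev1, c(50, 50)), "empty")
})

test_that("min_doubling_time is translation invariant and bounded by the window", {
  set.seed(27)
  for (i in 1:50) {
    a <- runif(1, 0, 50); b <- a + runif(1, 10, 100)
    k <- sample(0:4, 1)
    d <- sort(runif(k, a, b))
    ev <- event_record(d, censored_at = b + 10)
    v <- as.numeric(min_doubling_time(ev, c(a, b)))
    expect_lte(v, b - a + 1e-9)
    sh <- 13.7
    ev_s <- event_record(d + sh, censored_at = b + sh + 10)
    expect_equal(as.numeric(min_doubling_time(ev_s, c(a + sh, b + sh))), v,
                 tolerance = 1e-9)
  }
})

test_that("classify_fate applies the dead / adapted / arrested rules", {
  seg0 <- call_phases(cell_trace("c", seq(0, 84, 0.1), numeric(841)), 2.0)
  dead <- event_record(numeric(0), death = 30, censored_at = 30)
  expect_identical(classify_fate(dead, seg0, 84)$fate, "dead")
  none <- event_record(numeric(0), censored_at = 84)
  expect_identical(classify_fate(none, seg0, 84)$fate, "arrested")
  # constructed segmentation with an S/G2 onset at 55 h
  seg55 <- structure(list(
    intervals = data.frame(start_h = c(0, 55), end_h = c(55, 84),
                           phase = c("G0G1", "SG2")),
    threshold_used = 2, window_frames = 40, censored = TRUE,
    trace_end_h = 84), class = "phase_segmentation")
  fc <- classify_fate(none, seg55, 84)
  expect_identical(fc$fate, "adapted")
  expect_equal(fc$support, 55)
})

test_that("cohort classification is >= 99% accurate at 5% noise (detectable cells)", {
  p <- fate_preset("colo858_vem", noise_sd = 0.5)  # 5% of amplitude 10
  panel <- simulate_fate_cohort(p, 400, seed = 28)
  calls <- analyze_traces(panel, use_annotations = FALSE)
  truth <- panel$truth
  # cells whose ground-truth re-entry falls within ~2 h of the movie end carry
  # no threshold-crossing information at any noise level; accuracy is scored
  # on cells whose fate is in principle observable
  observable <- is.na(truth$reentry_h) | truth$reentry_h <= 80
  acc <- mean(calls$fate[observable] == truth$fate[observable])
  expect_gte(acc, 0.99)
})
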