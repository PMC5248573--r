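# Endpoint plate analytics: apoptosis scoring, relative viability, the
# growth-rate-inhibition (GR) metric, Hill dose-response fitting and
# sequential-dosing summaries.

#' Score apoptotic cells from spot intensities
#'
#' A cell is apoptotic iff its caspase-reporter spot intensity divided by its
#' nucleus area exceeds a separating threshold. When `spot_threshold` is
#' `NULL`, an Otsu split of the pooled log intensity/area distribution is
#' used (the field-standard way to place "a separating threshold").
#'
#' @param well data.frame with `spot_intensity` and `nucleus_area` columns.
#' @param spot_threshold Intensity-per-area threshold (> 0), or `NULL` for
#'   Otsu.
#' @return List: `apoptotic` (logical per cell), `fraction`,
#'   `threshold_used`.
#' @export
score_apoptosis <- function(well, spot_threshold = NULL) {
  if (any(well$nucleus_area <= 0)) stop("zero or negative nucleus area")
  ratio <- well$spot_intensity / well$nucleus_area
  if (is.null(spot_threshold)) {
    spot_threshold <- exp(otsu_threshold(log(pmax(ratio, 1e-12))))
  }
  if (spot_threshold <= 0) stop("spot_threshold must be > 0")
  apo <- ratio > spot_threshold
  list(apoptotic = apo, fraction = mean(apo), threshold_used = spot_threshold)
}

#' Relative viability of treated wells
#'
#' Viable count is total minus apoptotic; relative viability is the treated
#' viable count normalized to the mean viable count of the control wells.
#'
#' @param wells Treated wells: data.frame with `total_cells` and
#'   `apoptotic_count`.
#' @param control Control (DMSO) wells, same columns.
#' @return Numeric vector of relative viabilities, one per treated well.
#' @export
relative_viability <- function(wells, control) {
  ctrl_viable <- mean(control$total_cells - control$apoptotic_count)
  if (!is.finite(ctrl_viable) || ctrl_viable <= 0)
    stop("control viable count must be > 0")
  (wells$total_cells - wells$apoptotic_count) / ctrl_viable
}

#' Growth-rate-inhibition (GR) value
#'
#' Normalizes a treated endpoint count to the growth rate of untreated cells:
#' `GR = 2^(log2(x_c / x_0) / log2(x_ctrl / x_0)) - 1`. GR = 1 means no
#' effect, 0 complete cytostasis, negative values net cell loss.
#'
#' @param x_c Treated endpoint count (> 0).
#' @param x_0 Count at treatment start (> 0).
#' @param x_ctrl Untreated endpoint count (must exceed `x_0`).
#' @return Object of class `gr_result`: `x_c`, `x_0`, `x_ctrl`, `gr`.
#' @export
gr_value <- function(x_c, x_0, x_ctrl) {
  if (x_0 <= 0 || x_c <= 0) stop("counts must be > 0")
  if (x_ctrl <= x_0)
    stop("non-growing control: GR normalization undefined")
  gr <- 2^(log2(x_c / x_0) / log2(x_ctrl / x_0)) - 1
  structure(list(x_c = x_c, x_0 = x_0, x_ctrl = x_ctrl, gr = gr),
            class = "gr_result")
}

hill_response <- function(d, e_max, ec50, hill) {
  ifelse(d <= 0, 1, e_max + (1 - e_max) / (1 + (d / ec50)^hill))
}

#' Fit a descending Hill dose-response curve
#'
#' Least-squares fit of `r(d) = e_max + (1 - e_max) / (1 + (d / ec50)^hill)`:
#' a viability fraction falling from 1 at zero dose to the residual fraction
#' `e_max` at saturating dose, with positive Hill slope. The AUC is computed
#' by the trapezoid rule over log10 dose, mapping dose 0 to one tenth of the
#' smallest nonzero dose.
#'
#' @param doses Doses (uM), at least 4 distinct values including 0.
#' @param responses Viability fractions (same length).
#' @return Object of class `dose_response_fit`: `e_max`, `hill`, `ec50`,
#'   `auc`, `residuals`, `converged`, `degenerate` (flat-response flag),
#'   `at_bounds`.
#' @export
fit_dose_response <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("length mismatch")
  if (length(unique(doses)) < 4 || !any(doses == 0))
    stop("need >= 4 distinct doses including 0")
  auc <- dose_response_auc(doses, responses)
  if (stats::sd(responses) < 1e-10) {
    return(structure(list(e_max = mean(responses), hill = NA_real_,
                          ec50 = NA_real_, auc = auc,
                          residuals = responses - mean(responses),
                          converged = FALSE, degenerate = TRUE,
                          at_bounds = FALSE),
                     class = "dose_response_fit"))
  }
  obj <- function(p) {
    sum((responses - hill_response(doses, p[1], exp(p[2]), exp(p[3])))^2)
  }
  mid <- (1 + min(responses)) / 2
  pos <- doses[doses > 0]
  ec50_0 <- pos[which.min(abs(responses[doses > 0] - mid))]
  starts <- list(c(max(0, min(responses)), log(ec50_0), log(1)),
                 c(max(0, min(responses)), log(stats::median(pos)), log(2)))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-14)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  # polish with a second pass from the best point
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  p <- best$par
  e_max <- p[1]; ec50 <- exp(p[2]); hill <- exp(p[3])
  at_bounds <- e_max < 1e-6 || e_max > 1 - 1e-6
  res <- responses - hill_response(doses, e_max, ec50, hill)
  structure(list(e_max = e_max, hill = hill, ec50 = ec50, auc = auc,
                 residuals = res, converged = best$convergence == 0,
                 degenerate = FALSE, at_bounds = at_bounds),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Degenerate (flat) dose-response; level = %.3f\n", x$e_max))
  } else {
    cat(sprintf("Hill fit: E_max = %.3f, Hill = %.2f, EC50 = %.4g uM, AUC = %.3f\n",
                x$e_max, x$hill, x$ec50, x$auc))
  }
  invisible(x)
}

#' Trapezoid AUC of a response curve over log10 dose
#'
#' Dose 0 is mapped to one tenth of the smallest nonzero dose so the
#' untreated anchor contributes to the grid.
#'
#' @param doses Doses (uM). @param responses Responses (same length).
#' @return Scalar AUC (dimensionless x log10-dose units).
#' @export
dose_response_auc <- function(doses, responses) {
  agg <- stats::aggregate(responses, list(dose = doses), mean)
  d <- agg$dose; r <- agg$x
  if (any(d == 0)) d[d == 0] <- min(d[d > 0]) / 10
  x <- log10(d)
  o <- order(x)
  x <- x[o]; r <- r[o]
  sum(diff(x) * (r[-1] + r[-length(r)]) / 2)
}

#' Sequential-dosing protection summary
#'
#' For each pre-treatment dose arm, the mean viable count relative to the
#' DMSO (zero) pre-treatment arm, +/- SD over replicates.
#'
#' @param plate data.frame from [simulate_sequential_plate()] (needs
#'   `pretreat_dose` and `viable_count`; a zero pre-treatment arm must be
#'   present).
#' @return data.frame (`pretreat_dose`, `fold_change`, `sd`, `n`).
#' @export
sequential_dosing_summary <- function(plate) {
  if (!any(plate$pretreat_dose == 0)) stop("missing DMSO pre-treatment arm")
  ref <- mean(plate$viable_count[plate$pretreat_dose == 0])
  arms <- split(plate$viable_count, plate$pretreat_dose)
  out <- data.frame(
    pretreat_dose = as.numeric(names(arms)),
    fold_change = vapply(arms, mean, numeric(1)) / ref,
    sd = vapply(arms, stats::sd, numeric(1)) / ref,
    n = lengths(arms)
  )
  rownames(out) <- NULL
  out[order(out$pretreat_dose), ]
}
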