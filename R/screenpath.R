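# Screen hit selection and per-cell tissue gating with background exclusion.

#' Otsu threshold of a numeric vector
#'
#' Histogram-based split maximizing between-class variance, as used to
#' separate marker-high from marker-low cells.
#'
#' @param x Numeric vector. @param n_breaks Histogram bins.
#' @return Threshold value; attribute `degenerate` is TRUE when `x` has no
#'   spread.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) == 0) {
    return(structure(if (length(x)) x[1] else NA_real_, degenerate = TRUE))
  }
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_breaks + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  structure(mids[which.max(sigma_b)], degenerate = FALSE)
}

#' Select screen hits by consistent low z-scores across lines
#'
#' Per line, compound readouts are averaged over replicates and doses,
#' z-scored across compounds and ranked ascending; hits are the compounds
#' ranked within the `k_lowest` lowest z-scores in *every* line. Ties at rank
#' `k_lowest` are included and flagged.
#'
#' @param plate data.frame (`compound`, `dose_uM`, `line`, `replicate`,
#'   `ngfr`) as from [simulate_screen()].
#' @param k_lowest Rank cutoff (default 5).
#' @return Object of class `hit_list`: `hits` (compound ids), `zscores`
#'   (compound x line matrix), `ranks`, `ties` flag.
#' @export
screen_hits <- function(plate, k_lowest = 5) {
  lines <- unique(plate$line)
  compounds <- unique(plate$compound)
  if (length(compounds) < k_lowest) stop("fewer compounds than k_lowest")
  z <- sapply(lines, function(ln) {
    d <- plate[plate$line == ln, ]
    if (nrow(d) == 0) stop("missing line data")
    means <- vapply(split(d$ngfr, d$compound), mean, numeric(1))[compounds]
    if (any(is.na(means))) stop("missing line data")
    (means - mean(means)) / stats::sd(means)
  })
  rownames(z) <- compounds
  ranks <- apply(z, 2, rank, ties.method = "min")
  max_ranks <- apply(z, 2, rank, ties.method = "max")
  ties <- FALSE
  in_k <- matrix(FALSE, length(compounds), length(lines))
  for (j in seq_along(lines)) {
    # a tie group straddling the boundary is included (borderline hits are
    # kept), unless the group is larger than k itself -- a block of more than
    # k indistinguishable compounds cannot be "among the k lowest"
    straddle <- ranks[, j] <= k_lowest & max_ranks[, j] > k_lowest
    tie_size <- max_ranks[, j] - ranks[, j] + 1
    in_k[, j] <- ranks[, j] <= k_lowest &
      (max_ranks[, j] <= k_lowest | tie_size <= k_lowest)
    if (any(straddle & in_k[, j])) ties <- TRUE
  }
  hits <- compounds[rowSums(in_k) == length(lines)]
  structure(list(hits = hits, zscores = z, ranks = ranks, ties = ties,
                 k_lowest = k_lowest),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("Screen hits (within %d lowest z-scores in all %d lines):\n",
              x$k_lowest, ncol(x$zscores)))
  cat(" ", if (length(x$hits)) paste(x$hits, collapse = ", ") else "(none)",
      "\n")
  if (x$ties) cat("  note: ties at the rank cutoff were included\n")
  invisible(x)
}

#' Exclude cells in high-background tissue regions
#'
#' Removes cells whose pre-stain (secondary-antibody-only) intensity exceeds
#' `bg_threshold`; marker values of retained cells are untouched.
#'
#' @param cells data.frame with a `prestain` column.
#' @param bg_threshold Intensity threshold.
#' @return Filtered data.frame with attributes `n_excluded`, `n_used`.
#' @export
exclude_background <- function(cells, bg_threshold) {
  if (!"prestain" %in% names(cells)) stop("prestain column required")
  keep <- cells$prestain <= bg_threshold
  out <- cells[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "n_used") <- sum(keep)
  out
}

#' Gate marker-high cells in a per-cell table
#'
#' Thresholds each marker (`fixed` value, `quantile` of a reference fraction,
#' or `otsu` on the marker distribution — the default for log intensities)
#' and reports the fraction of cells strictly above threshold per marker,
#' plus joint 2x2 quadrant counts for two-marker tables.
#'
#' @param cells data.frame of per-cell log intensities.
#' @param markers Marker column names.
#' @param method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param thresholds Named numeric (per marker) for `method = "fixed"`.
#' @param ref_quantile Quantile for `method = "quantile"`.
#' @return Object of class `gate_result`: `threshold` per marker,
#'   `fraction_high` per marker, `quadrants` (counts, for two markers),
#'   `n_cells`, `degenerate` flags.
#' @export
gate_high <- function(cells, markers = c("ngfr", "ki67"),
                      method = c("otsu", "fixed", "quantile"),
                      thresholds = NULL, ref_quantile = 0.95) {
  method <- match.arg(method)
  if (nrow(cells) < 10) stop("too few cells to gate")
  thr <- numeric(0); frac <- numeric(0); degen <- logical(0)
  high <- list()
  for (mk in markers) {
    x <- cells[[mk]]
    t_mk <- switch(method,
      otsu = otsu_threshold(x),
      fixed = {
        if (is.null(thresholds) || is.null(thresholds[[mk]]))
          stop("fixed method needs a threshold per marker")
        thresholds[[mk]]
      },
      quantile = stats::quantile(x, ref_quantile, names = FALSE)
    )
    degen <- c(degen, isTRUE(attr(t_mk, "degenerate")))
    thr[mk] <- as.numeric(t_mk)
    high[[mk]] <- x > thr[mk]
    frac[mk] <- mean(high[[mk]])
  }
  quadrants <- NULL
  if (length(markers) == 2) {
    quadrants <- table(
      factor(ifelse(high[[1]], "high", "low"), c("low", "high")),
      factor(ifelse(high[[2]], "high", "low"), c("low", "high")),
      dnn = markers
    )
  }
  structure(list(threshold = thr, fraction_high = frac,
                 quadrants = quadrants, n_cells = nrow(cells),
                 degenerate = stats::setNames(degen, markers)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("Marker gating over", x$n_cells, "cells:\n")
  for (mk in names(x$fraction_high)) {
    cat(sprintf("  %-6s threshold %.3f, %.1f%% high%s\n", mk,
                x$threshold[mk], 100 * x$fraction_high[mk],
                if (x$degenerate[mk]) " (degenerate threshold)" else ""))
  }
  invisible(x)
}
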