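# Expression-level rules: cross-line differential selection, fold-change
# classification, Chebyshev clustering preparation, z-scored marker
# landscapes and AUC-based marker correlation.

# fold change of treated vs DMSO FPKM; (FPKM+1)-stabilized by default
fold_change_vs_dmso <- function(fpkm_treated, fpkm_dmso, stabilize = TRUE) {
  if (stabilize) {
    (fpkm_treated + 1) / (fpkm_dmso + 1)
  } else {
    ifelse(fpkm_dmso == 0, NA_real_, fpkm_treated / fpkm_dmso)
  }
}

#' Cross-line differential gene selection
#'
#' Implements the three-rule filter for genes differentially regulated
#' between an adapting line A and a non-adapting line B, per drug time point:
#' a gene is *eligible* if its q-value versus DMSO is below `q_cut` in at
#' least one line; it is *selected* if additionally its treated FPKM is at
#' least `fpkm_min` (in the eligibility-driving line by default, or the
#' maximum over lines with `fpkm_rule = "max"`) and the cross-line ratio of
#' fold-changes satisfies `|log2(FC_A / FC_B)| >= log2ratio_min`. The sign of
#' the log2 ratio assigns up versus down in A relative to B.
#'
#' @param table data.frame (`gene`, `line` in `{A, B}`, `condition` with a
#'   `"DMSO"` level, `fpkm`, `q`) as from [simulate_expression_table()].
#' @param q_cut,fpkm_min,log2ratio_min Filter thresholds.
#' @param stabilize Use `(FPKM + 1)`-stabilized fold-changes (default); with
#'   `FALSE`, genes with zero DMSO FPKM are flagged and excluded.
#' @param fpkm_rule `"driving"` (FPKM floor applied in the line whose q-value
#'   made the gene eligible) or `"max"` (max over lines).
#' @return Object of class `differential_selection`: per-time-point `up` and
#'   `down` gene id lists, the `thresholds` used, a tidy `details` table and
#'   `excluded` (zero-DMSO genes when `stabilize = FALSE`).
#' @export
select_differential_genes <- function(table, q_cut = 0.01, fpkm_min = 1,
                                      log2ratio_min = 1, stabilize = TRUE,
                                      fpkm_rule = c("driving", "max")) {
  fpkm_rule <- match.arg(fpkm_rule)
  conditions <- setdiff(unique(table$condition), "DMSO")
  up <- list(); down <- list(); details <- list(); excluded <- character(0)
  dmso <- table[table$condition == "DMSO", ]
  for (cond in conditions) {
    tr <- table[table$condition == cond, ]
    wide <- function(df, col) {
      a <- df[df$line == "A", ]; b <- df[df$line == "B", ]
      m <- merge(a[, c("gene", col)], b[, c("gene", col)], by = "gene",
                 suffixes = c("_A", "_B"))
      m
    }
    f <- merge(wide(tr, "fpkm"), wide(dmso, "fpkm"), by = "gene",
               suffixes = c("", "_dmso"))
    qs <- wide(tr, "q")
    m <- merge(f, qs, by = "gene")
    if (!stabilize) {
      bad <- m$gene[m$fpkm_A_dmso == 0 | m$fpkm_B_dmso == 0]
      excluded <- union(excluded, bad)
      m <- m[!(m$gene %in% bad), ]
    }
    fc_a <- fold_change_vs_dmso(m$fpkm_A, m$fpkm_A_dmso, stabilize)
    fc_b <- fold_change_vs_dmso(m$fpkm_B, m$fpkm_B_dmso, stabilize)
    l2r <- log2(fc_a / fc_b)
    elig_a <- m$q_A < q_cut
    elig_b <- m$q_B < q_cut
    eligible <- elig_a | elig_b
    fpkm_ok <- switch(fpkm_rule,
      driving = (elig_a & m$fpkm_A >= fpkm_min) |
                (elig_b & m$fpkm_B >= fpkm_min),
      max = pmax(m$fpkm_A, m$fpkm_B) >= fpkm_min
    )
    sel <- eligible & fpkm_ok & abs(l2r) >= log2ratio_min
    up[[cond]] <- m$gene[sel & l2r > 0]
    down[[cond]] <- m$gene[sel & l2r < 0]
    details[[cond]] <- data.frame(gene = m$gene,
                                  condition = rep(cond, nrow(m)),
                                  log2_ratio = l2r, eligible = eligible,
                                  fpkm_ok = fpkm_ok, selected = sel)
  }
  structure(list(up = up, down = down,
                 thresholds = list(q_cut = q_cut, fpkm_min = fpkm_min,
                                   log2ratio_min = log2ratio_min,
                                   stabilize = stabilize,
                                   fpkm_rule = fpkm_rule),
                 details = do.call(rbind, details), excluded = excluded),
            class = "differential_selection")
}

#' Classify a log2 fold-change into increase / decrease / no change
#'
#' `increase` for `log2fc > cut`, `decrease` for `log2fc < -cut`, and
#' `no_change` for `|log2fc| <= cut` (the boundary is inclusive of
#' `no_change`).
#'
#' @param log2fc Finite numeric vector. @param cut Classification cut.
#' @return Character vector of labels.
#' @export
classify_fold_change <- function(log2fc, cut = 0.5) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  ifelse(log2fc > cut, "increase",
         ifelse(log2fc < -cut, "decrease", "no_change"))
}

#' Prepare an expression matrix for Chebyshev hierarchical clustering
#'
#' Builds the `log2((FPKM + 1)_treated / (FPKM + 1)_DMSO)` matrix (genes x
#' line:condition columns), the pairwise Chebyshev (maximum-coordinate)
#' distance matrix and an agglomerative dendrogram.
#'
#' @param table Gene table as in [select_differential_genes()].
#' @param genes Optional subset of gene ids (e.g. a differential selection).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List: `matrix`, `dist` (class `dist`, Chebyshev), `hclust`,
#'   `newick` (dendrogram as a Newick string).
#' @export
prepare_cluster_matrix <- function(table, genes = NULL, linkage = "average") {
  if (!"DMSO" %in% table$condition) stop("DMSO condition required")
  if (!is.null(genes)) table <- table[table$gene %in% genes, ]
  conditions <- setdiff(unique(table$condition), "DMSO")
  lines <- unique(table$line)
  gene_ids <- unique(table$gene)
  cols <- list()
  for (ln in lines) {
    d0 <- table[table$line == ln & table$condition == "DMSO", ]
    base <- stats::setNames(d0$fpkm, d0$gene)[gene_ids]
    for (cond in conditions) {
      tr <- table[table$line == ln & table$condition == cond, ]
      v <- stats::setNames(tr$fpkm, tr$gene)[gene_ids]
      cols[[paste(ln, cond, sep = ":")]] <- log2((v + 1) / (base + 1))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- gene_ids
  d <- stats::dist(m, method = "maximum")
  hc <- stats::hclust(d, method = linkage)
  nwk <- if (nrow(m) >= 3) ape::write.tree(ape::as.phylo(hc)) else NA_character_
  list(matrix = m, dist = d, hclust = hc, newick = nwk)
}

#' z-scored two-marker landscape across conditions
#'
#' For each condition, replicate marker measurements are averaged, log
#' transformed and z-scored across conditions (per marker independently),
#' yielding the 2D landscape used to compare drug-combination effects on
#' NGFR versus Ki-67. A degenerate (zero-SD) marker is flagged and its
#' z-scores set to 0.
#'
#' @param measurements data.frame with `condition`, one column per marker
#'   (e.g. `ngfr`, `ki67`); rows are replicate/dose measurements.
#' @param markers Marker column names.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return data.frame with `condition`, `<marker>_log_mean` and `<marker>_z`
#'   columns; attribute `degenerate` lists zero-SD markers.
#' @export
zscore_landscape <- function(measurements, markers = c("ngfr", "ki67"),
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  conds <- unique(measurements$condition)
  if (length(conds) < 2) stop("need >= 2 conditions")
  out <- data.frame(condition = conds)
  degenerate <- character(0)
  for (mk in markers) {
    means <- vapply(conds, function(cc) {
      v <- measurements[[mk]][measurements$condition == cc]
      log(mean(v))
    }, numeric(1))
    s <- stats::sd(means)
    if (sd_type == "population")
      s <- s * sqrt((length(means) - 1) / length(means))
    if (!is.finite(s) || s == 0) {
      degenerate <- c(degenerate, mk)
      z <- rep(0, length(means))
    } else {
      z <- (means - mean(means)) / s
    }
    out[[paste0(mk, "_log_mean")]] <- means
    out[[paste0(mk, "_z")]] <- z
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Correlation of per-line dose-response AUCs for two markers
#'
#' Computes the AUC over log10 dose of each line's dose-response for each
#' marker, z-scores the AUCs across lines and reports their Pearson
#' correlation (the statistic used to relate drug-induced c-Jun and NGFR
#' changes across a cell-line panel).
#'
#' @param dose_response data.frame with `line`, `dose`, and one response
#'   column per marker.
#' @param markers Two marker column names.
#' @return List: `r` (Pearson), `auc` (lines x markers), `z` (z-scored AUCs).
#' @export
auc_correlation <- function(dose_response, markers = c("cjun", "ngfr")) {
  stopifnot(length(markers) == 2)
  lines <- unique(dose_response$line)
  if (length(lines) < 3) stop("need >= 3 lines")
  auc <- vapply(markers, function(mk) {
    vapply(lines, function(ln) {
      d <- dose_response[dose_response$line == ln, ]
      dose_response_auc(d$dose, d[[mk]])
    }, numeric(1))
  }, numeric(length(lines)))
  rownames(auc) <- lines
  if (any(apply(auc, 2, stats::sd) == 0))
    stop("constant AUCs: correlation undefined")
  z <- scale(auc)
  list(r = stats::cor(z[, 1], z[, 2]), auc = auc, z = z)
}
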