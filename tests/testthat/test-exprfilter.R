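# Expression rules: differential selection, fold-change classes, Chebyshev
# clustering preparation, z-scored landscapes and AUC correlation.

make_gene_table <- function(genes) {
  # genes: list of list(gene, fpkm_dmso_a, fpkm_a, q_a, fpkm_dmso_b, fpkm_b, q_b)
  do.call(rbind, lapply(genes, function(g) {
    data.frame(
      gene = g$gene,
      line = rep(c("A", "B"), each = 2),
      condition = rep(c("DMSO", "drug24h"), 2),
      fpkm = c(g$fpkm_dmso_a, g$fpkm_a, g$fpkm_dmso_b, g$fpkm_b),
      q = c(1, g$q_a, 1, g$q_b)
    )
  }))
}

test_that("select_differential_genes applies the three rules", {
  tab <- make_gene_table(list(
    # q_A = 0.005, raw FC_A = 4, FC_B = 1 -> log2 ratio = 2 -> up
    list(gene = "g_up", fpkm_dmso_a = 10, fpkm_a = 40, q_a = 0.005,
         fpkm_dmso_b = 10, fpkm_b = 10, q_b = 0.9),
    # non-significant in both lines -> ineligible despite a huge ratio
    list(gene = "g_ns", fpkm_dmso_a = 10, fpkm_a = 160, q_a = 0.5,
         fpkm_dmso_b = 10, fpkm_b = 10, q_b = 0.5),
    # NGFR-like: 15-fold up in A, 4-fold down in B -> ratio 60 -> up
    list(gene = "g_ngfr", fpkm_dmso_a = 10, fpkm_a = 150, q_a = 3e-4,
         fpkm_dmso_b = 40, fpkm_b = 10, q_b = 5e-4),
    # significant but below the FPKM floor in the driving line
    list(gene = "g_low", fpkm_dmso_a = 0.1, fpkm_a = 0.5, q_a = 0.005,
         fpkm_dmso_b = 0.1, fpkm_b = 0.1, q_b = 0.9)
  ))
  sel <- select_differential_genes(tab, stabilize = FALSE)
  expect_setequal_chr(sel$up$drug24h, c("g_up", "g_ngfr"))
  expect_length(sel$down$drug24h, 0)
  det <- sel$details
  expect_equal(det$log2_ratio[det$gene == "g_up"], 2)
  expect_equal(det$log2_ratio[det$gene == "g_ngfr"], log2(60))
  expect_false(det$selected[det$gene == "g_ns"])
  expect_false(det$selected[det$gene == "g_low"])

  # zero-DMSO genes flagged and excluded in raw-ratio mode
  tab0 <- make_gene_table(list(
    list(gene = "g0", fpkm_dmso_a = 0, fpkm_a = 5, q_a = 0.001,
         fpkm_dmso_b = 1, fpkm_b = 1, q_b = 0.9)))
  sel0 <- select_differential_genes(tab0, stabilize = FALSE)
  expect_identical(sel0$excluded, "g0")
})

test_that("selection equals the brute-force per-gene oracle on a random table", {
  set.seed(51)
  n <- 10000
  genes <- sprintf("g%05d", 1:n)
  tab <- expand.grid(gene = genes, line = c("A", "B"),
                     condition = c("DMSO", "drug24h"),
                     stringsAsFactors = FALSE)
  tab$fpkm <- rlnorm(nrow(tab), log(5), 1.5)
  tab$q <- ifelse(tab$condition == "DMSO", 1,
                  sample(c(0.001, 0.5), nrow(tab), TRUE, c(0.3, 0.7)))
  sel <- select_differential_genes(tab)
  orc <- oracle_de_filter(tab)
  expect_setequal_chr(sel$up$drug24h, orc$drug24h$up)
  expect_setequal_chr(sel$down$drug24h, orc$drug24h$down)
  # selected up/down are disjoint and every selected gene passes all rules
  expect_length(intersect(sel$up$drug24h, sel$down$drug24h), 0)
  det <- sel$details
  expect_true(all(det$eligible[det$selected] & det$fpkm_ok[det$selected] &
                    abs(det$log2_ratio[det$selected]) >= 1))
})

test_that("classify_fold_change partitions the line with an inclusive boundary", {
  expect_identical(classify_fold_change(0.6), "increase")
  expect_identical(classify_fold_change(-0.6), "decrease")
  expect_identical(classify_fold_change(c(0.5, -0.5, 0)),
                   rep("no_change", 3))
  set.seed(52)
  x <- runif(200, -3, 3)
  lab <- classify_fold_change(x)
  expect_true(all(lab %in% c("increase", "decrease", "no_change")))
  expect_identical(lab == "increase", x > 0.5)
  expect_identical(lab == "decrease", x < -0.5)
  expect_error(classify_fold_change(NaN), "finite")
})

test_that("prepare_cluster_matrix: Chebyshev distances and ratio matrix", {
  tab <- make_gene_table(list(
    list(gene = "ga", fpkm_dmso_a = 1, fpkm_a = 1, q_a = 1,
         fpkm_dmso_b = 1, fpkm_b = 15, q_b = 1),   # B col log2(16/2)=3
    list(gene = "gb", fpkm_dmso_a = 1, fpkm_a = 1, q_a = 1,
         fpkm_dmso_b = 1, fpkm_b = 3, q_b = 1),    # B col log2(4/2)=1
    list(gene = "gc", fpkm_dmso_a = 1, fpkm_a = 1, q_a = 1,
         fpkm_dmso_b = 1, fpkm_b = 1, q_b = 1)
  ))
  cm <- prepare_cluster_matrix(tab)
  m <- cm$matrix
  expect_equal(unname(m["ga", ]), c(0, 3))
  expect_equal(unname(m["gb", ]), c(0, 1))
  dd <- as.matrix(cm$dist)
  expect_equal(dd["ga", "gb"], 2)  # rows (0,0,3) vs (0,0,1): Chebyshev 2
  expect_equal(dd["gb", "gc"], 1)
  expect_true(grepl("ga", cm$newick))

  # identical FPKM everywhere -> all-zero matrix; identical rows merge first
  taba <- tab; taba$fpkm <- 1
  cma <- prepare_cluster_matrix(taba)
  expect_true(all(cma$matrix == 0))
  expect_true(all(as.matrix(cma$dist) == 0))

  # metric axioms on a random matrix (sampled triangle inequality)
  set.seed(53)
  rm <- matrix(rnorm(30 * 4), 30)
  dm <- as.matrix(dist(rm, method = "maximum"))
  expect_equal(dm, t(dm))
  for (i in 1:50) {
    ijk <- sample(30, 3)
    expect_lte(dm[ijk[1], ijk[3]],
               dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("zscore_landscape normalizes per marker across conditions", {
  meas <- data.frame(
    condition = rep(c("c1", "c2", "c3"), each = 2),
    ngfr = rep(exp(c(1, 2, 3)), each = 2),
    ki67 = rep(exp(c(5, 5, 5)), each = 2)
  )
  ls <- zscore_landscape(meas)
  expect_equal(ls$ngfr_z, c(-1, 0, 1))  # log means 1,2,3; sample SD = 1
  expect_identical(attr(ls, "degenerate"), "ki67")
  expect_equal(ls$ki67_z, c(0, 0, 0))
  expect_error(zscore_landscape(meas[meas$condition == "c1", ]), "2 conditions")

  # z-scores are invariant to the log base: manual base-10 z equals package z
  set.seed(54)
  meas2 <- data.frame(condition = rep(paste0("c", 1:7), each = 3),
                      ngfr = rlnorm(21, 1, 0.5), ki67 = rlnorm(21, 2, 0.3))
  z_e <- zscore_landscape(meas2)$ngfr_z
  m10 <- log10(vapply(split(meas2$ngfr, meas2$condition), mean, numeric(1)))
  m10 <- m10[unique(meas2$condition)]
  expect_equal(unname(scale(m10)[, 1]), z_e, tolerance = 1e-12)
  # mean 0, SD 1 whenever non-degenerate
  expect_equal(mean(z_e), 0, tolerance = 1e-12)
  expect_equal(sd(z_e), 1, tolerance = 1e-12)

  # MEK-inhibitor-like combo raises NGFR / lowers Ki-67; FAK-like lowers both
  combo <- data.frame(
    condition = rep(c("vem", "vem_tram", "vem_fak"), each = 2),
    ngfr = rep(c(10, 30, 3), each = 2), ki67 = rep(c(10, 3, 3), each = 2))
  lc <- zscore_landscape(combo)
  expect_gt(lc$ngfr_z[lc$condition == "vem_tram"],
            lc$ngfr_z[lc$condition == "vem_fak"])
  expect_lt(lc$ki67_z[lc$condition == "vem_tram"], 0)
  expect_lt(lc$ki67_z[lc$condition == "vem_fak"], 0)
})

test_that("auc_correlation recovers planted cross-line correlation", {
  doses <- c(0, 0.1, 0.32, 1, 3.2)
  build_panel <- function(slopes1, slopes2) {
    do.call(rbind, lapply(seq_along(slopes1), function(i) {
      data.frame(line = paste0("L", i), dose = doses,
                 cjun = 1 + slopes1[i] * seq_along(doses),
                 ngfr = 1 + slopes2[i] * seq_along(doses))
    }))
  }
  set.seed(55)
  a <- rnorm(9)
  # marker2 responses proportional to marker1 -> r = 1 (affine invariance)
  p1 <- build_panel(a, 2 * a)
  expect_equal(auc_correlation(p1, c("cjun", "ngfr"))$r, 1, tolerance = 1e-12)
  # planted correlation: AUC is affine in the slope, so recovered r equals
  # the sample correlation of the planted slope pairs exactly
  b <- 0.86 * scale(a)[, 1] + sqrt(1 - 0.86^2) * scale(rnorm(9))[, 1]
  p2 <- build_panel(a, b)
  expect_equal(auc_correlation(p2, c("cjun", "ngfr"))$r, cor(a, b),
               tolerance = 1e-10)
  expect_error(auc_correlation(build_panel(a[1:2], a[1:2])), "3 lines")
  # Monte-Carlo null: independent slopes -> r distribution centred at 0
  rs <- vapply(1:300, function(i) {
    auc_correlation(build_panel(rnorm(9), rnorm(9)), c("cjun", "ngfr"))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(8 * 300))  # ~3 SE of the null mean
})
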