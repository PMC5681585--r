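make_panel <- function(n = 60, n_genes = 5, snps_per_gene = 12, seed = 60,
                       tau2 = rep(0, n_genes)) {
  set.seed(seed)
  spacing <- 2e5
  vlist <- list(); dlist <- list(); genes <- list(); elist <- list()
  for (gi in seq_len(n_genes)) {
    tss <- gi * spacing
    g <- simulate_genotypes(n, snps_per_gene, seed = seed + gi,
                            pos_start = tss - 4000, pos_step = 700L)
    g$variants$id <- sprintf("g%d_%s", gi, g$variants$id)
    vlist[[gi]] <- g$variants
    dlist[[gi]] <- g$dosages
    e <- simulate_expression(g, tau2 = tau2[gi], seed = seed + 100 + gi)
    elist[[gi]] <- exp(e)   # strictly positive, rank-preserving raw scale
    genes[[gi]] <- data.frame(gene_id = sprintf("gene%02d", gi), chrom = "1",
                              tss = tss, strand = "+",
                              biotype = "protein_coding",
                              stringsAsFactors = FALSE)
  }
  geno <- genotype_matrix(do.call(cbind, dlist), do.call(rbind, vlist),
                          samples = sprintf("sample%04d", seq_len(n)))
  expr <- do.call(rbind, elist)
  genes <- do.call(rbind, genes)
  rownames(expr) <- genes$gene_id
  colnames(expr) <- geno$samples
  list(geno = geno, expr = expr, genes = genes)
}

test_that("quantile normalization maps ranks to normal quantiles", {
  x <- c(5, -2, 11)
  expect_equal(quantile_normalize(x),
               qnorm(c(3, 1, 5) / 6))
  # monotone-transform invariance and rank preservation
  y <- rnorm(20)
  expect_equal(quantile_normalize(y), quantile_normalize(exp(y)))
  expect_identical(order(quantile_normalize(y)), order(y))
  # ties share the average-rank quantile
  z <- quantile_normalize(c(1, 1, 3, 4))
  expect_equal(z[1], z[2])
  expect_error(quantile_normalize(rep(2, 5)), "constant")
  expect_error(quantile_normalize(c(1, 2)), "at least 3")
})

test_that("cis window is closed, TSS-centered, with strict MAF filtering", {
  pos <- c(94999L, 95000L, 100000L, 105000L, 105001L)
  set.seed(61)
  dos <- matrix(rbinom(40 * 5, 2, 0.4), 40, 5)
  # make variant 3 exactly MAF 0.05: dosage sum 4 over 40 samples
  dos[, 3] <- c(rep(1, 4), rep(0, 36))
  g <- genotype_matrix(dos, data.frame(id = paste0("v", 1:5), chrom = "7",
                                       pos = pos))
  gene <- data.frame(gene_id = "g", chrom = "7", tss = 100000L)
  cis <- extract_cis_snps(gene, g, window_kb = 10, maf_min = 0.05)
  expect_identical(cis$variants$id, c("v2", "v4"))  # boundaries in, 0.05 out
  none <- extract_cis_snps(data.frame(chrom = "8", tss = 100000L), g)
  expect_identical(n_variants(none), 0L)
  # brute-force window scan agrees
  half <- 5000
  manual <- g$variants$id[g$variants$pos >= 100000 - half &
                            g$variants$pos <= 100000 + half &
                            geno_maf(g) > 0.05]
  expect_identical(cis$variants$id, manual)
})

test_that("gene filters apply expression-fraction and SNP-count thresholds", {
  pan <- make_panel(n = 60, n_genes = 3, snps_per_gene = 12, seed = 62)
  expr <- pan$expr
  # gene 1 expressed in exactly n/2 - 1 samples -> excluded
  expr["gene01", ] <- c(rep(1, 29), rep(0, 31))
  # gene 2 expressed in exactly n/2 -> kept
  expr["gene02", ] <- c(rep(1, 30), rep(0, 30))
  sel <- select_genes(pan$genes, expr, pan$geno)
  expect_false("gene01" %in% sel$gene_id)
  expect_true("gene02" %in% sel$gene_id)
  # biotype filter
  genes2 <- pan$genes
  genes2$biotype[3] <- "lincRNA"
  sel2 <- select_genes(genes2, pan$expr, pan$geno)
  expect_false("gene03" %in% sel2$gene_id)
  # SNP-count boundary: 9 qualifying cis-SNPs excluded, 10 included
  sel9 <- select_genes(pan$genes, pan$expr, pan$geno, min_snps = 13L)
  expect_identical(nrow(sel9), 0L)
  sel10 <- select_genes(pan$genes, pan$expr, pan$geno, min_snps = 12L)
  expect_true(all(sel10$n_cis_snps >= 12L))
})

test_that("test_gene returns a coherent record; null construction gives p = 1", {
  pan <- make_panel(n = 50, n_genes = 1, snps_per_gene = 10, seed = 63,
                    tau2 = 0.5)
  gene <- pan$genes[1, ]
  cis <- extract_cis_snps(gene, pan$geno)
  res <- test_gene(gene, cis, pan$expr[1, ], L = 2000, M = 2000,
                   score = TRUE, seed = 64)
  expect_identical(res$n_snps, n_variants(cis))
  expect_true(res$p_alrt > 0 && res$p_alrt <= 1)
  expect_true(res$p_elrt > 0 && res$p_elrt <= 1)
  expect_true(res$p_score > 0 && res$p_score <= 1)
  # orthogonal phenotype construction: T = 0, p = 1 on both routes
  sdc <- spectral_decompose(cis)
  w <- rnorm(sdc$dof)
  w <- w - sdc$U %*% crossprod(sdc$U, w)
  e0 <- as.numeric(sdc$Q2 %*% w)
  # quantile normalization would break orthogonality; test the fitted core
  fit0 <- fit_reml(spectral_decompose(cis, e = e0))
  expect_identical(fit0$T, 0)
  nd <- simulate_null_draws(sdc, 500, seed = 65)
  expect_equal(exact_pvalue(fit0$T, nd), 1)
})

test_that("strong signal genes reach very small aLRT p-values", {
  set.seed(66)
  g <- simulate_genotypes(465, 20, seed = 66)
  # genetic variance ~ residual variance; the model's per-SNP
  # signal-to-noise is then lambda = tau2, h2 = lambda / (1 + lambda)
  zv <- sum(apply(g$dosages, 2, var))
  e <- simulate_expression(g, tau2 = 1 / zv, seed = 67)
  gene <- data.frame(gene_id = "strong", chrom = "1",
                     tss = g$variants$pos[10])
  res <- test_gene(gene, g, e, L = 1e4, seed = 68)
  expect_lt(res$p_alrt, 1e-6)
  expect_gt(res$h2, 0.05)
})

test_that("scan applies Bonferroni control and recovers planted signals", {
  n_genes <- 40
  tau2 <- rep(0, n_genes)
  signal <- c(3, 11, 22, 37)
  tau2[signal] <- 0.12           # ~h2 0.3-0.4 at 12 SNPs
  pan <- make_panel(n = 120, n_genes = n_genes, snps_per_gene = 12,
                    seed = 69, tau2 = tau2)
  res <- egene_scan(pan$genes, pan$geno, pan$expr, alpha = 0.05,
                    min_snps = 5L, L = 3000, seed = 70)
  expect_identical(attr(res, "bonferroni"), 0.05 / nrow(res))
  hits <- res$gene_id[res$egene_flag]
  planted <- pan$genes$gene_id[signal]
  expect_gte(sum(planted %in% hits), 3L)
  expect_lte(sum(!(hits %in% planted)), 1L)
  # eGene count monotone in threshold stringency
  expect_gte(sum(res$p_alrt <= 0.05 / 10), sum(res$p_alrt <= 0.05 / 1000))
})

test_that("scan results are invariant to sample permutation", {
  pan <- make_panel(n = 50, n_genes = 3, snps_per_gene = 10, seed = 71,
                    tau2 = c(0.3, 0, 0.1))
  res1 <- egene_scan(pan$genes, pan$geno, pan$expr, min_snps = 5L,
                     L = 1000, seed = 72)
  set.seed(73)
  perm <- sample(ncol(pan$expr))
  expr_p <- pan$expr[, perm]
  res2 <- egene_scan(pan$genes, pan$geno, expr_p, min_snps = 5L,
                     L = 1000, seed = 72)
  expect_equal(res1$T, res2$T, tolerance = 1e-10)
  expect_equal(res1$p_alrt, res2$p_alrt, tolerance = 1e-10)
})

test_that("Bonferroni thresholds follow alpha / G", {
  expect_equal(0.05 / 20000, 2.5e-6)
  pan <- make_panel(n = 50, n_genes = 1, snps_per_gene = 10, seed = 74,
                    tau2 = 0.2)
  res <- egene_scan(pan$genes, pan$geno, pan$expr, min_snps = 5L,
                    L = 500, seed = 75)
  expect_identical(attr(res, "bonferroni"), attr(res, "alpha") / 1)
})
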