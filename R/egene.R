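#' Quantile-normalize an expression vector to the standard normal
#'
#' Replaces values by `qnorm((rank - 0.5) / n)` using average ranks for
#' ties; the output has near-zero mean and sample quantiles matching the
#' standard normal, and is invariant to strictly monotone transforms of the
#' input.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return normalized numeric vector (names preserved).
#' @export
quantile_normalize <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in expression")
  if (max(x) == min(x)) stop("constant expression vector cannot be normalized")
  r <- rank(x, ties.method = "average")
  out <- qnorm((r - 0.5) / length(x))
  names(out) <- names(x)
  out
}

#' Extract cis-SNPs around a gene's transcription start site
#'
#' Keeps variants on the gene's chromosome with position in the closed
#' window `[TSS - W/2, TSS + W/2]` (1-based; default width 10 kb, centered
#' on the TSS, strand-agnostic) and MAF strictly above `maf_min`.
#'
#' @param gene one-row data.frame (or list) with `chrom` and `tss`.
#' @param geno a `genotype_matrix`.
#' @param window_kb full window width in kb.
#' @param maf_min strict MAF lower bound.
#' @return a `genotype_matrix` (possibly with zero variants).
#' @export
extract_cis_snps <- function(gene, geno, window_kb = 10, maf_min = 0.05) {
  half <- window_kb * 1000 / 2
  v <- geno$variants
  keep <- v$chrom == gene$chrom &
    v$pos >= gene$tss - half & v$pos <= gene$tss + half
  keep <- keep & geno_maf(geno) > maf_min
  subset_genotypes(geno, variants = which(keep))
}

#' Filter genes for testability
#'
#' Keeps protein-coding genes expressed (strictly positive measurement) in
#' at least half of the samples (`ceiling(n/2)`) and with at least
#' `min_snps` cis-SNPs passing the MAF filter inside the window.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand`, `biotype`.
#' @param expr genes x samples expression matrix with gene IDs as row names.
#' @param geno a `genotype_matrix` aligned to the expression samples.
#' @param window_kb,maf_min window and MAF settings (see
#'   [extract_cis_snps()]).
#' @param min_snps minimum cis-SNP count.
#' @param biotype required biotype (`NULL` disables the filter).
#' @return the filtered `genes` data.frame with an added `n_cis_snps`
#'   column.
#' @export
select_genes <- function(genes, expr, geno, window_kb = 10, maf_min = 0.05,
                         min_snps = 10L, biotype = "protein_coding") {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  n <- ncol(expr)
  need <- ceiling(n / 2)
  keep <- rep(TRUE, nrow(genes))
  if (!is.null(biotype) && !is.null(genes$biotype))
    keep <- keep & genes$biotype == biotype
  keep <- keep & genes$gene_id %in% rownames(expr)
  n_cis <- integer(nrow(genes))
  for (i in which(keep)) {
    expressed <- sum(expr[genes$gene_id[i], ] > 0)
    if (expressed < need) { keep[i] <- FALSE; next }
    cis <- extract_cis_snps(genes[i, ], geno, window_kb, maf_min)
    n_cis[i] <- n_variants(cis)
    if (n_cis[i] < min_snps) keep[i] <- FALSE
  }
  out <- genes[keep, , drop = FALSE]
  out$n_cis_snps <- n_cis[keep]
  if (nrow(out) == 0L) message("no genes pass the filters")
  rownames(out) <- NULL
  out
}

#' Test one gene's cis-SNP set against its expression
#'
#' Pipeline for a single gene: quantile normalization of the expression,
#' spectral decomposition of the cis genotypes, REML fit, approximate LRT
#' p-value via the mixture null fitted on `L` fresh draws, and optionally
#' the exact LRT (`M` draws) and the score test.
#'
#' @param gene one-row data.frame with `gene_id`, `chrom`, `tss`.
#' @param cis a `genotype_matrix` of the gene's cis-SNPs.
#' @param e raw expression vector aligned to the genotype samples.
#' @param covariates optional covariate columns (intercept always added).
#' @param L approximate-null draws.
#' @param M exact-null draws (`NULL` skips the eLRT).
#' @param score also run the score test.
#' @param mixture_method `kappa` estimator for the mixture fit.
#' @param window_kb recorded window width (bookkeeping only).
#' @param seed RNG seed for the null draws.
#' @return one-row data.frame: `gene_id`, `chrom`, `tss`, `n_snps`,
#'   `lambda_hat`, `h2`, `T`, `p_alrt`, `p_elrt`, `p_score`.
#' @export
test_gene <- function(gene, cis, e, covariates = NULL, L = 1e4, M = NULL,
                      score = FALSE, mixture_method = "moment",
                      window_kb = 10, seed = NULL) {
  en <- quantile_normalize(e)
  X <- design_matrix(length(en), covariates)
  sdc <- spectral_decompose(cis, X, en)
  fit <- fit_reml(sdc)
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, 2L)
  mix <- fit_mixture(simulate_null_draws(sdc, M = as.integer(L),
                                         seed = seeds[1L]),
                     method = mixture_method)
  p_alrt <- mixture_pvalue(fit$T, mix)
  p_elrt <- if (!is.null(M)) {
    exact_pvalue(fit$T, simulate_null_draws(sdc, M = as.integer(M),
                                            seed = seeds[2L]))
  } else NA_real_
  p_score <- if (score) score_test(sdc)$p_value else NA_real_
  data.frame(gene_id = gene$gene_id, chrom = gene$chrom, tss = gene$tss,
             n_snps = n_variants(cis),
             lambda_hat = fit$lambda_hat, h2 = fit$h2, T = fit$T,
             p_alrt = p_alrt, p_elrt = p_elrt, p_score = p_score,
             stringsAsFactors = FALSE)
}

#' Genome scan for eGenes
#'
#' Runs [select_genes()], then [test_gene()] per retained gene, and flags
#' eGenes at the Bonferroni-corrected threshold `alpha / G` over the `G`
#' tested genes (family-wise error control). Genes whose test fails are
#' skipped with a logged reason.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`, `biotype`).
#' @param geno a `genotype_matrix` covering all candidate variants.
#' @param expr genes x samples expression matrix (row names = gene IDs,
#'   column names = sample IDs aligned with `geno`).
#' @param covariates optional covariate matrix (e.g. PEER factors,
#'   population indicators); never computed internally.
#' @param alpha family-wise error rate.
#' @param window_kb,maf_min,min_snps,biotype gene/SNP filters.
#' @param L,M,score,mixture_method per-gene test settings (see
#'   [test_gene()]).
#' @param seed master seed; each gene derives its own child seed.
#' @return data.frame of class `egene_scan` with the [test_gene()] columns
#'   plus `egene_flag`; attributes `bonferroni` (threshold), `alpha`,
#'   `n_tested`.
#' @export
egene_scan <- function(genes, geno, expr, covariates = NULL, alpha = 0.05,
                       window_kb = 10, maf_min = 0.05, min_snps = 10L,
                       biotype = "protein_coding", L = 1e4, M = NULL,
                       score = FALSE, mixture_method = "moment", seed = 1L) {
  if (!is.null(colnames(expr))) {
    if (!setequal(colnames(expr), geno$samples))
      stop("expression and genotype samples differ: ",
           paste(head(c(setdiff(colnames(expr), geno$samples),
                        setdiff(geno$samples, colnames(expr)))), collapse = ", "))
    expr <- expr[, geno$samples, drop = FALSE]   # align by ID, never position
  }
  sel <- select_genes(genes, expr, geno, window_kb, maf_min, min_snps, biotype)
  if (nrow(sel) == 0L) stop("no testable genes")
  seeds <- derive_seeds(seed, nrow(sel))
  rows <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    gene <- sel[i, ]
    cis <- extract_cis_snps(gene, geno, window_kb, maf_min)
    rows[[i]] <- tryCatch(
      test_gene(gene, cis, expr[gene$gene_id, ], covariates, L = L, M = M,
                score = score, mixture_method = mixture_method,
                window_kb = window_kb, seed = seeds[i]),
      error = function(err) {
        message("gene ", gene$gene_id, " skipped: ", conditionMessage(err))
        NULL
      })
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) stop("all genes failed testing")
  G <- nrow(res)
  threshold <- alpha / G
  res$egene_flag <- res$p_alrt <= threshold
  attr(res, "bonferroni") <- threshold
  attr(res, "alpha") <- alpha
  attr(res, "n_tested") <- G
  attr(res, "seed") <- seed
  class(res) <- c("egene_scan", "data.frame")
  res
}

#' Per-chromosome eGene summary
#'
#' @param res an `egene_scan` result.
#' @return data.frame with genes tested, eGene count and proportion per
#'   chromosome.
#' @export
egene_summary <- function(res) {
  chroms <- sort(unique(res$chrom))
  out <- data.frame(
    chrom = chroms,
    n_genes = vapply(chroms, function(c) sum(res$chrom == c), integer(1)),
    n_egenes = vapply(chroms, function(c)
      sum(res$egene_flag[res$chrom == c]), integer(1)),
    row.names = NULL)
  out$prop_egene <- out$n_egenes / out$n_genes
  out
}
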