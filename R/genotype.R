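#' Genotype dosage matrix
#'
#' Container for an n-samples by p-variants matrix of alternate-allele
#' dosages in \[0, 2\] together with variant metadata. Missing dosages are
#' imputed to the per-variant mean at construction; variants are kept in
#' nondecreasing position order within each chromosome.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos` and
#'   optionally `ref`, `alt` (one row per column of `dosages`).
#' @param samples character vector of sample IDs (defaults to row names).
#' @param impute_missing impute `NA` dosages to the per-variant mean.
#' @param sort_variants reorder variants by (chrom, pos) if needed.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `samples`.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages),
                            impute_missing = TRUE, sort_variants = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)))
  if (is.null(variants$ref)) variants$ref <- NA_character_
  if (is.null(variants$alt)) variants$alt <- NA_character_
  if (nrow(variants) != ncol(dosages))
    stop("variants table and dosage matrix disagree on the number of variants")
  if (anyDuplicated(variants$id))
    stop("duplicate variant IDs: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(dosages)))
  if (anyDuplicated(samples)) stop("duplicate sample IDs")

  n_missing <- sum(is.na(dosages))
  if (n_missing > 0) {
    if (!impute_missing) stop(n_missing, " missing dosages and impute_missing = FALSE")
    mu <- colMeans(dosages, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2L]]
    message("imputed ", n_missing, " missing dosages to per-variant means")
  }
  if (any(!is.finite(dosages))) stop("non-finite dosages")
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9))
    stop("dosages outside [0, 2]")
  dosages[dosages < 0] <- 0
  dosages[dosages > 2] <- 2

  if (sort_variants) {
    ord <- order(variants$chrom, variants$pos)
    if (!identical(ord, seq_len(nrow(variants)))) {
      message("reordered variants by (chrom, pos)")
      variants <- variants[ord, , drop = FALSE]
      dosages <- dosages[, ord, drop = FALSE]
    }
  }
  rownames(variants) <- NULL
  dimnames(dosages) <- list(samples, variants$id)

  structure(list(dosages = dosages, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_variants(x), "variants\n")
  invisible(x)
}

#' Number of samples / variants
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname n_samples
#' @export
n_variants <- function(g) nrow(g$variants)

#' Per-variant minor allele frequency
#'
#' MAF computed as `min(f, 1 - f)` with `f = mean(dosage) / 2`.
#'
#' @param g a `genotype_matrix`.
#' @return named numeric vector of MAFs.
#' @export
geno_maf <- function(g) {
  f <- colMeans(g$dosages) / 2
  setNames(pmin(f, 1 - f), g$variants$id)
}

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param variants variant index or ID vector (NULL keeps all).
#' @param samples sample index or ID vector (NULL keeps all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(n_variants(g)) else {
    if (is.character(variants)) match(variants, g$variants$id) else variants
  }
  if (anyNA(vi)) stop("unknown variant IDs requested")
  si <- if (is.null(samples)) seq_len(n_samples(g)) else {
    if (is.character(samples)) match(samples, g$samples) else samples
  }
  if (anyNA(si)) stop("unknown sample IDs requested")
  genotype_matrix(g$dosages[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  samples = g$samples[si],
                  sort_variants = FALSE)
}

#' Drop low-frequency and zero-variance variants
#'
#' @param g a `genotype_matrix`.
#' @param maf_min keep variants with MAF strictly greater than this.
#' @return a filtered `genotype_matrix`; the number dropped is messaged.
#' @export
filter_variants <- function(g, maf_min = 0.05) {
  keep <- geno_maf(g) > maf_min & apply(g$dosages, 2L, stats::var) > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) message("dropped ", n_drop, " variants (MAF <= ", maf_min,
                          " or zero variance)")
  subset_genotypes(g, variants = which(keep))
}
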