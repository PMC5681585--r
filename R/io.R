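#' Read a genotype dosage matrix
#'
#' Two on-disk formats are supported. VCF (via `VariantAnnotation`): the
#' `DS` FORMAT field is used when present, otherwise `GT` calls are summed
#' to alternate-allele dosages; missing entries are mean-imputed with the
#' count logged; multi-allelic records are skipped or split per
#' `multiallelic`. Dosage TSV: header row of sample IDs after the five
#' fixed columns `variant_id`, `chrom`, `pos`, `ref`, `alt`; `.` denotes
#' missing.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param multiallelic `"skip"` or `"split"` multi-allelic VCF records.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           multiallelic = c("skip", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path, multiallelic)
  else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path, multiallelic) {
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt > 1L)) {
    if (multiallelic == "split") {
      vcf <- VariantAnnotation::expand(vcf)
      message("split ", sum(nalt > 1L), " multi-allelic records")
    } else {
      message("skipped ", sum(nalt > 1L), " multi-allelic records")
      vcf <- vcf[nalt == 1L]
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    dos <- gen$DS
    storage.mode(dos) <- "double"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1L]] == "1")
    })
  } else stop("VCF carries neither DS nor GT genotype fields")
  alt_chr <- vapply(seq_along(rr), function(i)
    as.character(VariantAnnotation::alt(vcf)[[i]][1L]), character(1))
  ids <- names(rr)
  if (is.null(ids))
    ids <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr),
                 as.character(VariantAnnotation::ref(vcf)), alt_chr, sep = ":")
  variants <- data.frame(
    id = make.unique(ids),   # split multi-allelics share a VCF ID
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr,
    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, samples = colnames(dos))
}

read_genotypes_dosage <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "."))
  fixed <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(fixed %in% names(tab)))
    stop("dosage TSV must start with columns: ", paste(fixed, collapse = ", "))
  samples <- setdiff(names(tab), fixed)
  if (length(samples) == 0L) stop("dosage TSV has no sample columns")
  dos <- t(as.matrix(tab[, samples, drop = FALSE]))
  storage.mode(dos) <- "double"
  variants <- data.frame(id = as.character(tab$variant_id),
                         chrom = as.character(tab$chrom),
                         pos = as.integer(tab$pos),
                         ref = as.character(tab$ref),
                         alt = as.character(tab$alt),
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples = samples)
}

#' Write a genotype matrix as dosage TSV
#'
#' @param g a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- cbind(data.frame(variant_id = g$variants$id, chrom = g$variants$chrom,
                          pos = g$variants$pos, ref = g$variants$ref,
                          alt = g$variants$alt, stringsAsFactors = FALSE),
               as.data.frame(t(g$dosages), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with gene IDs in the first column (`gene_id`) and one column per
#' sample.
#'
#' @param path input file.
#' @return numeric matrix, genes in rows (row names = gene IDs).
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "."))
  if (nrow(tab) == 0L) stop("empty expression file: ", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene IDs in expression file")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#' @param expr genes x samples matrix with row names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- cbind(data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE),
               as.data.frame(expr, check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation
#'
#' GFF3 (via `rtracklayer`; `gene` features with `gene_id` and `gene_type`
#' attributes) or 5-column TSV (`gene_id`, `chrom`, `tss`, `strand`,
#' `biotype`). The TSS is the feature start on the + strand and the feature
#' end on the - strand.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`, `biotype`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", path)
    strand <- as.character(GenomicRanges::strand(gr))
    genes <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      tss = ifelse(strand == "-", GenomicRanges::end(gr),
                   GenomicRanges::start(gr)),
      strand = ifelse(strand %in% c("+", "-"), strand, "unknown"),
      biotype = if (!is.null(gr$gene_type)) as.character(gr$gene_type)
                else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    genes <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss")
    if (!all(need %in% names(genes)))
      stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
    if (is.null(genes$strand)) genes$strand <- "unknown"
    if (is.null(genes$biotype)) genes$biotype <- NA_character_
    genes$chrom <- as.character(genes$chrom)
  }
  if (nrow(genes) == 0L) stop("empty annotation: ", path)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs in annotation")
  if (any(genes$tss < 1)) stop("TSS positions must be >= 1")
  genes
}

#' Read LD blocks from BED
#'
#' BED is 0-based half-open; internally a block covers the 1-based
#' positions `[start, end)` with `start = bed_start + 1` and
#' `end = bed_end`, so the BED line `chr6 25999999 34000000` becomes the
#' block 26,000,000-34,000,000 (length 8 Mb). The conversion is logged.
#'
#' @param path BED file (3+ columns; 4th column used as block ID when
#'   present).
#' @return an [ld_blocks()] table.
#' @export
read_blocks <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty BED file: ", path)
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns")
  blocks <- data.frame(chrom = as.character(tab[[1L]]),
                       start = as.numeric(tab[[2L]]) + 1,
                       end = as.numeric(tab[[3L]]),
                       stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) blocks$block_id <- as.character(tab[[4L]])
  message("converted ", nrow(blocks),
          " BED records from 0-based half-open to 1-based coordinates")
  ld_blocks(blocks)
}

#' Read a phenotype vector
#'
#' Two-column TSV `sample_id`, `value`; the type is inferred as binary when
#' all values are 0/1.
#'
#' @param path input file.
#' @return named numeric vector with attribute `type` in
#'   `{"binary", "continuous"}`.
#' @export
read_phenotype <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty phenotype file: ", path)
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop("phenotype TSV needs columns sample_id, value")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample IDs in phenotype")
  y <- setNames(as.numeric(tab$value), tab$sample_id)
  attr(y, "type") <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  y
}

format_pvalue <- function(p) {
  ifelse(is.na(p), ".", formatC(p, format = "e", digits = 6))
}

results_header <- function(extra = character(0)) {
  c(sprintf("# cisetest %s", as.character(packageVersion("cisetest"))),
    extra)
}

#' Write scan / enrichment / weight / power tables
#'
#' Tab-separated output with fixed column orders; p-values in scientific
#' notation with 6 significant digits; header comments record the tool
#' version and the run configuration (seeds, thresholds).
#'
#' @param res result object from [egene_scan()], [enrichment_folds()],
#'   [run_power_study()], [run_predixcan()] or [blue_weights()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(res, path) {
  tab <- as.data.frame(res)
  for (col in intersect(c("p_alrt", "p_elrt", "p_score"), names(tab)))
    tab[[col]] <- format_pvalue(tab[[col]])
  hdr <- results_header(c(
    sprintf("# alpha=%s bonferroni=%s n_tested=%s seed=%s",
            attr(res, "alpha"), attr(res, "bonferroni"),
            attr(res, "n_tested"), attr(res, "seed"))))
  write_with_header(tab, hdr, path)
}

#' @rdname write_scan_results
#' @export
write_enrichment <- function(res, path) {
  tab <- as.data.frame(res)[, c("block_id", "chrom", "start", "end",
                                "n_egenes", "fold")]
  write_with_header(tab, results_header(), path)
}

#' @rdname write_scan_results
#' @export
write_power_table <- function(res, path) {
  hdr <- results_header(sprintf("# alpha=%s seed=%s",
                                attr(res, "alpha"), attr(res, "seed")))
  write_with_header(as.data.frame(res), hdr, path)
}

#' @rdname write_scan_results
#' @export
write_predixcan <- function(res, path) {
  tab <- as.data.frame(res)
  tab$p <- format_pvalue(tab$p)
  hdr <- results_header(sprintf("# alpha=%s bonferroni=%s",
                                attr(res, "alpha"), attr(res, "bonferroni")))
  write_with_header(tab, hdr, path)
}

#' @rdname write_scan_results
#' @export
write_weights <- function(res, path) {
  tab <- data.frame(gene_id = attr(res, "gene_id"),
                    variant_id = res$variant_id, ref = res$ref, alt = res$alt,
                    weight = sprintf("%.17g", res$weight),
                    lambda_hat = attr(res, "lambda_hat"),
                    h2 = attr(res, "h2"), stringsAsFactors = FALSE)
  write_with_header(tab, results_header(), path)
}

#' Read a weights TSV back into a `blue_weights` table
#' @param path weights TSV written by [write_weights()].
#' @return a `blue_weights` table (single gene) or named list (several).
#' @export
read_weights <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  split_tabs <- split(tab, tab$gene_id)
  out <- lapply(split_tabs, function(t1) {
    structure(data.frame(variant_id = t1$variant_id, ref = t1$ref,
                         alt = t1$alt, weight = as.numeric(t1$weight),
                         stringsAsFactors = FALSE),
              class = c("blue_weights", "data.frame"),
              gene_id = t1$gene_id[1L],
              lambda_hat = t1$lambda_hat[1L], h2 = t1$h2[1L])
  })
  if (length(out) == 1L) out[[1L]] else out
}

write_with_header <- function(tab, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(tab) == 0L) {
    writeLines(paste(names(tab), collapse = "\t"), con)
  } else {
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  invisible(path)
}
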