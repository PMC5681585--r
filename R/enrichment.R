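#' LD-block table
#'
#' Validates approximately independent LD blocks. Internally a block covers
#' the 1-based positions `[start, end)` (half-open); its length is
#' `end - start` base pairs. Blocks must not overlap within a chromosome.
#'
#' @param blocks data.frame with `chrom`, `start`, `end` and optionally
#'   `block_id`.
#' @return validated data.frame of class `ld_blocks`.
#' @export
ld_blocks <- function(blocks) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(blocks)))
  if (any(blocks$end <= blocks$start)) stop("blocks must satisfy end > start")
  if (is.null(blocks$block_id))
    blocks$block_id <- sprintf("block%04d", seq_len(nrow(blocks)))
  if (anyDuplicated(blocks$block_id)) stop("duplicate block IDs")
  for (c in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == c, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop("overlapping LD blocks on chromosome ", c)
  }
  rownames(blocks) <- NULL
  class(blocks) <- c("ld_blocks", "data.frame")
  blocks
}

#' Assign genes to LD blocks by TSS
#'
#' A gene belongs to the unique block whose half-open interval
#' `[start, end)` contains its TSS; genes outside every block get `NA`.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param blocks an [ld_blocks()] table.
#' @return character vector of block IDs aligned with `genes` rows.
#' @export
assign_genes_to_blocks <- function(genes, blocks) {
  blocks <- ld_blocks(blocks)
  vapply(seq_len(nrow(genes)), function(i) {
    hit <- which(blocks$chrom == genes$chrom[i] &
                   blocks$start <= genes$tss[i] &
                   genes$tss[i] < blocks$end)
    if (length(hit) == 1L) blocks$block_id[hit] else NA_character_
  }, character(1))
}

#' eGene enrichment folds over LD blocks
#'
#' For each block, the enrichment fold is the ratio of the proportion of
#' eGenes to the proportion of length:
#' `fold_b = (g_b / G_c) / (l_b / L_c)`, with `g_b` the block's eGene count,
#' `G_c` the total eGenes in scope, `l_b = end - start`, and `L_c` the total
#' length in scope. Scope defaults to the chromosome; `L_c` defaults to the
#' summed block lengths, with `total_length` allowing an external total
#' (e.g. full chromosome length).
#'
#' @param results an [egene_scan()] result (or any data.frame with
#'   `gene_id`, `chrom`, `tss`, `egene_flag`).
#' @param blocks an [ld_blocks()] table.
#' @param scope `"chromosome"` or `"genome"`.
#' @param total_length optional named vector (per chromosome) or scalar
#'   (genome scope) overriding `L_c`.
#' @return data.frame of class `enrichment_result`: `block_id`, `chrom`,
#'   `start`, `end`, `length`, `n_egenes`, `total_egenes`, `fold`.
#' @export
enrichment_folds <- function(results, blocks, scope = c("chromosome", "genome"),
                             total_length = NULL) {
  scope <- match.arg(scope)
  blocks <- ld_blocks(blocks)
  eg <- results[results$egene_flag, , drop = FALSE]
  if (nrow(eg) == 0L) stop("no eGenes in scope")
  eg$block <- assign_genes_to_blocks(eg, blocks)

  out <- blocks
  out$length <- out$end - out$start
  out$n_egenes <- vapply(out$block_id, function(b)
    sum(!is.na(eg$block) & eg$block == b), integer(1))
  out$scope <- if (scope == "chromosome") out$chrom else "genome"

  out$total_egenes <- NA_integer_
  out$fold <- NA_real_
  for (sc in unique(out$scope)) {
    in_sc <- out$scope == sc
    Gc <- if (scope == "chromosome") sum(eg$chrom == sc) else nrow(eg)
    if (Gc == 0L) {
      warning("scope ", sc, " has no eGenes; skipped")
      next
    }
    Lc <- if (is.null(total_length)) {
      sum(out$length[in_sc])
    } else if (scope == "chromosome") {
      if (is.null(names(total_length)) && length(total_length) == 1L)
        total_length else unname(total_length[sc])
    } else sum(total_length)
    out$total_egenes[in_sc] <- Gc
    out$fold[in_sc] <- (out$n_egenes[in_sc] / Gc) / (out$length[in_sc] / Lc)
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Approximate z-test for a block's enrichment fold
#'
#' Compares the target block's fold with the mean and standard deviation of
#' the folds of the other blocks in the same scope:
#' `z = (fold_target - mean(others)) / sd(others)`, one-sided upper
#' p-value from the standard normal. The median of the other folds is
#' reported alongside for descriptive comparison.
#'
#' @param folds an [enrichment_folds()] table.
#' @param block_id target block.
#' @return list with `z`, `p`, `fold`, `mean_others`, `sd_others`,
#'   `median_others`, `n_others`.
#' @export
block_ztest <- function(folds, block_id) {
  i <- match(block_id, folds$block_id)
  if (is.na(i)) stop("unknown block: ", block_id)
  others <- folds$fold[folds$scope == folds$scope[i] &
                         folds$block_id != block_id]
  others <- others[!is.na(others)]
  if (length(others) < 3L) stop("need at least 3 other blocks in scope")
  s <- sd(others)
  if (s == 0) stop("zero variance among other blocks' folds")
  z <- (folds$fold[i] - mean(others)) / s
  list(z = z, p = pnorm(z, lower.tail = FALSE), fold = folds$fold[i],
       mean_others = mean(others), sd_others = s,
       median_others = median(others), n_others = length(others))
}
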