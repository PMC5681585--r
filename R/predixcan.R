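#' Harmonize trained weights with a target genotype panel
#'
#' Matches trained variants to the target panel by variant ID (optionally
#' falling back to `chrom:pos`) and enforces allele consistency: exact
#' ref/alt matches are kept; swapped alleles flip the weight sign (the
#' imputed expression then differs only by an additive constant, which the
#' downstream regression absorbs); strand-ambiguous pairs (A/T, C/G) whose
#' alleles do not match exactly are dropped, as are other mismatches and
#' unmatched variants. All drops are counted.
#'
#' @param weights a [blue_weights()] table (needs `variant_id`, `ref`,
#'   `alt`, `weight`).
#' @param G target `genotype_matrix`.
#' @param by_position fall back to `chrom:pos` keys for IDs missing in the
#'   target panel.
#' @return list with `weights` (aligned numeric vector), `dosages`
#'   (samples x matched variants), `variant_id`, and drop counters
#'   `n_train`, `n_matched`, `n_flipped`, `n_unmatched`,
#'   `n_dropped_ambiguous`, `n_dropped_mismatch`.
#' @export
harmonize_weights <- function(weights, G, by_position = FALSE) {
  tv <- G$variants
  idx <- match(weights$variant_id, tv$id)
  if (by_position) {
    key_t <- paste(tv$chrom, tv$pos, sep = ":")
    miss <- is.na(idx) & !is.na(weights$chrom) & !is.na(weights$pos)
    if (any(miss))
      idx[miss] <- match(paste(weights$chrom[miss], weights$pos[miss], sep = ":"),
                         key_t)
  }
  n_train <- nrow(weights)
  keep <- integer(0); wvals <- numeric(0)
  n_flip <- n_amb <- n_mis <- 0L
  ambiguous <- function(a, b) {
    pair <- paste(sort(c(toupper(a), toupper(b))), collapse = "/")
    pair %in% c("A/T", "C/G")
  }
  for (i in seq_len(n_train)) {
    j <- idx[i]
    if (is.na(j)) next
    r1 <- toupper(weights$ref[i]); a1 <- toupper(weights$alt[i])
    r2 <- toupper(tv$ref[j]); a2 <- toupper(tv$alt[j])
    if (is.na(r1) || is.na(a1) || is.na(r2) || is.na(a2) ||
        (r1 == r2 && a1 == a2)) {
      keep <- c(keep, j); wvals <- c(wvals, weights$weight[i])
    } else if (r1 == a2 && a1 == r2) {
      if (ambiguous(r1, a1)) { n_amb <- n_amb + 1L } else {
        keep <- c(keep, j); wvals <- c(wvals, -weights$weight[i])
        n_flip <- n_flip + 1L
      }
    } else {
      n_mis <- n_mis + 1L
    }
  }
  n_unmatched <- sum(is.na(idx))
  if (length(keep) == 0L) stop("zero matched variants after harmonization")
  list(weights = wvals,
       dosages = G$dosages[, keep, drop = FALSE],
       variant_id = tv$id[keep],
       n_train = n_train, n_matched = length(keep), n_flipped = n_flip,
       n_unmatched = n_unmatched, n_dropped_ambiguous = n_amb,
       n_dropped_mismatch = n_mis)
}

#' Impute gene expression from harmonized weights
#'
#' `e_hat = G beta_hat` over the matched variants.
#'
#' @param harmonized output of [harmonize_weights()].
#' @return numeric vector, one imputed expression value per target sample.
#' @export
impute_expression <- function(harmonized) {
  as.numeric(harmonized$dosages %*% harmonized$weights)
}

#' Test imputed expression against a phenotype
#'
#' Binary phenotypes are tested by logistic regression of the phenotype on
#' the imputed expression (plus covariates) with a Wald test on the
#' expression coefficient; continuous phenotypes use ordinary least
#' squares. Complete separation in the logistic fit triggers a Firth
#' penalized fallback (flagged in the result).
#'
#' @param ehat imputed expression vector.
#' @param y phenotype vector; `type` is inferred as binary when all values
#'   are 0/1.
#' @param covariates optional covariate matrix.
#' @param type `"auto"`, `"binary"` or `"continuous"`.
#' @return list with `effect`, `se`, `p`, `type`, `firth` (fallback flag).
#' @export
association_test <- function(ehat, y, covariates = NULL,
                             type = c("auto", "binary", "continuous")) {
  type <- match.arg(type)
  if (length(ehat) != length(y)) stop("ehat and y lengths differ")
  if (stats::var(ehat) == 0) stop("constant imputed expression")
  if (length(unique(y)) < 2L) stop("phenotype has fewer than 2 distinct values")
  if (type == "auto") type <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  dat <- data.frame(.y = y, ehat = ehat)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    dat <- cbind(dat, as.data.frame(covariates))
  }
  if (type == "continuous") {
    fit <- lm(.y ~ ., data = dat)
    cf <- summary(fit)$coefficients["ehat", ]
    return(list(effect = unname(cf[1L]), se = unname(cf[2L]),
                p = unname(cf[4L]), type = type, firth = FALSE))
  }
  if (!all(y %in% c(0, 1))) stop("binary phenotype must be coded 0/1")
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(cond)))
        invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  separated <- !fit$converged || all(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(coef(fit)) > 15)
  if (!separated) {
    cf <- summary(fit)$coefficients["ehat", ]
    return(list(effect = unname(cf[1L]), se = unname(cf[2L]),
                p = unname(cf[4L]), type = type, firth = FALSE))
  }
  ff <- firth_logistic(cbind(1, ehat, covariates), y)
  list(effect = ff$coef[2L], se = ff$se[2L],
       p = 2 * pnorm(-abs(ff$coef[2L] / ff$se[2L])),
       type = type, firth = TRUE)
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment);
# used only as a separation fallback, so a plain IRLS loop suffices.
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wv <- mu * (1 - mu)
    XW <- X * Wv
    info <- crossprod(X, XW)
    Cinv <- solve(info)
    h <- rowSums((X %*% Cinv) * XW)          # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- Cinv %*% U
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  list(coef = beta, se = sqrt(diag(solve(info))))
}

#' Gene-level association of imputed expression in a target cohort
#'
#' For every gene with training heritability strictly above `h2_min`,
#' harmonizes the trained weights with the target panel, imputes expression
#' and tests it against the phenotype, then applies Bonferroni control at
#' `alpha` over the tested genes.
#'
#' @param weights_db named list of [blue_weights()] tables (names = gene
#'   IDs), each carrying `lambda_hat`/`h2` attributes.
#' @param G target `genotype_matrix`.
#' @param y phenotype vector aligned with `G` samples.
#' @param covariates optional covariates.
#' @param h2_min strict lower bound on training heritability.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param by_position see [harmonize_weights()].
#' @return data.frame of class `predixcan_result`: `gene_id`, `n_train`,
#'   `n_matched`, `effect`, `se`, `p`, `h2`, `firth`, `significant`;
#'   attribute `bonferroni`.
#' @export
run_predixcan <- function(weights_db, G, y, covariates = NULL,
                          h2_min = 0.01, alpha = 0.05, by_position = FALSE) {
  h2s <- vapply(weights_db, function(w) attr(w, "h2"), numeric(1))
  keep <- names(weights_db)[h2s > h2_min]
  if (length(keep) == 0L) stop("no genes pass the heritability filter")
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    gid <- keep[i]
    w <- weights_db[[gid]]
    rows[[i]] <- tryCatch({
      h <- harmonize_weights(w, G, by_position = by_position)
      at <- association_test(impute_expression(h), y, covariates)
      data.frame(gene_id = gid, n_train = h$n_train, n_matched = h$n_matched,
                 effect = at$effect, se = at$se, p = at$p,
                 h2 = attr(w, "h2"), firth = at$firth,
                 stringsAsFactors = FALSE)
    }, error = function(err) {
      message("gene ", gid, " skipped: ", conditionMessage(err))
      NULL
    })
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) stop("all genes failed testing")
  threshold <- alpha / nrow(res)
  res$significant <- res$p <= threshold
  rownames(res) <- NULL
  attr(res, "bonferroni") <- threshold
  attr(res, "alpha") <- alpha
  class(res) <- c("predixcan_result", "data.frame")
  res
}
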