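#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Per-SNP allele frequencies are drawn uniformly between the MAF bounds;
#' dosages are the sum of two haplotypes. Linkage disequilibrium between
#' adjacent sites is induced through a latent Gaussian AR(1) process with
#' autocorrelation `rho` thresholded at the allele frequency (`rho = 0`
#' gives independent SNPs); the correlation is therefore on the latent
#' scale. Columns whose realized MAF does not exceed the lower bound are
#' redrawn (marginally, so extreme-frequency redraws slightly dilute LD).
#'
#' @param n samples.
#' @param p SNPs.
#' @param maf_range lower/upper bound of the allele-frequency distribution.
#' @param rho latent AR(1) correlation between adjacent sites in `[0, 1)`.
#' @param seed RNG seed.
#' @param chrom,pos_start,pos_step variant coordinates for the metadata.
#' @return a `genotype_matrix`.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), rho = 0,
                               seed = NULL, chrom = "1", pos_start = 1e6,
                               pos_step = 100L) {
  stopifnot(rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] < maf_range[2])
  if (!is.null(seed)) set.seed(seed)
  freq <- runif(p, maf_range[1], maf_range[2])
  thresh <- qnorm(freq)

  draw_haplotypes <- function() {
    # two latent AR(1) Gaussian haplotypes per sample, thresholded per SNP
    hap <- function() {
      z <- matrix(rnorm(n * p), n, p)
      if (rho > 0 && p > 1) {
        for (j in 2:p) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      sweep(z, 2L, thresh, "<") * 1
    }
    hap() + hap()
  }
  dos <- draw_haplotypes()
  # enforce realized MAF above the lower bound by redrawing offending columns
  for (tries in 1:100) {
    f <- colMeans(dos) / 2
    bad <- which(pmin(f, 1 - f) <= maf_range[1])
    if (length(bad) == 0L) break
    for (j in bad) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      dos[, j] <- (z1 < thresh[j]) + (z2 < thresh[j])
    }
  }
  variants <- data.frame(id = sprintf("snp%04d", seq_len(p)),
                         chrom = chrom,
                         pos = pos_start + (seq_len(p) - 1L) * pos_step,
                         ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants,
                  samples = sprintf("sample%04d", seq_len(n)),
                  sort_variants = FALSE)
}

#' Simulate gene expression from cis-SNP effects
#'
#' `e = Z beta + eps` with `beta ~ N(0, tau^2)` on a random subset of
#' `n_causal` columns and `eps ~ N(0, 1)`; `tau = 0` gives the global null
#' (iid standard-normal expression).
#'
#' @param Z `genotype_matrix` or dosage matrix.
#' @param tau2 effect-size variance tau^2.
#' @param n_causal number of causal SNPs (defaults to all columns).
#' @param seed RNG seed.
#' @return numeric phenotype vector with attributes `causal` (column
#'   indices) and `beta`.
#' @export
simulate_expression <- function(Z, tau2, n_causal = NULL, seed = NULL) {
  if (inherits(Z, "genotype_matrix")) Z <- Z$dosages
  p <- ncol(Z); n <- nrow(Z)
  if (is.null(n_causal)) n_causal <- p
  stopifnot(n_causal <= p, tau2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  causal <- sort(sample.int(p, n_causal))
  e <- rnorm(n)
  beta <- numeric(n_causal)
  if (tau2 > 0) {
    beta <- rnorm(n_causal, 0, sqrt(tau2))
    e <- e + as.numeric(Z[, causal, drop = FALSE] %*% beta)
  }
  attr(e, "causal") <- causal
  attr(e, "beta") <- beta
  e
}

#' Type-I-error and power study for eLRT and aLRT
#'
#' Reproduces the numerical-study design: one master genotype panel of `p`
#' SNPs; for each cell of the (tau^2, selected-SNP-count) grid a fixed
#' random subset of columns is both the tested SNP set and the causal set;
#' per replicate, fresh effects `beta ~ N(0, tau^2)` and noise generate the
#' phenotype, the restricted LRT statistic is computed in the shared
#' spectral basis, and power (or type-I error for `tau2 = 0`) is the
#' proportion of p-values below `alpha`. The exact test (eLRT) uses `M`
#' null draws per cell; the approximate test (aLRT) fits the point-mass /
#' scaled-chi-square mixture on an independent set of `L` draws.
#'
#' @param tau2 vector of effect-size variances (0 rows give type-I error).
#' @param n_snps vector of selected-SNP counts.
#' @param n,p sample size and master panel width.
#' @param R replicates per cell.
#' @param M exact-null draws per cell.
#' @param L approximate-null draws per cell (vector allowed).
#' @param alpha significance level.
#' @param maf_range,rho genotype-generator parameters.
#' @param mixture_method `kappa` estimator for the mixture fit.
#' @param include_score also report the score test per cell.
#' @param seed master seed; every cell derives its own child seeds.
#' @param Z optional pre-built master `genotype_matrix` (overrides n, p).
#' @return data.frame of class `power_table` with one row per
#'   (tau2, n_snps, method, L) cell: `estimate`, binomial Monte-Carlo `se`,
#'   `se_null` (power uncertainty induced by estimating the null threshold
#'   from finitely many draws; zero for the score test), `R`.
#' @export
run_power_study <- function(tau2 = c(0.03^2, 0.08^2, 0.10^2),
                            n_snps = c(10L, 25L, 50L, 75L, 100L),
                            n = 465L, p = 100L, R = 1e4, M = 1e5, L = 1e4,
                            alpha = 1e-4, maf_range = c(0.05, 0.5), rho = 0,
                            mixture_method = "moment",
                            include_score = FALSE, seed = 1L, Z = NULL) {
  R <- as.integer(R); M <- as.integer(M)
  seeds <- derive_seeds(seed, 1L + 3L * length(tau2) * length(n_snps) * (2L + length(L)))
  if (is.null(Z)) Z <- simulate_genotypes(n, p, maf_range, rho, seed = seeds[1L])
  n <- n_samples(Z); p <- n_variants(Z)
  stopifnot(max(n_snps) <= p)
  X <- design_matrix(n)

  out <- list()
  si <- 1L
  for (t2 in tau2) {
    for (m in n_snps) {
      si <- si + 1L
      set.seed(seeds[si]); cols <- sort(sample.int(p, m))
      Zc <- Z$dosages[, cols, drop = FALSE]
      sdc <- spectral_decompose(Zc, X)

      si <- si + 1L
      null_e <- simulate_null_draws(sdc, M = M, seed = seeds[si])
      mixes <- list()
      for (li in seq_along(L)) {
        si <- si + 1L
        mixes[[li]] <- fit_mixture(
          simulate_null_draws(sdc, M = as.integer(L[li]), seed = seeds[si]),
          method = mixture_method)
      }

      si <- si + 1L
      set.seed(seeds[si])
      E <- matrix(rnorm(n * R), n, R)
      if (t2 > 0) {
        beta <- matrix(rnorm(m * R, 0, sqrt(t2)), m, R)
        E <- E + Zc %*% beta
      }
      rot <- rotate_phenotypes(sdc, E)
      res <- cpp_sup_rlrt(rot$u2, rot$tail2, sdc$xi, sdc$dof,
                          default_lambda_grid(), 60L, ZERO_TOL)
      Tstat <- res$T

      # local density of the alternative statistics near a threshold; used
      # to propagate null-threshold estimation noise into the power SE
      f_alt <- function(thr) {
        h <- max(0.5, 0.05 * thr)
        mean(abs(Tstat - thr) <= h) / (2 * h)
      }
      mix1 <- mixes[[1L]]
      null_density <- function(t)
        (1 - mix1$phi) * stats::dchisq(t / mix1$kappa, 1) / mix1$kappa

      cell <- function(method, Lval, pvals, se_null = 0) {
        est <- mean(pvals < alpha)
        data.frame(tau2 = t2, n_snps = m, method = method,
                   L = Lval, estimate = est,
                   se = sqrt(est * (1 - est) / R),
                   se_null = se_null, R = R,
                   stringsAsFactors = FALSE)
      }
      # eLRT: the empirical (1 - alpha) null quantile carries Monte-Carlo
      # noise sd ~ sqrt(alpha (1 - alpha) / M) / f_null(threshold)
      thr_e <- as.numeric(stats::quantile(null_e$draws, 1 - alpha, type = 1))
      sd_thr_e <- sqrt(alpha * (1 - alpha) / M) / max(null_density(thr_e), 1e-12)
      rows <- list(cell("elrt", M, exact_pvalue(Tstat, null_e),
                        se_null = f_alt(thr_e) * sd_thr_e))
      for (li in seq_along(L)) {
        mx <- mixes[[li]]
        qa <- qchisq(min(alpha / (1 - mx$phi), 1), 1, lower.tail = FALSE)
        thr_a <- mx$kappa * qa
        # mixture-threshold noise from the kappa and phi estimates
        sd_thr_a <- sqrt((qa * mx$kappa_se)^2 +
                           (mx$kappa * (alpha / (1 - mx$phi)^2) /
                              stats::dchisq(qa, 1) * mx$phi_se)^2)
        rows[[length(rows) + 1L]] <-
          cell("alrt", as.integer(L[li]), mixture_pvalue(Tstat, mixes[[li]]),
               se_null = f_alt(thr_a) * sd_thr_a)
      }
      if (include_score) {
        S <- colSums(sdc$xi * rot$u2) / rot$rss
        pv <- vapply(S, score_ratio_pvalue, numeric(1),
                     xi = sdc$xi, dof = sdc$dof)
        rows[[length(rows) + 1L]] <- cell("score", NA_integer_, pv)
      }
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  class(res) <- c("power_table", "data.frame")
  res
}
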