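#' REML fit of the one-variance-component mixed model
#'
#' Maximizes the restricted log-likelihood over the signal-to-noise ratio
#' `lambda >= 0` by a bracketed search: evaluation on a fixed log-spaced grid
#' (101 points on log10(lambda) in \[-5, 5\], with the boundary `lambda = 0`
#' as reference) followed by golden-section refinement inside the bracketing
#' interval. The boundary LRT statistic is
#' `T = 2 * (l_R(lambda_hat) - l_R(0))`, clipped at zero; values below the
#' zero tolerance are snapped to exactly zero so the point mass of the
#' boundary null is represented faithfully. The identical search is used to
#' simulate the null distribution (see [simulate_null_draws()]), so observed
#' and null statistics share the same discretization.
#'
#' @param sd a `spectral_decomp` built with a phenotype.
#' @param grid positive lambda grid for the bracketing pass.
#' @param refine_iter golden-section iterations for the polish.
#' @param zero_tol statistics below this are treated as exactly 0.
#' @return An object of class `reml_fit`: `lambda_hat`, `sigma2_hat`,
#'   `tau2_hat`, `h2` (= lambda/(1+lambda)), `T`, `loglik_alt`,
#'   `loglik_null`, `b_hat` (GLS fixed effects), `converged`, plus the
#'   decomposition used.
#' @export
fit_reml <- function(sd, grid = default_lambda_grid(), refine_iter = 60L,
                     zero_tol = ZERO_TOL) {
  check_phenotype(sd)
  if (sd$K == 0L) {
    lam <- 0; Tstat <- 0
  } else {
    res <- cpp_sup_rlrt(matrix(sd$u^2, ncol = 1L), sd$tail2, sd$xi,
                        sd$dof, grid, as.integer(refine_iter), zero_tol)
    lam <- res$lambda[1L]
    Tstat <- res$T[1L]
  }
  converged <- TRUE
  if (sd$K > 0L && lam >= max(grid) * (1 - 1e-10)) {
    warning("lambda estimate at the upper search bound; flagged as non-converged")
    converged <- FALSE
  }
  ll0 <- restricted_loglik(sd, 0)
  denom <- 1 + lam * sd$xi
  sigma2 <- (sum(sd$u^2 / denom) + sd$tail2) / sd$dof
  structure(list(lambda_hat = lam,
                 sigma2_hat = sigma2,
                 tau2_hat = lam * sigma2,
                 h2 = lam / (1 + lam),
                 T = Tstat,
                 loglik_null = ll0,
                 loglik_alt = ll0 + Tstat / 2,
                 b_hat = gls_fixed_effects(sd, lam),
                 converged = converged,
                 sd = sd),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit: lambda_hat =", signif(x$lambda_hat, 4),
      " h2 =", signif(x$h2, 4), " T =", signif(x$T, 4), "\n")
  invisible(x)
}

# Solve V^{-1} y with V = lambda Z Z' + I through the Woodbury identity
# (p x p solve; no n x n inverse is materialized).
vinv_mult <- function(Z, lambda, y) {
  if (lambda == 0) return(y)
  p <- ncol(Z)
  M <- crossprod(Z) + diag(p) / lambda
  y - Z %*% solve(M, crossprod(Z, y))
}

# GLS estimate of the fixed effects at a given lambda.
gls_fixed_effects <- function(sd, lambda) {
  ViX <- vinv_mult(sd$Z, lambda, sd$X)
  Vie <- vinv_mult(sd$Z, lambda, sd$e)
  b <- solve(crossprod(sd$X, ViX), crossprod(sd$X, Vie))
  setNames(as.numeric(b), colnames(sd$X))
}

#' Variance-component score test
#'
#' Score statistic for H0: lambda = 0,
#' `Q = sum_s xi_s u_s^2 / (2 sigma0^4)` with `sigma0^2` the null residual
#' variance. Because `sigma0^2` is estimated from the same residuals, the
#' p-value is computed from the scale-free ratio form
#' `S = sum_s xi_s u_s^2 / RSS`, whose null distribution involves the same
#' weighted chi-square mixture but stays calibrated under variance
#' estimation: `P(S_null >= S) = P(sum_s (xi_s - S) w_s^2 - S chi2_{dof-K}
#' >= 0)` with iid standard-normal `w_s`. The default evaluates this tail by
#' Liu-type moment matching of the (indefinite) quadratic form; `"mc"`
#' simulates the ratio null directly.
#'
#' @param sd a `spectral_decomp` built with a phenotype.
#' @param method `"liu"` (moment-matched non-central chi-square tail) or
#'   `"mc"` (Monte Carlo on the ratio-statistic null).
#' @param mc_draws draws for the Monte Carlo tail.
#' @param seed RNG seed for `method = "mc"`.
#' @return list with `statistic` (Q) and `p_value` (in (0, 1\]).
#' @export
score_test <- function(sd, method = c("liu", "mc"), mc_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  check_phenotype(sd)
  sigma2_0 <- sd$rss / sd$dof
  if (sd$K == 0L) return(list(statistic = 0, p_value = 1))
  num <- sum(sd$xi * sd$u^2)
  Q <- num / (2 * sigma2_0^2)
  if (Q <= 0) return(list(statistic = 0, p_value = 1))
  p <- if (method == "liu") {
    score_ratio_pvalue(num / sd$rss, sd$xi, sd$dof)
  } else {
    if (!is.null(seed)) set.seed(seed)
    K <- sd$K
    W2 <- matrix(rchisq(K * mc_draws, df = 1), K)
    tail2 <- if (sd$dof > K) rchisq(mc_draws, sd$dof - K) else numeric(mc_draws)
    Snull <- colSums(sd$xi * W2) / (colSums(W2) + tail2)
    (sum(Snull >= num / sd$rss) + 1) / (mc_draws + 1)
  }
  list(statistic = Q, p_value = min(max(p, 1e-300), 1))
}

# Tail of the ratio statistic S = sum xi u^2 / RSS at its observed value,
# via Liu moment matching on the indefinite quadratic form
# sum_{s<=K} (xi_s - S) w_s^2 - S * chi2_{dof-K}.
score_ratio_pvalue <- function(S, xi, dof) {
  K <- length(xi)
  w1 <- xi - S
  c1 <- sum(w1) - (dof - K) * S
  c2 <- sum(w1^2) + (dof - K) * S^2
  c3 <- sum(w1^3) - (dof - K) * S^3
  c4 <- sum(w1^4) + (dof - K) * S^4
  liu_pvalue_moments(0, c1, c2, c3, c4)
}

# Liu et al. (2009) moment-matching tail approximation P(Q >= q) for a
# (possibly indefinite) quadratic form in standard normals, given the first
# four cumulant-style moments c_k = sum(weights^k).
liu_pvalue_moments <- function(q, c1, c2, c3, c4) {
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  pchisq(tstar * sqrt(2) * a + l + d, df = l, ncp = d, lower.tail = FALSE)
}

# Positive-weight convenience wrapper (tail of sum_s w_s chi2_1 at q).
liu_pvalue <- function(q, w) {
  liu_pvalue_moments(q, sum(w), sum(w^2), sum(w^3), sum(w^4))
}

#' Best linear unbiased estimator (BLUE) of cis-SNP effects
#'
#' Computes `beta_hat = lambda_hat Z' V^{-1} (e - X b_hat)` with
#' `V = lambda_hat Z Z' + I`, evaluated through the Woodbury identity so no
#' n x n inverse is formed. With `lambda_hat = 0` the weights are exactly
#' zero. The result doubles as the per-gene weight vector for expression
#' imputation in an independent cohort.
#'
#' @param fit a `reml_fit`.
#' @return An object of class `blue_weights`: data.frame with columns
#'   `variant_id`, `ref`, `alt`, `weight`, and attributes `gene_id`,
#'   `lambda_hat`, `h2`.
#' @export
blue_weights <- function(fit) {
  if (!inherits(fit, "reml_fit")) stop("fit must be a reml_fit")
  sd <- fit$sd
  lam <- fit$lambda_hat
  if (is.null(lam)) stop("lambda estimate unset")
  if (lam == 0) {
    beta <- numeric(sd$p)
  } else {
    r <- sd$e - as.numeric(sd$X %*% fit$b_hat)
    beta <- lam * as.numeric(crossprod(sd$Z, vinv_mult(sd$Z, lam, r)))
  }
  ids <- colnames(sd$Z)
  if (is.null(ids)) ids <- paste0("snp", seq_len(sd$p))
  w <- data.frame(variant_id = ids,
                  ref = if (!is.null(sd$variants)) sd$variants$ref else NA_character_,
                  alt = if (!is.null(sd$variants)) sd$variants$alt else NA_character_,
                  weight = beta,
                  stringsAsFactors = FALSE)
  structure(w, class = c("blue_weights", "data.frame"),
            gene_id = NA_character_, lambda_hat = lam, h2 = fit$h2)
}
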