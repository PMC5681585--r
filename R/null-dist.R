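#' Simulate the exact null distribution of the boundary LRT statistic
#'
#' Draws from the null distribution of the restricted LRT statistic using
#' the spectral representation: for each draw, standard-normal coefficients
#' are sampled in the rotated basis (the `dof - K` components beyond the
#' positive eigenvalues are collapsed into a single chi-square variate,
#' which is exact in distribution) and the statistic
#' `sup_{lambda>=0} [ dof log(S(0)/S(lambda)) - sum_s log(1 + lambda xi_s) ]`
#' is maximized with the same bracketed grid-plus-golden-section search used
#' by [fit_reml()], then clipped at zero. Only the eigenvalues `xi` and
#' `dof` enter, so one draw set serves every phenotype tested against the
#' same genotype set.
#'
#' @param sd a `spectral_decomp` (phenotype not required).
#' @param M number of draws (>= 1).
#' @param seed RNG seed; draws are bit-reproducible given (seed, M, xi).
#' @param grid,refine_iter,zero_tol search parameters shared with
#'   [fit_reml()].
#' @param block_size draws are generated and maximized in blocks of this
#'   size to bound memory.
#' @return An object of class `exact_null`: sorted nonnegative `draws`,
#'   `M`, `seed`, and an eigenvalue `fingerprint`.
#' @export
simulate_null_draws <- function(sd, M, seed = NULL,
                                grid = default_lambda_grid(),
                                refine_iter = 60L, zero_tol = ZERO_TOL,
                                block_size = 16384L) {
  if (sd$K == 0L) stop("no positive eigenvalues: the set test is undefined (K = 0)")
  M <- as.integer(M)
  if (M < 1L) stop("M must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  K <- sd$K; dof <- sd$dof
  tail_df <- dof - K
  draws <- numeric(M)
  done <- 0L
  while (done < M) {
    b <- min(block_size, M - done)
    u2 <- matrix(rnorm(K * b)^2, nrow = K, ncol = b)
    tail2 <- if (tail_df > 0L) rchisq(b, df = tail_df) else numeric(b)
    res <- cpp_sup_rlrt(u2, tail2, sd$xi, dof, grid,
                        as.integer(refine_iter), zero_tol)
    draws[(done + 1L):(done + b)] <- res$T
    done <- done + b
  }
  structure(list(draws = sort(draws), M = M, seed = seed,
                 fingerprint = null_fingerprint(sd)),
            class = "exact_null")
}

null_fingerprint <- function(sd) {
  sprintf("K=%d;dof=%d;sum_xi=%.10g;sum_xi2=%.10g",
          sd$K, sd$dof, sum(sd$xi), sum(sd$xi^2))
}

#' @export
print.exact_null <- function(x, ...) {
  cat("exact_null:", x$M, "draws; P(T = 0) =",
      signif(mean(x$draws <= ZERO_TOL), 4), "\n")
  invisible(x)
}

#' Empirical p-value from simulated null draws
#'
#' `p = (#\{draws >= T\} + 1) / (M + 1)`; the plus-one keeps p-values valid
#' (never zero) at the cost of a floor of `1/(M + 1)`.
#'
#' @param T observed statistic(s), nonnegative; vectorized.
#' @param null an `exact_null`.
#' @return p-values in `[1/(M+1), 1]`.
#' @export
exact_pvalue <- function(T, null) {
  if (any(T < 0)) stop("T must be nonnegative")
  # draws are sorted ascending; count strictly-below with a tie guard so
  # T = 0 counts every zero draw as >= T
  n_lt <- findInterval(T - 1e-12, null$draws)
  (null$M - n_lt + 1) / (null$M + 1)
}

#' Fit the point-mass/scaled-chi-square mixture null
#'
#' Approximates the boundary-LRT null by
#' `phi * chi2_0 + (1 - phi) * kappa * chi2_1`, where `chi2_0` is a point
#' mass at zero. `phi` is the fraction of (numerically) zero draws. The
#' scale `kappa` is estimated from the positive draws by the method of
#' moments (`kappa = mean`, since E chi2_1 = 1), by single-quantile matching
#' (`kappa = median / qchisq(0.5, 1)`), or by least-squares matching of a
#' grid of empirical quantiles against chi-square(1) quantiles
#' (`"quantile_grid"`). The "local probability" estimator named in the
#' literature is not defined in the available sources and is left as an
#' explanatory stub.
#'
#' @param null an `exact_null` whose draws (L of them, L >= 100) train the
#'   mixture.
#' @param method one of `"moment"`, `"quantile"`, `"quantile_grid"`,
#'   `"local"`.
#' @param zero_tol draws at or below this count as the point mass.
#' @return An object of class `mixture_null` with `phi`, `kappa`, `L`,
#'   `method`.
#' @export
fit_mixture <- function(null, method = c("moment", "quantile", "quantile_grid",
                                         "local"),
                        zero_tol = ZERO_TOL) {
  method <- match.arg(method)
  if (method == "local")
    stop("the 'method of local probability' is not implemented: ",
         "no defining formula is available; use 'moment' or 'quantile'")
  draws <- null$draws
  L <- length(draws)
  if (L < 100L) stop("need at least 100 null draws to fit the mixture")
  zero <- draws <= zero_tol
  pos <- draws[!zero]
  if (length(pos) < 1L) stop("no positive null draws; mixture fit is degenerate")
  phi <- mean(zero)
  kappa <- switch(method,
    moment = mean(pos),
    quantile = median(pos) / qchisq(0.5, df = 1),
    quantile_grid = {
      tau <- seq(0.05, 0.95, by = 0.05)
      qe <- as.numeric(stats::quantile(pos, tau, type = 7))
      qc <- qchisq(tau, df = 1)
      sum(qe * qc) / sum(qc^2)
    })
  if (!is.finite(kappa) || kappa <= 0) stop("kappa estimate is not positive")
  structure(list(phi = phi, kappa = kappa, L = L, method = method,
                 # sampling uncertainty of the estimators (used to propagate
                 # null-estimation noise into power-study standard errors)
                 kappa_se = sd(pos) / sqrt(length(pos)),
                 phi_se = sqrt(phi * (1 - phi) / L),
                 n_pos = length(pos),
                 seed = null$seed, fingerprint = null$fingerprint),
            class = "mixture_null")
}

#' @export
print.mixture_null <- function(x, ...) {
  cat(sprintf("mixture_null: phi = %.4f, kappa = %.4f (L = %d, %s)\n",
              x$phi, x$kappa, x$L, x$method))
  invisible(x)
}

#' p-value under the mixture null
#'
#' `p = 1` for statistics at the zero point mass, otherwise
#' `p = (1 - phi) * P(chi2_1 > T / kappa)`; monotone nonincreasing in `T`.
#'
#' @param T observed statistic(s), nonnegative; vectorized.
#' @param mix a `mixture_null`.
#' @param zero_tol statistics at or below this take p = 1.
#' @return p-values in (0, 1\].
#' @export
mixture_pvalue <- function(T, mix, zero_tol = ZERO_TOL) {
  if (any(T < 0)) stop("T must be nonnegative")
  p <- (1 - mix$phi) * pchisq(T / mix$kappa, df = 1, lower.tail = FALSE)
  p[T <= zero_tol] <- 1
  pmin(pmax(p, 1e-300), 1)
}

#' Persist / restore simulated null draws
#'
#' Two-column TSV (draw index, statistic) with header comments recording the
#' seed, the draw count, and the eigenvalue fingerprint.
#'
#' @param null an `exact_null`.
#' @param path output file path.
#' @return `write_null_draws` returns `path` invisibly; `read_null_draws`
#'   returns an `exact_null`.
#' @export
write_null_draws <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cisetest %s null draws", as.character(packageVersion("cisetest"))),
               sprintf("# seed=%s M=%d", ifelse(is.null(null$seed), "NA", null$seed), null$M),
               sprintf("# fingerprint=%s", null$fingerprint),
               "index\tstatistic"), con)
  writeLines(sprintf("%d\t%.17g", seq_len(null$M), null$draws), con)
  invisible(path)
}

#' @rdname write_null_draws
#' @export
read_null_draws <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  seed <- suppressWarnings(as.integer(sub(".*seed=([^ ]+).*", "\\1", meta[2L])))
  fp <- sub("# fingerprint=", "", meta[3L], fixed = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(draws = sort(as.numeric(tab$statistic)),
                 M = nrow(tab),
                 seed = if (is.na(seed)) NULL else seed,
                 fingerprint = fp),
            class = "exact_null")
}
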