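#' Fixed-effect design matrix
#'
#' Builds the covariate matrix X with a leading intercept column. Including
#' the intercept is equivalent to centering the phenotype and stays correct
#' when further covariates are added.
#'
#' @param n number of samples.
#' @param covariates optional numeric matrix/data.frame of additional columns.
#' @return numeric matrix with `n` rows and full column rank.
#' @export
design_matrix <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates have wrong number of rows")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("covariate matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  X
}

#' Spectral decomposition of the projected genotype cross-product
#'
#' Projects genotypes orthogonally to the covariate column space (projector
#' P0) and eigen-decomposes Z' P0 Z. In the resulting basis the covariance
#' of the mixed model is diagonal, so the restricted likelihood is a sum over
#' eigenvalues and the boundary LRT null can be simulated cheaply.
#'
#' @param Z `genotype_matrix` or plain numeric n x p dosage matrix.
#' @param X covariate matrix (intercept added via [design_matrix()] when
#'   `NULL`); must have full column rank and fewer columns than samples.
#' @param e optional length-n phenotype; when supplied, the rotated data `u`
#'   and residual tail are stored so the decomposition is self-contained for
#'   fitting.
#' @param tol eigenvalues below `tol * max(xi)` are treated as zero.
#' @return An object of class `spectral_decomp` with elements `xi` (K
#'   positive eigenvalues, descending), `K`, `dof` = n - q, `u` (length-K
#'   rotated data), `tail2` (residual sum of squares beyond the K-space),
#'   `rss` (= `sum(u^2) + tail2` = squared norm of P0 e), plus the rotation
#'   handles needed to rotate new phenotypes.
#' @export
spectral_decompose <- function(Z, X = NULL, e = NULL, tol = 1e-8) {
  variants <- NULL
  if (inherits(Z, "genotype_matrix")) {
    variants <- Z$variants
    Z <- Z$dosages
  }
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (is.null(X)) X <- design_matrix(n)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and Z disagree on sample count")
  q <- ncol(X)
  if (n <= q) stop("need more samples than covariate columns (n > q)")
  qrX <- qr(X)
  if (qrX$rank < q) {
    nms <- colnames(X)
    if (is.null(nms)) nms <- paste0("X", seq_len(q))
    dep <- nms[qrX$pivot[(qrX$rank + 1L):q]]
    stop("covariate matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  Qfull <- qr.Q(qrX, complete = TRUE)
  Q2 <- Qfull[, (q + 1L):n, drop = FALSE]      # orthonormal basis of P0 space

  A <- crossprod(Q2, Z)                        # (n - q) x p
  dof <- n - q
  if (p == 0L || max(abs(A)) == 0) {
    xi <- numeric(0); K <- 0L
    U <- matrix(0, dof, 0L)
  } else if (p <= dof) {
    ev <- eigen(crossprod(A), symmetric = TRUE)      # p x p
    pos <- ev$values > tol * max(ev$values)
    xi <- ev$values[pos]
    K <- length(xi)
    U <- A %*% sweep(ev$vectors[, pos, drop = FALSE], 2L, sqrt(xi), "/")
  } else {
    ev <- eigen(tcrossprod(A), symmetric = TRUE)     # (n-q) x (n-q)
    pos <- ev$values > tol * max(ev$values)
    xi <- ev$values[pos]
    K <- length(xi)
    U <- ev$vectors[, pos, drop = FALSE]
  }

  sd_obj <- structure(list(xi = xi, K = K, dof = dof, n = n, q = q, p = p,
                           U = U, Q2 = Q2, X = X, Z = Z,
                           variants = variants,
                           u = NULL, tail2 = NULL, rss = NULL, e = NULL),
                      class = "spectral_decomp")
  if (!is.null(e)) {
    rot <- rotate_phenotypes(sd_obj, matrix(as.numeric(e), ncol = 1L))
    sd_obj$u <- if (K > 0) rot$u_signed[, 1L] else numeric(0)
    sd_obj$tail2 <- rot$tail2[1L]
    sd_obj$rss <- rot$rss[1L]
    sd_obj$e <- as.numeric(e)
  }
  sd_obj
}

#' Rotate phenotypes into the spectral basis
#'
#' @param sd a `spectral_decomp`.
#' @param E numeric matrix with one phenotype per column (n rows).
#' @return list with `u2` (K x B squared coefficients), `u_signed` (K x B
#'   signed coefficients), `tail2` (length B), `rss` (length B, squared norm
#'   of the covariate-projected phenotype).
#' @export
rotate_phenotypes <- function(sd, E) {
  E <- as.matrix(E)
  if (nrow(E) != sd$n) stop("phenotype length does not match the decomposition")
  W <- crossprod(sd$Q2, E)                     # (n - q) x B
  rss <- colSums(W^2)
  if (sd$K > 0) {
    Us <- crossprod(sd$U, W)                   # K x B
    u2 <- Us^2
    tail2 <- pmax(rss - colSums(u2), 0)
  } else {
    Us <- matrix(0, 0L, ncol(E))
    u2 <- Us
    tail2 <- rss
  }
  list(u2 = u2, u_signed = Us, tail2 = tail2, rss = rss)
}

# A phenotype is degenerate when its covariate-projected residual is zero
# relative to its own scale (e lies in the covariate span).
check_phenotype <- function(sd) {
  if (is.null(sd$rss)) stop("decomposition carries no phenotype; rebuild with e")
  scale <- sum(sd$e^2)
  if (sd$rss <= 0 || (scale > 0 && sd$rss <= 1e-12 * scale))
    stop("degenerate phenotype: zero residual after covariate projection")
  invisible(TRUE)
}

#' Restricted log-likelihood profile
#'
#' Evaluates the restricted log-likelihood of the one-component mixed model
#' at given signal-to-noise ratios `lambda`, profiling out the residual
#' variance:
#' `l_R(lambda) = -1/2 [ dof * log(2 pi sigma2(lambda)) +
#'   sum_s log(1 + lambda xi_s) + dof ]`
#' with `sigma2(lambda) = (1/dof) sum_s u_s^2 / (1 + lambda xi_s)` (the sum
#' runs over all `dof` rotated components; those beyond K have zero
#' eigenvalue).
#'
#' @param sd a `spectral_decomp` carrying rotated data (built with `e`).
#' @param lambda nonnegative scalar or vector.
#' @return numeric vector of restricted log-likelihood values.
#' @export
restricted_loglik <- function(sd, lambda) {
  check_phenotype(sd)
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  u2 <- sd$u^2
  vapply(lambda, function(l) {
    denom <- 1 + l * sd$xi
    s2 <- (sum(u2 / denom) + sd$tail2) / sd$dof
    -0.5 * (sd$dof * log(2 * pi * s2) + sum(log(denom)) + sd$dof)
  }, numeric(1))
}
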