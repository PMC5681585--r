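# Dense-matrix oracles, independent of the spectral code paths.

# orthonormal basis of the complement of the column space of X
oracle_q2 <- function(X) {
  n <- nrow(X); q <- ncol(X)
  qr.Q(qr(X), complete = TRUE)[, (q + 1L):n, drop = FALSE]
}

# restricted log-likelihood via explicit determinants and inverses of
# V = I + lambda A A' in the error-contrast basis
oracle_restricted_loglik <- function(Z, X, e, lambda) {
  Q2 <- oracle_q2(X)
  A <- crossprod(Q2, Z)
  w <- crossprod(Q2, e)
  m <- nrow(A)
  V <- diag(m) + lambda * tcrossprod(A)
  s2 <- as.numeric(crossprod(w, solve(V, w))) / m
  -0.5 * (m * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) + m)
}

# eigenvalues of Z' P0 Z via a dense eigensolve of P0 Z Z' P0
oracle_xi <- function(Z, X, tol = 1e-8) {
  n <- nrow(Z)
  P0 <- diag(n) - X %*% solve(crossprod(X), t(X))
  ev <- eigen(P0 %*% tcrossprod(Z) %*% P0, symmetric = TRUE)$values
  ev[ev > tol * max(ev, 0)]
}

# BLUE of the random effects by direct dense evaluation
oracle_blue <- function(Z, X, e, lambda) {
  n <- nrow(Z)
  if (lambda == 0) return(numeric(ncol(Z)))
  V <- lambda * tcrossprod(Z) + diag(n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% e)
  as.numeric(lambda * t(Z) %*% Vi %*% (e - X %*% b))
}

# plain logistic regression fitted by hand-rolled IRLS (oracle for the
# association test's Wald p-value)
oracle_logistic <- function(X, y, maxit = 50L) {
  X <- cbind(1, X)
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-as.numeric(X %*% beta)))
    W <- mu * (1 - mu)
    beta <- beta + solve(crossprod(X, X * W), crossprod(X, y - mu))
  }
  mu <- 1 / (1 + exp(-as.numeric(X %*% beta)))
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  z <- beta / se
  list(coef = as.numeric(beta), se = se, p = 2 * pnorm(-abs(z)))
}

# small deterministic genotype fixture
toy_genotypes <- function(n = 20, p = 5, seed = 101, maf = 0.3) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2, maf), n, p)
  variants <- data.frame(id = paste0("rs", seq_len(p)), chrom = "1",
                         pos = 1000L * seq_len(p), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples = paste0("s", seq_len(n)))
}
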