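# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible child seed from a master seed and a key
#'
#' Streams are keyed by small integers (stage, group, ...) so results do not
#' depend on processing order. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(master, ...) {
  key <- c(as.double(master), as.double(unlist(list(...))))
  h <- 0
  for (k in key) h <- (h * 1000003 + (k %% 2147483647)) %% 2147483629
  as.integer(h %% 2147483647)
}

#' Check symmetric positive definiteness
#' @noRd
is_pd <- function(R, tol = 1e-10) {
  if (!isSymmetric(unname(R), tol = 1e-8)) return(FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

#' Ridge-repair a correlation matrix to positive definiteness
#' @noRd
repair_corr <- function(R, eps = 1e-8) {
  k <- 0
  while (!is_pd(R) && k < 50) {
    R <- R + diag(eps * 2^k, nrow(R))
    R <- stats::cov2cor(R)
    k <- k + 1
  }
  if (!is_pd(R)) stopf("correlation matrix could not be repaired to positive definite")
  if (k > 0) warnf("correlation matrix ridge-repaired to positive definite (%d steps)", k)
  R
}

#' Draw n rows from MVN(0, Sigma) via Cholesky
#' @noRd
rmvn <- function(n, Sigma) {
  K <- nrow(Sigma)
  L <- chol(Sigma)
  matrix(stats::rnorm(n * K), n, K) %*% L
}

#' Draw n parameter vectors from MVN(mu, Sigma) (quasi-Bayesian draws)
#' @noRd
rmvn_mu <- function(n, mu, Sigma) {
  Z <- rmvn(n, Sigma)
  sweep(Z, 2, mu, "+")
}
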