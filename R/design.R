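#' Assemble the interaction regression design
#'
#' Builds `A = [E W xi eta Gamma]`: an intercept column, optional covariates,
#' the two genotype score blocks, and the interaction block `Gamma` whose
#' i-th row is the Kronecker product `xi_i' (x) eta_i'`.  Interaction columns
#' are ordered row-major over `(j, l)`: column `(j - 1) * L + l` holds
#' `xi[, j] * eta[, l]`.
#'
#' @param xi n x J score matrix of gene 1.
#' @param eta n x L score matrix of gene 2.
#' @param W optional n x d covariate matrix.
#' @return object of class `design_bundle` with fields `A`, `E`, `W`, `xi`,
#'   `eta`, `Gamma` and `dims = list(n, d, J, L, JL)`.
#' @export
build_design <- function(xi, eta, W = NULL) {
  xi <- as.matrix(xi)
  eta <- as.matrix(eta)
  n <- nrow(xi)
  if (nrow(eta) != n) stop("xi and eta row counts differ")
  J <- ncol(xi)
  L <- ncol(eta)
  if (J < 1L || L < 1L) stop("need at least one score column per gene")
  if (!is.null(W)) {
    W <- as.matrix(W)
    if (nrow(W) != n) stop("covariate row count differs from scores")
  }
  d <- if (is.null(W)) 0L else ncol(W)
  Gamma <- xi[, rep(seq_len(J), each = L), drop = FALSE] *
    eta[, rep(seq_len(L), times = J), drop = FALSE]
  E <- matrix(1, n, 1L)
  A <- cbind(E, W, xi, eta, Gamma)
  structure(list(A = A, E = E, W = W, xi = xi, eta = eta, Gamma = Gamma,
                 dims = list(n = n, d = d, J = J, L = L, JL = J * L)),
            class = "design_bundle")
}

#' Least-squares fit of the multivariate interaction regression
#'
#' Solves `Y = A b + e` columnwise by least squares through the singular
#' value decomposition of `A`, so rank-deficient designs are handled with the
#' Moore-Penrose generalized inverse (minimum-norm solution) when
#' `allow_rank_deficient` is `TRUE`.  The residual covariance of the K
#' response score columns is the unbiased multivariate OLS estimate
#' `Sigma = R'R / (n - q)` with `q = 1 + d + J + L + JL`.
#'
#' @param design a [build_design()] bundle.
#' @param Y n x K response score matrix.
#' @param allow_rank_deficient use the generalized inverse when `A` has
#'   deficient column rank (default `TRUE`); with `FALSE`, a deficient or
#'   over-saturated design is an error.
#' @return object of class `fit_result`: `b_hat` (q x K, row blocks mu /
#'   omega / alpha / beta / gamma of sizes 1, d, J, L, JL), `Sigma_hat`
#'   (K x K), `AtA_inv` (generalized inverse of `A'A`), `rank`, `dims`,
#'   `residuals`.
#' @export
fit_mvreg <- function(design, Y, allow_rank_deficient = TRUE) {
  stopifnot(inherits(design, "design_bundle"))
  Y <- as.matrix(Y)
  A <- design$A
  n <- nrow(A)
  q <- ncol(A)
  if (nrow(Y) != n) stop("response rows do not match design")
  if (n <= q)
    stop("n must exceed the ", q, " design columns (1 + d + J + L + JL); ",
         "need n >= ", q + 1)
  sv <- svd(A)
  tol <- max(sv$d) * max(n, q) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank < q && !allow_rank_deficient)
    stop("design is rank deficient (rank ", rank, " < ", q, ")")
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  b_hat <- sv$v %*% (dinv * crossprod(sv$u, Y))
  AtA_inv <- sv$v %*% (dinv^2 * t(sv$v))
  R <- Y - A %*% b_hat
  Sigma_hat <- crossprod(R) / (n - q)
  structure(list(b_hat = b_hat, Sigma_hat = Sigma_hat, AtA_inv = AtA_inv,
                 rank = rank, dims = c(design$dims, K = ncol(Y)),
                 residuals = R),
            class = "fit_result")
}

#' Wald chi-square test of the interaction block
#'
#' Extracts the interaction coefficients `gamma_hat` (last JL rows of
#' `b_hat`) and their covariance `Lambda = Sigma_hat (x) G`, where `G` is the
#' trailing JL x JL block of the generalized inverse of `A'A`.  Under
#' column-stacking of `gamma_hat`, `Lambda` is exactly the trailing
#' JLK x JLK block of `var(vec(b_hat)) = Sigma (x) (A'A)^{-1}` restricted to
#' the interaction rows, so the statistic
#' `T_I = vec(gamma_hat)' Lambda^{+} vec(gamma_hat)` is asymptotically
#' central chi-square with `df = rank(Lambda)` (equal to `J*L*K` for a
#' regular design) under the no-interaction null.
#'
#' Near-singular `Lambda` is inverted through its symmetric
#' eigendecomposition with a relative eigenvalue cutoff of `1e-10`; when the
#' rank falls below `JLK` the result is flagged.
#'
#' @param fit a [fit_mvreg()] result.
#' @param design the [build_design()] bundle the fit came from.
#' @return object of class `interaction_result`: `T_I`, `df`, `p_value`,
#'   `gamma_hat` (JL x K), `Lambda`, `dims`, `flags`.
#' @export
interaction_test <- function(fit, design) {
  stopifnot(inherits(fit, "fit_result"), inherits(design, "design_bundle"))
  dm <- fit$dims
  q <- 1L + dm$d + dm$J + dm$L + dm$JL
  idx <- (q - dm$JL + 1L):q
  gamma_hat <- fit$b_hat[idx, , drop = FALSE]
  G <- fit$AtA_inv[idx, idx, drop = FALSE]
  Lambda <- kronecker(fit$Sigma_hat, G)
  eg <- eigen((Lambda + t(Lambda)) / 2, symmetric = TRUE)
  cutoff <- max(eg$values[1], 0) * 1e-10
  keep <- eg$values > cutoff
  df <- sum(keep)
  v <- as.vector(gamma_hat)
  flags <- character(0)
  if (df < dm$JL * dm$K) flags <- c(flags, "lambda_singular")
  if (df == 0L) {
    T_I <- 0
    p <- 1
  } else {
    z <- crossprod(eg$vectors[, keep, drop = FALSE], v)
    T_I <- sum(z^2 / eg$values[keep])
    p <- stats::pchisq(T_I, df = df, lower.tail = FALSE)
  }
  structure(list(T_I = T_I, df = df, p_value = p, gamma_hat = gamma_hat,
                 Lambda = Lambda, dims = dm, flags = flags),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> T_I = %.4g, df = %d, p = %.3g%s\n",
              x$T_I, x$df, x$p_value,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}
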