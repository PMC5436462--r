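#' Scalar-response comparator test (SFGM)
#'
#' Same genotype-function machinery as [run_bfgm()] but the response is a
#' single overall-expression value per sample (e.g. a size-factor-normalized
#' total or an RPKM, usually inverse-normal transformed), so `K = 1` and the
#' interaction test has `J*L` degrees of freedom.
#'
#' @param gene1,gene2 [genotype_matrix()] objects.
#' @param trait a [scalar_trait()] or plain numeric vector of length n.
#' @param W optional covariates.
#' @param config a [bfgm_config()].
#' @return an `interaction_result` with method tag `"sfgm"`.
#' @export
sfgm_test <- function(gene1, gene2, trait, W = NULL, config = bfgm_config()) {
  y <- if (inherits(trait, "scalar_trait")) trait$values else as.numeric(trait)
  xi <- genotype_scores(encode(gene1), var_threshold = config$var_explained)
  eta <- genotype_scores(encode(gene2), var_threshold = config$var_explained)
  res <- bfgm_core(clamp_cols(xi$scores, config$max_components),
                   clamp_cols(eta$scores, config$max_components),
                   matrix(y, ncol = 1L), W)
  res$method <- "sfgm"
  res
}

#' Per-position minimum-p comparator (RNAmin)
#'
#' Runs the scalar-response test at every grid position of the curve, taking
#' the read count at that position as the response, and reports the raw
#' minimum p-value and its position.  No multiplicity correction is applied;
#' under the null the minimum is anticonservative by construction.
#' Zero-variance positions are skipped.
#'
#' @inheritParams run_bfgm
#' @return list `min_p`, `position` (grid coordinate of the minimizer),
#'   `p_values` (per retained position), `positions`.
#' @export
rnamin_test <- function(gene1, gene2, trait_curves, W = NULL,
                        config = bfgm_config()) {
  xi <- clamp_cols(genotype_scores(encode(gene1),
                                   var_threshold = config$var_explained)$scores,
                   config$max_components)
  eta <- clamp_cols(genotype_scores(encode(gene2),
                                    var_threshold = config$var_explained)$scores,
                    config$max_components)
  keep <- which(apply(trait_curves$values, 2L, stats::sd) > 0)
  if (!length(keep)) stop("no position with variation in the curve")
  ## one design, many scalar responses: fit all positions in one pass
  jlk <- cap_components(ncol(xi), ncol(eta), 1L, nrow(xi),
                        if (is.null(W)) 0L else ncol(as.matrix(W)))
  xi <- xi[, seq_len(jlk["J"]), drop = FALSE]
  eta <- eta[, seq_len(jlk["L"]), drop = FALSE]
  design <- build_design(xi, eta, W)
  fit <- fit_mvreg(design, trait_curves$values[, keep, drop = FALSE])
  q <- ncol(design$A)
  n <- design$dims$n
  JL <- design$dims$JL
  idx <- (q - JL + 1L):q
  G <- fit$AtA_inv[idx, idx, drop = FALSE]
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  gkeep <- eg$values > max(eg$values[1], 0) * 1e-10
  df <- sum(gkeep)
  Z <- crossprod(eg$vectors[, gkeep, drop = FALSE],
                 fit$b_hat[idx, , drop = FALSE])
  quad <- colSums(Z^2 / eg$values[gkeep])
  sigma2 <- colSums(fit$residuals^2) / (n - q)
  p <- stats::pchisq(quad / sigma2, df = df, lower.tail = FALSE)
  i <- which.min(p)
  list(min_p = p[i], position = trait_curves$positions[keep][i],
       p_values = p, positions = trait_curves$positions[keep])
}

#' Pairwise single-SNP minimum-p comparator
#'
#' For every cross-gene SNP pair, fits the functional-response model with the
#' two frequency-centered encoded SNPs and their product as scalar
#' predictors, tests the product block (`df = K`), and returns the raw
#' minimum p-value with the minimizing pair.  Monomorphic SNPs are skipped.
#'
#' @inheritParams run_bfgm
#' @return list `min_p`, `snp_pair` (column indices into `gene1`, `gene2`),
#'   `p_values` (matrix over retained pairs).
#' @export
minp_pairwise <- function(gene1, gene2, trait_curves, W = NULL,
                          config = bfgm_config()) {
  e1 <- encode(gene1)
  e2 <- encode(gene2)
  ok1 <- which(!e1$monomorphic & apply(gene1$counts, 2L, stats::sd) > 0)
  ok2 <- which(!e2$monomorphic & apply(gene2$counts, 2L, stats::sd) > 0)
  if (!length(ok1) || !length(ok2)) stop("no polymorphic SNP pair to test")
  Y <- clamp_cols(response_scores(trait_curves, config)$fpca$scores,
                  config$max_components)
  pmat <- matrix(NA_real_, length(ok1), length(ok2))
  for (a in seq_along(ok1)) {
    for (b in seq_along(ok2)) {
      design <- build_design(e1$values[, ok1[a], drop = FALSE],
                             e2$values[, ok2[b], drop = FALSE], W)
      fit <- fit_mvreg(design, Y)
      pmat[a, b] <- interaction_test(fit, design)$p_value
    }
  }
  i <- which(pmat == min(pmat), arr.ind = TRUE)[1, ]
  list(min_p = min(pmat), snp_pair = c(ok1[i[1]], ok2[i[2]]),
       p_values = pmat)
}

#' Regression-on-principal-components comparator
#'
#' The response curve matrix (samples x positions) is reduced by ordinary
#' principal component analysis, retaining the smallest number of components
#' explaining at least `var_explained` of the variance; genotype predictors
#' are the same functional scores as in [run_bfgm()], and the interaction
#' block is tested jointly.
#'
#' @inheritParams run_bfgm
#' @param var_explained PCA variance fraction to retain (default 0.8).
#' @return an `interaction_result` with method tag `"pca"` and the retained
#'   component count in `dims$K`.
#' @export
pca_regression_test <- function(gene1, gene2, trait_curves, W = NULL,
                                config = bfgm_config(), var_explained = 0.8) {
  xi <- genotype_scores(encode(gene1), var_threshold = config$var_explained)
  eta <- genotype_scores(encode(gene2), var_threshold = config$var_explained)
  Y <- pca_scores(trait_curves$values, var_explained)
  res <- bfgm_core(clamp_cols(xi$scores, config$max_components),
                   clamp_cols(eta$scores, config$max_components),
                   clamp_cols(Y, config$max_components), W)
  res$method <- "pca"
  res
}

## PC scores of a samples x positions matrix retaining >= var_explained.
pca_scores <- function(X, var_explained) {
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  k <- min(which(cumsum(lambda) / sum(lambda) >= var_explained - 1e-12)[1],
           rank)
  Xc %*% sv$v[, seq_len(k), drop = FALSE]
}
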