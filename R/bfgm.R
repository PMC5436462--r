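#' Configuration for the functional interaction tests
#'
#' @param var_explained cumulative variance fraction used to pick the numbers
#'   of genotype components (J, L) and response components (K); default 0.8.
#' @param max_components hard cap on any single component count.
#' @param grid_m number of sub-intervals of the common response grid
#'   (default 256; 2456 reproduces a median-gene-length grid).
#' @param loess_span,loess_degree local polynomial smoothing parameters used
#'   when regridding raw per-position counts.
#' @param hwe_alpha Hardy-Weinberg exact-test threshold for QC.
#' @param normalize_curves divide each sample's curve by its size factor when
#'   factors are supplied (default `TRUE`).
#' @param seed optional integer seed recorded for orchestration.
#' @return a list of class `bfgm_config`.
#' @export
bfgm_config <- function(var_explained = 0.8, max_components = 8L,
                        grid_m = 256L, loess_span = 0.3, loess_degree = 2L,
                        hwe_alpha = 1e-9, normalize_curves = TRUE,
                        seed = NULL) {
  structure(list(var_explained = var_explained,
                 max_components = as.integer(max_components),
                 grid_m = as.integer(grid_m), loess_span = loess_span,
                 loess_degree = as.integer(loess_degree),
                 hwe_alpha = hwe_alpha, normalize_curves = normalize_curves,
                 seed = seed),
            class = "bfgm_config")
}

## Reduce (J, L, K) until J*L*K <= n/2 and the design fits with n > q;
## trims the largest count first so the interaction block stays balanced.
cap_components <- function(J, L, K, n, d) {
  repeat {
    q <- 1 + d + J + L + J * L
    if (J * L * K <= n / 2 && n > q) break
    big <- which.max(c(J, L, K))
    if (c(J, L, K)[big] == 1L) break
    if (big == 1L) J <- J - 1L else if (big == 2L) L <- L - 1L else K <- K - 1L
  }
  c(J = J, L = L, K = K)
}

## Shared core: scores in, test out.  Trims components to the cap, assembles
## the design, fits, and tests the interaction block.
bfgm_core <- function(xi, eta, Y, W = NULL) {
  n <- nrow(xi)
  d <- if (is.null(W)) 0L else ncol(as.matrix(W))
  jlk <- cap_components(ncol(xi), ncol(eta), ncol(Y), n, d)
  xi <- xi[, seq_len(jlk["J"]), drop = FALSE]
  eta <- eta[, seq_len(jlk["L"]), drop = FALSE]
  Y <- Y[, seq_len(jlk["K"]), drop = FALSE]
  design <- build_design(xi, eta, W)
  fit <- fit_mvreg(design, Y)
  res <- interaction_test(fit, design)
  res$fit <- fit
  res$design <- design
  res
}

## Response curve -> (regridded curve, FPCA scores).  Already-regridded
## curves (unit region, grid-spaced positions) are passed through.
response_scores <- function(trait_curves, config, size_factors = NULL) {
  stopifnot(inherits(trait_curves, "position_curve"))
  if (!is.null(size_factors) && config$normalize_curves) {
    if (length(size_factors) != nrow(trait_curves$values))
      stop("one size factor per sample required")
    trait_curves$values <- trait_curves$values / size_factors
    trait_curves <- position_curve(trait_curves$values,
                                   trait_curves$positions,
                                   chrom = trait_curves$chrom,
                                   start = trait_curves$start,
                                   end = trait_curves$end)
  }
  on_grid <- trait_curves$start == 0 && trait_curves$end == 1 &&
    length(unique(round(diff(trait_curves$positions), 12))) == 1L
  if (!on_grid)
    trait_curves <- regrid_loess(trait_curves, common_grid(config$grid_m),
                                 span = config$loess_span,
                                 degree = config$loess_degree)
  fp <- fit_fpca(trait_curves, var_threshold = config$var_explained)
  list(curve = trait_curves, fpca = fp)
}

#' Functional-response, functional-predictor interaction test (BFGM)
#'
#' The full pipeline: frequency-centered genotype encoding of both gene
#' regions, FPCA scores of the two genotype functions (J and L components at
#' the configured variance fraction), regridding and FPCA of the response
#' read-count curve (K components), design assembly, multivariate least
#' squares, and the chi-square Wald test on the interaction block with
#' `J*L*K` degrees of freedom.
#'
#' @param gene1,gene2 [genotype_matrix()] objects (QC-filtered) over the same
#'   samples in the same order as `trait_curves`.
#' @param trait_curves [position_curve()] of per-position read counts of the
#'   target gene (raw positions, or already on a unit grid).
#' @param W optional n x d covariate matrix.
#' @param config a [bfgm_config()].
#' @param size_factors optional per-sample normalization factors applied to
#'   the curves when `config$normalize_curves` is `TRUE`.
#' @return an `interaction_result` (see [interaction_test()]) with the
#'   component counts used recorded in `dims` and the method tag in
#'   `method`.
#' @export
run_bfgm <- function(gene1, gene2, trait_curves, W = NULL,
                     config = bfgm_config(), size_factors = NULL) {
  n <- nrow(trait_curves$values)
  if (nrow(gene1$counts) != n || nrow(gene2$counts) != n)
    stop("genotype stage: sample counts differ from trait curves")
  xi <- genotype_scores(encode(gene1), var_threshold = config$var_explained)
  eta <- genotype_scores(encode(gene2), var_threshold = config$var_explained)
  rs <- response_scores(trait_curves, config, size_factors)
  res <- bfgm_core(clamp_cols(xi$scores, config$max_components),
                   clamp_cols(eta$scores, config$max_components),
                   clamp_cols(rs$fpca$scores, config$max_components), W)
  res$method <- "bfgm"
  res
}

clamp_cols <- function(m, k) m[, seq_len(min(ncol(m), k)), drop = FALSE]
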