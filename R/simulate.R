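#' Simulate genotypes for two gene regions under Hardy-Weinberg sampling
#'
#' SNPs are independent; each SNP's minor allele frequency is drawn from the
#' requested spectrum (`"rare"`: U(0.001, 0.05); `"mixed"`: each SNP is
#' common U(0.05, 0.5) or rare with equal probability) and genotypes are
#' binomial(2, maf) counts.  A fraction of SNPs per gene is flagged causal
#' (at least one).  Randomness comes from the current RNG stream, so
#' `set.seed()` before the call gives bit-identical output.
#'
#' @param n number of samples.
#' @param p SNPs per gene (length-2 vector or a single count for both).
#' @param maf_spectrum `"rare"` or `"mixed"`.
#' @param causal_fraction fraction of SNPs flagged causal (default 0.1).
#' @param region_length bp length of each simulated region.
#' @return list of two [genotype_matrix()] objects, each with attributes
#'   `maf_true` and `causal` (column indices).
#' @export
simulate_genotypes <- function(n, p = c(10L, 10L), maf_spectrum = "rare",
                               causal_fraction = 0.1,
                               region_length = 10000L) {
  if (length(p) == 1L) p <- rep(p, 2L)
  lapply(seq_len(2L), function(k) {
    pk <- p[k]
    maf <- switch(match.arg(maf_spectrum, c("rare", "mixed")),
                  rare = stats::runif(pk, 0.001, 0.05),
                  mixed = ifelse(stats::runif(pk) < 0.5,
                                 stats::runif(pk, 0.05, 0.5),
                                 stats::runif(pk, 0.001, 0.05)))
    counts <- matrix(stats::rbinom(n * pk, 2L, rep(maf, each = n)), n, pk)
    pos <- sort(sample.int(region_length - 2L, pk)) + 1L
    g <- genotype_matrix(counts, pos, chrom = paste0("sim", k),
                         start = 1, end = region_length)
    attr(g, "maf_true") <- maf
    attr(g, "causal") <- sort(sample.int(pk, max(1L, round(causal_fraction * pk))))
    g
  })
}

#' Parametric template read-count curves
#'
#' A stand-in family for a panel of real RNA-seq genes: each gene has a
#' smooth positive mean profile (mixture of Gaussian bumps on the unit
#' interval) and per-sample variation built from a few random amplitude
#' scores on additional smooth shapes, plus small white noise that the
#' regridding smoother removes.  Used to drive the null-model construction;
#' real curves read from disk can be supplied in their place.
#'
#' @param n_genes number of template genes.
#' @param n samples per gene (the same sample index runs across genes).
#' @param min_len,max_len per-gene position counts are drawn uniformly in
#'   this range.
#' @return list of [position_curve()]s.
#' @export
template_curves <- function(n_genes = 10L, n = 100L, min_len = 150L,
                            max_len = 400L) {
  bump <- function(u, c, w) exp(-((u - c) / w)^2)
  lapply(seq_len(n_genes), function(k) {
    len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
    u <- (seq_len(len) - 1) / (len - 1)
    mean_fn <- 2 + 6 * bump(u, stats::runif(1, 0.2, 0.5), stats::runif(1, 0.08, 0.2)) +
      4 * bump(u, stats::runif(1, 0.5, 0.85), stats::runif(1, 0.08, 0.2))
    s1 <- bump(u, stats::runif(1, 0.2, 0.8), stats::runif(1, 0.1, 0.25))
    s2 <- sin(pi * u * stats::runif(1, 1.5, 3))
    a <- stats::rnorm(n, 1, 0.25)
    b <- stats::rnorm(n, 0, 0.8)
    cc <- stats::rnorm(n, 0, 0.5)
    vals <- outer(a, mean_fn) + outer(b, s1) + outer(cc, s2) +
      matrix(stats::rnorm(n * len, 0, 0.05), n, len)
    position_curve(pmax(vals, 0), seq_len(len), chrom = paste0("tmpl", k))
  })
}

#' Null-model specification from template curves
#'
#' Implements the six-step correlated-error construction: regrid every
#' template gene to the unit grid with the local polynomial smoother,
#' average the regridded matrices over genes per sample, run FPCA on the
#' pooled matrix to obtain the mean function (reconstructed from averaged
#' component scores), center per position, and take the FPCA eigenfunctions
#' and score covariance of the centered data as the error process.  For the
#' marginal-effect models the additive effect functions are multiples of the
#' leading error eigenfunctions, with per-causal-SNP multipliers drawn
#' uniformly from \[0.5, 1.5\].
#'
#' @param template list of [position_curve()]s (>= 2 genes, equal n).
#' @param model_id 1 (no marginal effect), 2 (marginal effect at gene 1) or
#'   3 (marginal effects at both genes).
#' @param genotypes list of two [genotype_matrix()] objects (required for
#'   models 2-3; their `causal` attributes select the effect SNPs).
#' @param grid target [common_grid()].
#' @param span,degree regridding smoother parameters.
#' @param err_var variance fraction retained for the error basis.
#' @param effect_scale marginal effect size as a multiple of the leading
#'   error component's standard deviation.
#' @return object of class `null_model_spec`.
#' @export
build_null_spec <- function(template, model_id = 1L, genotypes = NULL,
                            grid = common_grid(128L), span = 0.3, degree = 2,
                            err_var = 0.99, effect_scale = 0.5) {
  if (length(template) < 2L) stop("need at least 2 template genes")
  model_id <- as.integer(model_id)
  stopifnot(model_id %in% 1:3)
  mats <- lapply(template, function(cv)
    regrid_loess(cv, grid, span = span, degree = degree)$values)
  ns <- vapply(mats, nrow, 0L)
  if (length(unique(ns)) != 1L) stop("template genes must share samples")
  ybar <- Reduce(`+`, mats) / length(mats)
  pooled <- position_curve(ybar, grid$points, start = 0, end = 1)
  fp <- fit_fpca(pooled, var_threshold = err_var)
  mu <- fp$basis$mean_fn +
    drop(colMeans(fp$scores) %*% fp$basis$eigenfunctions)
  Phi <- fp$basis$eigenfunctions
  Sigma <- stats::cov(fp$scores)
  lam1 <- fp$basis$eigenvalues[1]
  w <- fp$basis$weights
  ## interaction signal shape: leading eigenfunction centered to zero mean
  ## under quadrature (no net change in total expression), norm sqrt(lam1)
  g <- Phi[1, ] - sum(w * Phi[1, ])
  g <- g / sqrt(sum(w * g^2)) * sqrt(lam1)
  alpha <- beta <- NULL
  r_j <- s_k <- NULL
  causal <- list(NULL, NULL)
  if (model_id >= 2L) {
    if (is.null(genotypes)) stop("models 2-3 need genotypes")
    causal[[1]] <- attr(genotypes[[1]], "causal") %||%
      seq_len(ncol(genotypes[[1]]$counts))
    alpha <- effect_scale * sqrt(lam1) * Phi[1, ]
    r_j <- stats::runif(length(causal[[1]]), 0.5, 1.5)
  }
  if (model_id == 3L) {
    causal[[2]] <- attr(genotypes[[2]], "causal") %||%
      seq_len(ncol(genotypes[[2]]$counts))
    beta <- effect_scale * sqrt(lam1) *
      Phi[min(2L, nrow(Phi)), ]
    s_k <- stats::runif(length(causal[[2]]), 0.5, 1.5)
  }
  structure(list(model_id = model_id, points = grid$points, weights = w,
                 mu = mu, Phi = Phi, Sigma = Sigma,
                 Sigma_sqrt = sym_sqrt(Sigma),
                 eigenvalues = fp$basis$eigenvalues[seq_len(nrow(Phi))],
                 g = g, alpha = alpha, beta = beta, r_j = r_j, s_k = s_k,
                 causal = causal),
            class = "null_model_spec")
}

sym_sqrt <- function(S) {
  if (length(S) == 1L) return(matrix(sqrt(max(S, 0)), 1L, 1L))
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Generate read-count curves under a null (no-interaction) model
#'
#' Curves are `mu(tau)` plus, for models 2-3, additive marginal terms
#' `sum_j x_ij r_j alpha(tau)` (and the gene-2 analogue), plus correlated
#' errors built from multivariate normal component scores with the
#' covariance estimated from the templates.  No interaction term is ever
#' included.
#'
#' @param spec a [build_null_spec()] result.
#' @param genotypes list of two [genotype_matrix()] objects (models 2-3).
#' @param n sample count (defaults to the genotype sample count).
#' @return a [position_curve()] on the spec's grid.
#' @export
generate_null_traits <- function(spec, genotypes = NULL, n = NULL) {
  stopifnot(inherits(spec, "null_model_spec"))
  if (spec$model_id >= 2L && is.null(genotypes))
    stop("model ", spec$model_id, " needs genotypes")
  if (is.null(n)) {
    if (is.null(genotypes)) stop("n required when no genotypes are given")
    n <- nrow(genotypes[[1]]$counts)
  }
  vals <- matrix(spec$mu, n, length(spec$points), byrow = TRUE)
  if (spec$model_id >= 2L) {
    x <- genotypes[[1]]$counts[, spec$causal[[1]], drop = FALSE]
    vals <- vals + outer(drop(x %*% spec$r_j), spec$alpha)
  }
  if (spec$model_id == 3L) {
    z <- genotypes[[2]]$counts[, spec$causal[[2]], drop = FALSE]
    vals <- vals + outer(drop(z %*% spec$s_k), spec$beta)
  }
  Tn <- nrow(spec$Phi)
  eps <- matrix(stats::rnorm(n * Tn), n, Tn) %*% spec$Sigma_sqrt
  vals <- vals + eps %*% spec$Phi
  position_curve(vals, spec$points, start = 0, end = 1)
}

#' Two-locus interaction (penetrance) model
#'
#' The genotypic interaction multiplier is a 3 x 3 table over minor-allele
#' counts (0, 1, 2) at the two causal loci, scaled by the risk parameter
#' `r`.  Built-in patterns: `DomORDom` (effect iff at least one minor allele
#' at either locus), `DomANDDom` (at both), `RecORRec` (two minor alleles at
#' either), `Threshold` (total minor-allele count across the pair >= 3).  A
#' custom 3 x 3 0/1 table may be supplied instead.
#'
#' @param name one of `"DomORDom"`, `"DomANDDom"`, `"RecORRec"`,
#'   `"Threshold"`.
#' @param r risk parameter in \[0, 1\].
#' @param lambda_table optional custom 3 x 3 indicator table (rows: gene-1
#'   minor-allele count 0/1/2; columns: gene-2).
#' @return object of class `interaction_model_spec`.
#' @export
interaction_model_spec <- function(name = c("DomORDom", "DomANDDom",
                                            "RecORRec", "Threshold"),
                                   r, lambda_table = NULL) {
  name <- match.arg(name)
  if (!(is.numeric(r) && r >= 0 && r <= 1))
    stop("risk parameter r must lie in [0, 1]")
  if (is.null(lambda_table)) {
    c1 <- matrix(0:2, 3L, 3L)
    c2 <- t(c1)
    lambda_table <- switch(name,
      DomORDom = (c1 >= 1 | c2 >= 1),
      DomANDDom = (c1 >= 1 & c2 >= 1),
      RecORRec = (c1 == 2 | c2 == 2),
      Threshold = (c1 + c2 >= 3)) + 0
  } else {
    lambda_table <- as.matrix(lambda_table)
    stopifnot(all(dim(lambda_table) == c(3L, 3L)))
  }
  structure(list(name = name, r = r, lambda_table = lambda_table),
            class = "interaction_model_spec")
}

#' Generate read-count curves with an epistatic signal
#'
#' For every pair of causal SNPs across the two genes, each individual
#' receives `r * lambda[class]` times the common signal shape `g(tau)`
#' according to their genotype class at the pair; contributions sum over
#' pairs.  Errors (and the overall mean) follow the null spec, so `r = 0`
#' reproduces the null generator draw for draw on the same RNG stream.
#'
#' @param im an [interaction_model_spec()].
#' @param spec a [build_null_spec()] result (model 1 errors).
#' @param gene1,gene2 [genotype_matrix()] objects carrying `causal`
#'   attributes (all SNPs are causal when the attribute is absent).
#' @param g_fn optional signal shape on the spec grid (defaults to the
#'   spec's built-in zero-mean leading-eigenfunction shape).
#' @return a [position_curve()] on the spec's grid.
#' @export
generate_power_traits <- function(im, spec, gene1, gene2, g_fn = NULL) {
  stopifnot(inherits(im, "interaction_model_spec"),
            inherits(spec, "null_model_spec"))
  n <- nrow(gene1$counts)
  if (nrow(gene2$counts) != n) stop("genotype sample counts differ")
  g <- g_fn %||% spec$g
  causal1 <- attr(gene1, "causal") %||% seq_len(ncol(gene1$counts))
  causal2 <- attr(gene2, "causal") %||% seq_len(ncol(gene2$counts))
  lam_tot <- numeric(n)
  for (a in causal1) {
    ca <- pmin(pmax(round(gene1$counts[, a]), 0), 2)
    for (b in causal2) {
      cb <- pmin(pmax(round(gene2$counts[, b]), 0), 2)
      lam_tot <- lam_tot + im$r * im$lambda_table[cbind(ca + 1L, cb + 1L)]
    }
  }
  vals <- matrix(spec$mu, n, length(spec$points), byrow = TRUE) +
    outer(lam_tot, g)
  Tn <- nrow(spec$Phi)
  eps <- matrix(stats::rnorm(n * Tn), n, Tn) %*% spec$Sigma_sqrt
  position_curve(vals + eps %*% spec$Phi, spec$points, start = 0, end = 1)
}

#' Empirical type-1 error of the interaction test
#'
#' Simulates genotype gene pairs, builds the null trait generator from a
#' fresh template panel, generates trait curves with no interaction term,
#' runs the functional interaction test on every replicate, and reports the
#' fraction of p-values below each nominal level with binomial standard
#' errors.  Replicates are split evenly across `n_pairs` independent
#' genotype pairs (genotypes fixed within a pair, traits redrawn).
#'
#' @param n sample size per replicate.
#' @param model_id null model (1, 2 or 3).
#' @param reps total replicates (>= 100).
#' @param alphas nominal significance levels.
#' @param n_pairs number of genotype gene pairs to average over.
#' @param p_snps SNPs per gene.
#' @param maf_spectrum,causal_fraction genotype simulation settings.
#' @param n_template_genes,n_template_samples template panel size.
#' @param grid_m response grid sub-intervals.
#' @param config a [bfgm_config()] controlling the test itself.
#' @param seed integer seed (all randomness derives from it).
#' @return data frame with one row per alpha: `model`, `n`, `alpha`,
#'   `rate`, `se`, `reps`; the replicate p-values are in attribute
#'   `p_values`.
#' @export
type1_experiment <- function(n = 1000L, model_id = 1L, reps = 1000L,
                             alphas = c(0.05, 0.01), n_pairs = 2L,
                             p_snps = c(10L, 10L), maf_spectrum = "rare",
                             causal_fraction = 0.1,
                             n_template_genes = 10L,
                             n_template_samples = 100L, grid_m = 128L,
                             config = bfgm_config(grid_m = grid_m),
                             seed = 1L) {
  if (reps < 100L) stop("need at least 100 replicates")
  set.seed(seed)
  tmpl <- template_curves(n_template_genes, n_template_samples)
  grid <- common_grid(grid_m)
  per_pair <- diff(floor(seq(0, reps, length.out = n_pairs + 1L)))
  pvals <- numeric(0)
  for (pair in seq_len(n_pairs)) {
    genos <- simulate_genotypes(n, p_snps, maf_spectrum, causal_fraction)
    spec <- build_null_spec(tmpl, model_id, genos, grid,
                            span = config$loess_span,
                            degree = config$loess_degree)
    xi <- clamp_cols(genotype_scores(encode(genos[[1]]),
                                     var_threshold = config$var_explained)$scores,
                     config$max_components)
    eta <- clamp_cols(genotype_scores(encode(genos[[2]]),
                                      var_threshold = config$var_explained)$scores,
                      config$max_components)
    for (rep in seq_len(per_pair[pair])) {
      traits <- generate_null_traits(spec, genos, n)
      Y <- clamp_cols(fit_fpca(traits,
                               var_threshold = config$var_explained)$scores,
                      config$max_components)
      pvals <- c(pvals, bfgm_core(xi, eta, Y)$p_value)
    }
  }
  out <- data.frame(model = model_id, n = n, alpha = alphas,
                    rate = vapply(alphas, function(a) mean(pvals < a), 0),
                    reps = length(pvals))
  out$se <- sqrt(out$rate * (1 - out$rate) / out$reps)
  attr(out, "p_values") <- pvals
  out
}

#' Empirical power of the interaction tests
#'
#' Simulates an epistatic signal under the requested two-locus models over a
#' grid of risk parameters and estimates the rejection rate at `alpha` for
#' each requested method.  As in the type-1 design, results are averaged
#' over `n_pairs` independently simulated genotype gene pairs (each fixed
#' across its replicates and across r values); with independent rare SNPs
#' the interaction content a single genotype draw carries is highly
#' variable, and pair averaging is what makes the power curve a property of
#' the design rather than of one draw.  Traits are redrawn every replicate.
#'
#' @param r_grid risk parameter values in \[0, 1\].
#' @param models character vector of interaction model names
#'   (see [interaction_model_spec()]).
#' @param methods subset of `c("bfgm", "pca", "sfgm")`.
#' @param n sample size.
#' @param reps total replicates per (model, r) cell, split across pairs.
#' @param alpha significance level.
#' @param n_pairs genotype gene pairs to average over.
#' @param p_snps,maf_spectrum,causal_fraction genotype settings (the power
#'   design uses a 20% causal fraction).
#' @param n_template_genes,n_template_samples,grid_m generator settings.
#' @param config a [bfgm_config()].
#' @param seed integer seed.
#' @return tidy data frame: `model`, `r`, `method`, `power`, `se`, `reps`.
#' @export
power_experiment <- function(r_grid = c(0, 0.2, 0.5, 0.8),
                             models = "DomORDom",
                             methods = c("bfgm", "pca", "sfgm"),
                             n = 2000L, reps = 200L, alpha = 0.05,
                             n_pairs = 4L, p_snps = c(20L, 20L),
                             maf_spectrum = "rare", causal_fraction = 0.2,
                             n_template_genes = 10L,
                             n_template_samples = 100L, grid_m = 64L,
                             config = bfgm_config(grid_m = grid_m),
                             seed = 1L) {
  set.seed(seed)
  tmpl <- template_curves(n_template_genes, n_template_samples)
  grid <- common_grid(grid_m)
  per_pair <- diff(floor(seq(0, reps, length.out = n_pairs + 1L)))
  out <- list()
  for (model in models) {
    hits <- matrix(0, 0, length(methods), dimnames = list(NULL, methods))
    cells <- lapply(r_grid, function(r) hits)
    names(cells) <- as.character(r_grid)
    for (pair in seq_len(n_pairs)) {
      genos <- simulate_genotypes(n, p_snps, maf_spectrum, causal_fraction)
      spec <- build_null_spec(tmpl, 1L, genos, grid,
                              span = config$loess_span,
                              degree = config$loess_degree)
      xi <- clamp_cols(genotype_scores(encode(genos[[1]]),
                                       var_threshold = config$var_explained)$scores,
                       config$max_components)
      eta <- clamp_cols(genotype_scores(encode(genos[[2]]),
                                        var_threshold = config$var_explained)$scores,
                        config$max_components)
      w <- spec$weights
      for (r in r_grid) {
        im <- interaction_model_spec(model, r)
        block <- matrix(0, per_pair[pair], length(methods),
                        dimnames = list(NULL, methods))
        for (rep in seq_len(per_pair[pair])) {
          traits <- generate_power_traits(im, spec, genos[[1]], genos[[2]])
          for (mth in methods) {
            p <- switch(mth,
              bfgm = {
                Y <- clamp_cols(fit_fpca(traits,
                                         var_threshold = config$var_explained)$scores,
                                config$max_components)
                bfgm_core(xi, eta, Y)$p_value
              },
              pca = {
                Y <- clamp_cols(pca_scores(traits$values, 0.8),
                                config$max_components)
                bfgm_core(xi, eta, Y)$p_value
              },
              sfgm = {
                total <- drop(traits$values %*% w)
                bfgm_core(xi, eta,
                          matrix(inverse_normal(total)$values,
                                 ncol = 1L))$p_value
              })
            block[rep, mth] <- p < alpha
          }
        }
        cells[[as.character(r)]] <- rbind(cells[[as.character(r)]], block)
      }
    }
    for (r in r_grid) {
      pw <- colMeans(cells[[as.character(r)]])
      total <- nrow(cells[[as.character(r)]])
      out[[length(out) + 1L]] <- data.frame(
        model = model, r = r, method = methods, power = unname(pw),
        se = sqrt(unname(pw) * (1 - unname(pw)) / total), reps = total,
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
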