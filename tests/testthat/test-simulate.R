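test_that("simulated genotypes respect the MAF spectrum and HWE", {
  set.seed(20)
  genos <- simulate_genotypes(5000, c(20, 20), maf_spectrum = "rare")
  for (g in genos) {
    expect_true(all(attr(g, "maf_true") < 0.05))
    expect_true(all(attr(g, "maf_true") > 0.001))
    expect_true(all(g$maf <= 0.08))  # sample frequency near the drawn MAF
    expect_true(all(diff(g$positions) > 0))
    expect_gte(length(attr(g, "causal")), 1)
  }
  # genotype frequencies at the drawn MAF follow HWE within 3.5 sigma
  set.seed(21)
  big <- simulate_genotypes(1e5, c(3, 3), maf_spectrum = "mixed")[[1]]
  for (j in 1:3) {
    f <- attr(big, "maf_true")[j]
    probs <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- tabulate(round(big$counts[, j]) + 1L, 3L)
    # counts were oriented towards the sample minor allele
    if (big$flipped[j]) probs <- rev(probs)
    z <- abs(obs - 1e5 * probs) / sqrt(pmax(1e5 * probs * (1 - probs), 1))
    expect_lt(max(z), 3.5)
  }
  # fixed seed reproduces bit-identical output
  set.seed(99)
  a <- simulate_genotypes(50, c(4, 4))
  set.seed(99)
  b <- simulate_genotypes(50, c(4, 4))
  expect_identical(a, b)
})

test_that("null spec construction matches a longhand rebuild on a toy panel", {
  set.seed(22)
  tmpl <- template_curves(3, 25, min_len = 60, max_len = 90)
  grid <- common_grid(16)
  spec <- build_null_spec(tmpl, 1, grid = grid)
  # longhand: regrid each gene with reference loess, average over genes,
  # then the averaged-score mean reconstruction collapses to the column mean
  mats <- lapply(tmpl, function(cv) {
    u <- (cv$positions - cv$start) / (cv$end - cv$start)
    t(apply(cv$values, 1, function(y)
      predict(loess(y ~ u, span = 0.3, degree = 2, family = "gaussian",
                    surface = "direct"),
              newdata = data.frame(u = grid$points))))
  })
  ybar <- (mats[[1]] + mats[[2]] + mats[[3]]) / 3
  expect_equal(spec$mu, colMeans(ybar), tolerance = 1e-8,
               ignore_attr = TRUE)
  # error basis matches FPCA of the centered pooled matrix
  fp <- fit_fpca(position_curve(ybar, grid$points, start = 0, end = 1),
                 var_threshold = 0.99)
  expect_equal(spec$Phi, fp$basis$eigenfunctions, tolerance = 1e-8)
  expect_equal(spec$Sigma, cov(fp$scores), tolerance = 1e-8)
})

test_that("degenerate templates give zero-noise draws equal to the mean", {
  pts <- 1:80
  flat1 <- position_curve(matrix(rep(sin(pts / 9) + 2, 10), 10, 80,
                                 byrow = TRUE), pts)
  flat2 <- position_curve(matrix(rep(cos(pts / 7) + 2, 10), 10, 80,
                                 byrow = TRUE), pts)
  spec <- build_null_spec(list(flat1, flat2), 1, grid = common_grid(16))
  expect_lt(max(abs(spec$Sigma)), 1e-12)
  traits <- generate_null_traits(spec, n = 6)
  expect_lt(max(abs(sweep(traits$values, 2, spec$mu))), 1e-8)
})

test_that("simulated error covariance converges to the eigen-reconstruction", {
  set.seed(23)
  tmpl <- template_curves(4, 60, min_len = 60, max_len = 90)
  spec <- build_null_spec(tmpl, 1, grid = common_grid(32))
  draws <- generate_null_traits(spec, n = 5000)
  emp <- cov(draws$values)
  target <- t(spec$Phi) %*% spec$Sigma %*% spec$Phi
  rel <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel, 0.05)
  # per-position mean over the draws stays within 3 sigma of mu
  sd_pos <- sqrt(diag(target) / 5000)
  expect_lt(max(abs(colMeans(draws$values) - spec$mu) / sd_pos), 3)
})

test_that("marginal-effect models nest the no-effect model", {
  set.seed(24)
  genos <- simulate_genotypes(40, c(5, 5), maf_spectrum = "mixed")
  tmpl <- template_curves(3, 30, min_len = 60, max_len = 90)
  spec2 <- build_null_spec(tmpl, 2, genos, common_grid(16))
  expect_length(spec2$r_j, length(attr(genos[[1]], "causal")))
  expect_true(all(spec2$r_j >= 0.5 & spec2$r_j <= 1.5))
  spec1 <- spec2
  spec1$model_id <- 1L
  spec0 <- spec2
  spec0$alpha <- spec0$alpha * 0
  set.seed(7)
  t1 <- generate_null_traits(spec1, genos, 40)
  set.seed(7)
  t0 <- generate_null_traits(spec0, genos, 40)
  expect_equal(t0$values, t1$values, tolerance = 1e-12)
  # with a nonzero effect the causal carriers shift by x'r * alpha exactly
  set.seed(7)
  t2 <- generate_null_traits(spec2, genos, 40)
  shift <- outer(drop(genos[[1]]$counts[, spec2$causal[[1]], drop = FALSE]
                      %*% spec2$r_j), spec2$alpha)
  expect_equal(t2$values - t1$values, shift, tolerance = 1e-10)
  expect_error(generate_null_traits(spec2, n = 40), "needs genotypes")
})

test_that("power generator: null limit, penetrance lookup, monotonicity", {
  set.seed(25)
  genos <- simulate_genotypes(300, c(5, 5), maf_spectrum = "mixed",
                              causal_fraction = 0.2)
  tmpl <- template_curves(3, 40, min_len = 60, max_len = 90)
  spec <- build_null_spec(tmpl, 1, genos, common_grid(16))
  # r = 0 reproduces the null generator draw for draw
  im0 <- interaction_model_spec("DomORDom", 0)
  set.seed(5)
  p0 <- generate_power_traits(im0, spec, genos[[1]], genos[[2]])
  set.seed(5)
  n0 <- generate_null_traits(spec, genos, 300)
  expect_equal(p0$values, n0$values, tolerance = 1e-12)
  expect_error(interaction_model_spec("DomORDom", 1.2), "\\[0, 1\\]")

  # noiseless penetrance lookup under DomORDom with a single causal pair
  cnt1 <- c(0, 0, 1, 2, 0)
  cnt2 <- c(0, 0, 0, 1, 2)
  g1 <- geno_from_counts(cbind(cnt1))
  g2 <- geno_from_counts(cbind(cnt2))
  attr(g1, "causal") <- 1L
  attr(g2, "causal") <- 1L
  spec0 <- spec
  spec0$Sigma <- spec0$Sigma * 0
  spec0$Sigma_sqrt <- spec0$Sigma_sqrt * 0
  im <- interaction_model_spec("DomORDom", 0.7)
  tp <- generate_power_traits(im, spec0, g1, g2)
  gen <- sweep(tp$values, 2, spec$mu)
  carrier <- as.numeric(cnt1 >= 1 | cnt2 >= 1)
  expect_equal(gen, outer(0.7 * carrier, spec$g), tolerance = 1e-10)

  # built-in penetrance tables
  expect_equal(interaction_model_spec("DomANDDom", 1)$lambda_table,
               outer(0:2, 0:2, function(a, b) (a >= 1 & b >= 1) + 0))
  expect_equal(interaction_model_spec("RecORRec", 1)$lambda_table,
               outer(0:2, 0:2, function(a, b) (a == 2 | b == 2) + 0))
  expect_equal(interaction_model_spec("Threshold", 1)$lambda_table,
               outer(0:2, 0:2, function(a, b) (a + b >= 3) + 0))

  # rejection rate is nondecreasing in r (within Monte-Carlo slack) at the
  # sample size the power design targets
  set.seed(25)
  genos2 <- simulate_genotypes(2000, c(10, 10), maf_spectrum = "rare",
                               causal_fraction = 0.2)
  spec2 <- build_null_spec(tmpl, 1, genos2, common_grid(16))
  cfg <- bfgm_config(grid_m = 16)
  power_at <- function(r, reps = 40) {
    im_r <- interaction_model_spec("DomORDom", r)
    mean(replicate(reps, {
      tr <- generate_power_traits(im_r, spec2, genos2[[1]], genos2[[2]])
      run_bfgm(genos2[[1]], genos2[[2]], tr, config = cfg)$p_value < 0.05
    }))
  }
  set.seed(26)
  pw <- vapply(c(0, 0.5, 1), power_at, 0)
  expect_gte(pw[2], pw[1] - 0.12)
  expect_gte(pw[3], pw[2] - 0.12)
  expect_gt(pw[3], pw[1])
})

test_that("type-1 experiment driver: boundary alpha, determinism, errors", {
  res <- type1_experiment(n = 150, model_id = 1, reps = 120,
                          alphas = c(1, 0.05), n_pairs = 1,
                          p_snps = c(4, 4), n_template_genes = 2,
                          n_template_samples = 20, grid_m = 16, seed = 3)
  expect_equal(res$rate[res$alpha == 1], 1)
  expect_equal(res$reps[1], 120)
  res2 <- type1_experiment(n = 150, model_id = 1, reps = 120,
                           alphas = c(1, 0.05), n_pairs = 1,
                           p_snps = c(4, 4), n_template_genes = 2,
                           n_template_samples = 20, grid_m = 16, seed = 3)
  expect_identical(attr(res, "p_values"), attr(res2, "p_values"))
  expect_error(type1_experiment(reps = 50), "100 replicates")
})

test_that("power experiment driver emits a tidy deterministic table", {
  run <- function() power_experiment(r_grid = c(0, 1), models = "DomANDDom",
                                     methods = c("bfgm", "sfgm"), n = 150,
                                     reps = 15, p_snps = c(4, 4),
                                     n_template_genes = 2,
                                     n_template_samples = 20,
                                     grid_m = 16, seed = 8)
  pw <- run()
  expect_equal(nrow(pw), 4)
  expect_setequal(unique(pw$method), c("bfgm", "sfgm"))
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  expect_identical(pw, run())
})
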