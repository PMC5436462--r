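test_that("frequency-centered encoding follows the printed map", {
  # symmetric case P_M = P_m = 0.5
  g <- geno_from_counts(cbind(c(0, 0, 1, 1, 2, 2)))
  expect_equal(g$maf, 0.5)
  expect_equal(unname(encode(g)$values[, 1]), c(1, 1, 0, 0, -1, -1))
  # P_m = 0.1: MM -> 0.2, Mm -> -0.8, mm -> -1.8
  g2 <- geno_from_counts(cbind(c(1, 1, rep(0, 8)), c(2, rep(0, 9))))
  expect_equal(g2$maf, c(0.1, 0.1))
  e2 <- encode(g2)$values
  expect_equal(unname(e2[1:3, 1]), c(-0.8, -0.8, 0.2))
  expect_equal(unname(e2[1:2, 2]), c(-1.8, 0.2))
  # expected value under HWE genotype probabilities is 0 for any P_m
  for (pm in c(0.05, 0.2, 0.5)) {
    pM <- 1 - pm
    expect_equal(pM^2 * 2 * pm + 2 * pM * pm * (pm - pM) + pm^2 * (-2 * pM),
                 0, tolerance = 1e-12)
  }
  # exact sample HWE proportions give an exactly centered column
  g3 <- geno_from_counts(cbind(rep(c(0, 1, 2), c(81, 18, 1))))
  expect_equal(mean(encode(g3)$values[, 1]), 0, tolerance = 1e-12)
  # monomorphic SNPs encode to zero and are flagged
  g4 <- geno_from_counts(cbind(rep(0, 10)))
  e4 <- encode(g4)
  expect_true(e4$monomorphic[1])
  expect_true(all(e4$values[, 1] == 0))
})

test_that("the exact HWE test matches a brute-force conditional oracle", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    cnt <- table(factor(sample(0:2, n, replace = TRUE,
                               prob = c(0.5, 0.3, 0.2)), levels = 0:2))
    nA <- cnt[[1]]; nH <- cnt[[2]]; na <- cnt[[3]]
    hr <- min(nA, na); hc <- max(nA, na)
    nr <- 2 * hr + nH
    hets <- seq(nr %% 2, nr, by = 2)
    pr <- vapply(hets, function(h)
      hwe_table_prob((nr - h) / 2, h, n - (nr + h) / 2), 0)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    p_oracle <- sum(pr[pr <= pr[match(nH, hets)] * (1 + 1e-7)])
    expect_equal(hwe_exact_test(nA, nH, na), min(1, p_oracle),
                 tolerance = 1e-9)
  }
  # total heterozygote deficit in n = 100 is astronomically unlikely
  expect_lt(hwe_exact_test(50, 0, 50), 1e-9)
})

test_that("QC removes singletons, duplicates and HWE failures, idempotently", {
  set.seed(21)
  ok <- hwe_counts(100, c(0.3, 0.2))
  singleton <- c(1, rep(0, 99))
  hwe_bad <- rep(c(0, 2), 50)              # no hets at frequency 0.5
  counts <- cbind(ok[, 1], singleton, hwe_bad, ok[, 2], ok[, 2])
  g <- genotype_matrix(counts, c(10, 20, 30, 40, 40), chrom = "1")
  filt <- qc_filter(g)
  rep_tab <- attr(filt, "qc_report")
  expect_equal(ncol(filt$counts), 2)
  expect_setequal(rep_tab$reason, c("singleton", "hwe", "duplicate"))
  expect_equal(rep_tab$reason[rep_tab$position == 20], "singleton")
  expect_equal(rep_tab$reason[rep_tab$position == 30], "hwe")
  expect_equal(rep_tab$reason[rep_tab$position == 40], "duplicate")
  # idempotent
  twice <- qc_filter(filt)
  expect_identical(twice$counts, filt$counts)
  expect_equal(nrow(attr(twice, "qc_report")), 0)
})

test_that("VCF round-trips preserve counts, positions and orientation", {
  set.seed(4)
  counts <- hwe_counts(20, c(0.25, 0.4, 0.1))
  g <- genotype_matrix(counts, c(150, 300, 450), chrom = "9",
                       start = 100, end = 500)
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  back <- read_vcf_region(path, list(chrom = "9", start = 100, end = 500))
  expect_equal(unname(back$counts), unname(g$counts))
  expect_equal(back$positions, as.numeric(g$positions))
  expect_equal(back$maf, g$maf)
})

test_that("VCF reading translates GT, orients the minor allele, imputes, errors", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t101\tv1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t102\tv2\tA\tT\t.\tPASS\t.\tGT\t1/1\t1|1\t0/1",  # ALT freq > 0.5
    "1\t103\tv3\tA\tT\t.\tPASS\t.\tGT\t./.\t0/1\t0/1"), path)
  g <- read_vcf_region(path, list(chrom = "1", start = 100, end = 200))
  expect_equal(unname(g$counts[, 1]), c(0, 1, 2))
  # v2: ALT frequency 5/6 -> flipped, maf = 1/6
  expect_equal(unname(g$counts[, 2]), c(0, 0, 1))
  expect_equal(g$maf[2], 1 / 6, tolerance = 1e-12)
  # v3: missing genotype imputed to the mean of observed counts
  expect_equal(unname(g$counts[, 3]), c(1, 1, 1))
  expect_equal(attr(g, "imputed"), c(0L, 0L, 1L))
  # empty region sentinel
  empty <- read_vcf_region(path, list(chrom = "1", start = 5000, end = 6000))
  expect_equal(ncol(empty$counts), 0)
  # malformed GT names the record
  writeLines(c(readLines(path)[1:3],
               "1\t150\tvbad\tA\tT\t.\tPASS\t.\tGT\t0/2\t0/0\t0/0"), path)
  expect_error(read_vcf_region(path, list(chrom = "1", start = 1, end = 999)),
               "malformed GT.*vbad")
})

test_that("genotype scores: rank-1 proportionality and permutation equivariance", {
  set.seed(31)
  g1 <- geno_from_counts(cbind(hwe_counts(50, 0.3)))
  sc <- genotype_scores(encode(g1), J = 1)
  enc <- encode(g1)$values[, 1]
  expect_equal(abs(cor(sc$scores[, 1], enc)), 1, tolerance = 1e-10)

  g <- geno_from_counts(hwe_counts(40, runif(6, 0.1, 0.5)))
  sc_all <- genotype_scores(encode(g), var_threshold = 0.9)$scores
  perm <- sample(40)
  gp <- geno_from_counts(g$counts[perm, ])
  scp <- genotype_scores(encode(gp), var_threshold = 0.9)$scores
  expect_equal(scp, sc_all[perm, ], tolerance = 1e-10)
})

test_that("genotype score covariance matches the eigendecomposition oracle", {
  set.seed(32)
  g <- geno_from_counts(hwe_counts(200, runif(10, 0.05, 0.5)))
  e <- encode(g)
  sc <- genotype_scores(e, var_threshold = 0.999)
  # oracle: weighted covariance eigenvalues at the SNP nodes
  u <- (g$positions - g$start) / (g$end - g$start)
  w <- bfgm:::trapezoid_weights(u)
  K <- outer(sqrt(w), sqrt(w)) * cov(e$values)
  lam <- pmax(eigen(K, symmetric = TRUE, only.values = TRUE)$values, 0)
  J <- ncol(sc$scores)
  expect_lt(max(abs(diag(cov(sc$scores)) - lam[seq_len(J)])), 1e-6)
  expect_lt(max(abs(cov(sc$scores) - diag(diag(cov(sc$scores))))), 1e-6)
})

test_that("max r2 finds perfect, zero and brute-force maximal LD", {
  set.seed(33)
  c1 <- hwe_counts(500, c(0.2, 0.3, 0.4))
  g1 <- geno_from_counts(c1)
  # perfect LD: copy a column across genes
  g2 <- geno_from_counts(cbind(c1[, 2], hwe_counts(500, 0.25)))
  res <- max_r2(g1, g2)
  expect_equal(res$r2_max, 1.0, tolerance = 1e-12)
  expect_equal(res$pair, c(2, 1))
  # orthogonal columns give r2 = 0
  a <- rep(c(0, 1, 0, 1), 25)
  b <- rep(c(0, 0, 1, 1), 25)
  expect_equal(max_r2(geno_from_counts(cbind(a)),
                      geno_from_counts(cbind(b)))$r2_max, 0,
               tolerance = 1e-12)
  # brute-force all-pairs oracle
  g3 <- geno_from_counts(hwe_counts(300, runif(5, 0.1, 0.5)))
  g4 <- geno_from_counts(hwe_counts(300, runif(5, 0.1, 0.5)))
  res2 <- max_r2(g3, g4)
  oracle <- max(vapply(1:5, function(i) max(vapply(1:5, function(j)
    cor(g3$counts[, i], g4$counts[, j])^2, 0)), 0))
  expect_equal(res2$r2_max, oracle, tolerance = 1e-14)
  # monomorphic columns are skipped; all-monomorphic is a sentinel
  mono <- geno_from_counts(cbind(rep(0, 300)))
  expect_true(is.na(max_r2(mono, mono)$r2_max))
})
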