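# Shared fixture builders; everything is generated in code under fixed seeds.

# Smooth curves with low-rank cross-sample structure on an arbitrary grid.
rand_curves_on_grid <- function(n, m, seed = 1) {
  set.seed(seed)
  pts <- seq(0, 1, length.out = m + 1)
  shapes <- rbind(sin(pi * pts), cos(2 * pi * pts), pts^2)
  vals <- matrix(rnorm(n * 3), n, 3) %*% shapes + 5 +
    matrix(rnorm(n * (m + 1), 0, 0.1), n, m + 1)
  position_curve(vals, pts, start = 0, end = 1)
}

# Genotype matrix from explicit counts with evenly spaced positions.
geno_from_counts <- function(counts, positions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(positions)) positions <- seq_len(ncol(counts)) * 10
  genotype_matrix(counts, positions, chrom = "1")
}

# Independent HWE genotype draw (used where simulate_genotypes' region
# bookkeeping is irrelevant).
hwe_counts <- function(n, maf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(maf, function(f) rbinom(n, 2, f), numeric(n))
}

# Independent exact-HWE probability of a genotype table, from the closed-form
# conditional distribution (used as the oracle for hwe_exact_test).
hwe_table_prob <- function(n_hom_rare, n_het, n_hom_com) {
  n <- n_hom_rare + n_het + n_hom_com
  nr <- 2 * n_hom_rare + n_het
  exp(lfactorial(n) - lfactorial(n_hom_rare) - lfactorial(n_het) -
        lfactorial(n_hom_com) + n_het * log(2) +
        lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n))
}
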