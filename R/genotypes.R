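#' Genotype matrix for one gene region
#'
#' Minor-allele counts in `{0, 1, 2}` for `n` samples at `p` biallelic SNPs
#' with strictly increasing 1-based positions.  Columns whose sample allele
#' frequency exceeds 0.5 are re-oriented (counts flipped to `2 - c`) so that
#' `maf <= 0.5` always holds; frequencies are estimated from the sample
#' itself.
#'
#' @param counts n x p integer matrix of allele counts.
#' @param positions p strictly increasing genomic coordinates (bp, 1-based).
#' @param chrom chromosome label.
#' @param start,end region bounds; default to the position range.
#' @param orient flip columns with allele frequency > 0.5 (default `TRUE`).
#' @return object of class `genotype_matrix` with fields `counts`,
#'   `positions`, `chrom`, `start`, `end`, `maf`, `flipped`.
#' @export
genotype_matrix <- function(counts, positions, chrom = ".",
                            start = if (length(positions)) min(positions) else 0,
                            end = if (length(positions)) max(positions) else 1,
                            orient = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  positions <- as.numeric(positions)
  if (ncol(counts) != length(positions))
    stop("one position per SNP column required")
  ## non-decreasing is allowed on input: duplicated positions are a QC
  ## matter (qc_filter removes them); strictly increasing after QC
  if (length(positions) > 1 && any(diff(positions) < 0))
    stop("positions must be sorted")
  if (ncol(counts) > 0 && any(!is.finite(counts)))
    stop("no column may be entirely missing; impute before construction")
  flipped <- logical(ncol(counts))
  if (orient && ncol(counts) > 0) {
    af <- colMeans(counts) / 2
    flipped <- af > 0.5
    counts[, flipped] <- 2 - counts[, flipped, drop = FALSE]
  }
  maf <- if (ncol(counts)) colMeans(counts) / 2 else numeric(0)
  structure(list(counts = counts, positions = positions, chrom = chrom,
                 start = start, end = end, maf = maf, flipped = flipped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %s:[%s, %s]\n",
              nrow(x$counts), ncol(x$counts), x$chrom,
              format(x$start), format(x$end)))
  invisible(x)
}

is_empty_genotypes <- function(g) ncol(g$counts) == 0L

#' Read diploid biallelic genotypes from a VCF region
#'
#' Keeps biallelic SNPs inside the region, translates GT fields to counts of
#' the ALT allele, mean-imputes missing genotypes per SNP (recorded in the
#' `imputed` attribute), and orients each column so the minor allele is
#' counted (`maf <= 0.5`).
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region `list(chrom =, start =, end =)` or a vector
#'   `c(chrom, start, end)`; 1-based inclusive as in VCF.
#' @return a [genotype_matrix()]; zero columns if no variant falls in the
#'   region.
#' @export
read_vcf_region <- function(path, region) {
  if (!is.list(region))
    region <- list(chrom = region[[1]], start = as.numeric(region[[2]]),
                   end = as.numeric(region[[3]]))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  keep <- chrom == region$chrom & pos >= region$start & pos <= region$end &
    vcfR::is.biallelic(v)
  if (!any(keep))
    return(genotype_matrix(matrix(0, 0, 0), numeric(0), chrom = region$chrom,
                           start = region$start, end = region$end))
  gt <- vcfR::extract.gt(v[keep, ], element = "GT")
  pos <- pos[keep]
  ids <- rownames(gt) %||% as.character(pos)
  counts <- matrix(NA_real_, ncol(gt), nrow(gt))
  for (j in seq_len(nrow(gt))) {
    a <- gt[j, ]
    miss <- is.na(a) | a %in% c(".", "./.", ".|.")
    cnt <- rep(NA_real_, length(a))
    if (any(!miss)) {
      parts <- strsplit(a[!miss], "[/|]")
      bad <- vapply(parts, function(x)
        length(x) != 2L || !all(x %in% c("0", "1")), TRUE)
      if (any(bad))
        stop("malformed GT at record ", ids[j], ": ",
             paste(unique(a[!miss][bad]), collapse = ", "))
      cnt[!miss] <- vapply(parts, function(x) sum(x == "1"), 0)
    }
    counts[, j] <- cnt
  }
  ord <- order(pos)
  counts <- counts[, ord, drop = FALSE]
  pos <- pos[ord]
  imputed <- integer(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    miss <- is.na(counts[, j])
    if (all(miss)) stop("SNP at position ", pos[j], " entirely missing")
    if (any(miss)) {
      counts[miss, j] <- mean(counts[!miss, j])
      imputed[j] <- sum(miss)
    }
  }
  g <- genotype_matrix(counts, pos, chrom = region$chrom,
                       start = region$start, end = region$end)
  attr(g, "imputed") <- imputed
  g
}

#' Write a genotype matrix as a minimal plain-text VCF
#'
#' Emits a VCF 4.2 body with GT-only FORMAT, `REF=A`, `ALT=C`, for round-trip
#' use with [read_vcf_region()].  Fractional (imputed) counts are rounded to
#' the nearest genotype.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @export
write_vcf <- function(g, path) {
  n <- nrow(g$counts)
  samples <- paste0("S", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$counts))) {
    cnt <- pmin(pmax(round(g$counts[, j]), 0), 2)
    writeLines(paste(c(g$chrom, g$positions[j], paste0("snp", j), "A", "C",
                       ".", "PASS", ".", "GT", gt_str[cnt + 1]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype table `(nAA, nAa, naa)`: the
#' p-value is the total probability, under HWE given the allele counts, of
#' heterozygote counts no more probable than the observed one (two-sided,
#' enumeration over all compatible tables).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  ## log P(het = h | allele counts) up to a constant, via log-factorials
  lp <- lfactorial(n) - lfactorial((n_rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_rare + hets) / 2) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Quality-control filter for genotype matrices
#'
#' Removes, in order: SNPs at duplicated positions (first occurrence kept),
#' singleton SNPs (minor allele observed exactly once in the sample), and
#' SNPs failing the exact Hardy-Weinberg test at `hwe_alpha`
#' (default `1e-9`).  Applying the filter twice is the same as applying it
#' once.
#'
#' @param g a [genotype_matrix()].
#' @param hwe_alpha p-value below which HW disequilibrium is declared.
#' @param drop_singletons,drop_duplicates toggles for the two count-based
#'   rules.
#' @return filtered `genotype_matrix` with attribute `qc_report`, a data
#'   frame of removed positions and reasons.
#' @export
qc_filter <- function(g, hwe_alpha = 1e-9, drop_singletons = TRUE,
                      drop_duplicates = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$counts) < 2L) stop("QC needs at least 2 samples")
  p <- ncol(g$counts)
  reason <- rep(NA_character_, p)
  if (drop_duplicates && p > 1)
    reason[duplicated(g$positions)] <- "duplicate"
  for (j in seq_len(p)) {
    if (!is.na(reason[j])) next
    cnt <- round(g$counts[, j])
    mac <- min(sum(cnt), 2 * length(cnt) - sum(cnt))
    if (drop_singletons && mac == 1) {
      reason[j] <- "singleton"
      next
    }
    tab <- tabulate(cnt + 1L, 3L)
    if (hwe_exact_test(tab[1], tab[2], tab[3]) < hwe_alpha)
      reason[j] <- "hwe"
  }
  keep <- is.na(reason)
  report <- data.frame(position = g$positions[!keep],
                       reason = reason[!keep])
  out <- genotype_matrix(g$counts[, keep, drop = FALSE], g$positions[keep],
                         chrom = g$chrom, start = g$start, end = g$end,
                         orient = FALSE)
  attr(out, "qc_report") <- report
  out
}

#' Frequency-centered genotype encoding
#'
#' Encodes genotypes at each SNP by allele frequency: homozygous major
#' (count 0) as `2 P_m`, heterozygous as `P_m - P_M`, homozygous minor
#' (count 2) as `-2 P_M`, where `P_m` and `P_M` are the minor and major
#' allele frequencies of the SNP estimated from the sample.  Under exact
#' Hardy-Weinberg proportions the encoded column has population mean zero.
#' Monomorphic SNPs encode to all-zero columns and are flagged.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `encoded_genotypes`: `values` (n x p),
#'   `monomorphic` (logical per SNP), and the `source` matrix.
#' @export
encode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p_m <- g$maf
  p_M <- 1 - p_m
  ## value at count c: 2*p_m - c * (p_m + p_M) = 2*p_m - c  (since p_m+p_M=1)
  vals <- sweep(-g$counts, 2L, 2 * p_m, `+`)
  structure(list(values = vals, monomorphic = p_m == 0, source = g),
            class = "encoded_genotypes")
}

#' Functional principal component scores of the genotype function
#'
#' Treats each sample's frequency-centered encoded vector as function values
#' at the SNP positions mapped affinely into `[0, 1]`, and computes FPCA
#' scores with non-uniform trapezoid quadrature at those nodes (the genotype
#' function is kept discrete; no smoother is applied to step-like data).
#'
#' @param e an [encode()]d genotype set.
#' @param J number of components, or `NULL` to use `var_threshold`.
#' @param var_threshold cumulative variance fraction to reach (default 0.8
#'   when `J` is `NULL`).
#' @return list with `scores` (n x J) and `basis` (see [fit_fpca()]);
#'   requesting more components than the rank truncates with a flag.
#' @export
genotype_scores <- function(e, J = NULL, var_threshold = NULL) {
  stopifnot(inherits(e, "encoded_genotypes"))
  g <- e$source
  if (is_empty_genotypes(g)) stop("no SNPs to score")
  if (is.null(J) && is.null(var_threshold)) var_threshold <- 0.8
  start <- g$start
  end <- g$end
  if (end <= start) {  # single-SNP region: place the point mass mid-interval
    start <- start - 1
    end <- end + 1
  }
  curve <- position_curve(e$values, g$positions, chrom = g$chrom,
                          start = start, end = end)
  fit_fpca(curve, n_components = J, var_threshold = var_threshold)
}

#' Maximum linkage-disequilibrium r-squared between two genes
#'
#' Squared Pearson correlation of minor-allele counts over every cross-gene
#' SNP pair; monomorphic columns are skipped.  The p-value is the
#' correlation test of the maximizing pair.
#'
#' @param g1,g2 [genotype_matrix()] objects over the same samples in the
#'   same order.
#' @return list `r2_max`, `pair` (column indices in `g1`, `g2`), `p_value`;
#'   all `NA` if every pair is degenerate.
#' @export
max_r2 <- function(g1, g2) {
  stopifnot(nrow(g1$counts) == nrow(g2$counts))
  sd1 <- apply(g1$counts, 2L, stats::sd)
  sd2 <- apply(g2$counts, 2L, stats::sd)
  ok1 <- which(sd1 > 0)
  ok2 <- which(sd2 > 0)
  if (!length(ok1) || !length(ok2))
    return(list(r2_max = NA_real_, pair = c(NA_integer_, NA_integer_),
                p_value = NA_real_))
  r <- stats::cor(g1$counts[, ok1, drop = FALSE],
                  g2$counts[, ok2, drop = FALSE])
  r2 <- r^2
  idx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
  pair <- c(ok1[idx[1]], ok2[idx[2]])
  pv <- stats::cor.test(g1$counts[, pair[1]], g2$counts[, pair[2]])$p.value
  list(r2_max = max(r2), pair = unname(pair), p_value = pv)
}
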