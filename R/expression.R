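#' Gene-level count table
#'
#' @param counts nonnegative n samples x G genes matrix.
#' @param gene_lengths G positive lengths in bp.
#' @param library_sizes per-sample totals; default `rowSums(counts)`.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, gene_lengths,
                        library_sizes = rowSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(gene_lengths) != ncol(counts))
    stop("one length per gene required")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts, gene_lengths = as.numeric(gene_lengths),
                 library_sizes = as.numeric(library_sizes)),
            class = "count_table")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio of its count
#' to the gene's geometric mean across samples.  The reference set is the
#' genes with all-positive counts; with `pseudo_reference = TRUE` the
#' geometric mean is instead taken over the positive counts only, so genes
#' with scattered zeros still contribute.  No global rescaling is applied
#' (raw median-of-ratios convention).
#'
#' @param ct a [count_table()].
#' @param pseudo_reference fall back to positive-count geometric means.
#' @return n positive size factors.
#' @export
size_factors <- function(ct, pseudo_reference = FALSE) {
  stopifnot(inherits(ct, "count_table"))
  counts <- ct$counts
  if (pseudo_reference) {
    geo <- apply(counts, 2L, function(x) {
      pos <- x > 0
      if (!any(pos)) return(0)
      exp(mean(log(x[pos])))
    })
    ref <- geo > 0
  } else {
    ref <- colSums(counts > 0) == nrow(counts)
    if (!any(ref))
      stop("no gene has all-positive counts; retry with pseudo_reference = TRUE")
    geo <- exp(colMeans(log(counts[, ref, drop = FALSE])))
    geo <- replace(numeric(ncol(counts)), which(ref), geo)
  }
  apply(counts[, ref, drop = FALSE], 1L,
        function(x) stats::median(x / geo[ref]))
}

#' Reads per kilobase per million mapped reads
#'
#' `1e9 * count / (gene_length * library_size)`.
#'
#' @param ct a [count_table()].
#' @return n x G matrix of RPKM values.
#' @export
rpkm <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(ct$library_sizes <= 0)) stop("zero library size")
  1e9 * ct$counts / outer(ct$library_sizes, ct$gene_lengths)
}

#' Expressing-rate gene filter
#'
#' A gene is retained when the fraction of samples with any nonzero read over
#' the gene is at least `min_rate` (boundary inclusive).
#'
#' @param curves named list of [position_curve()]s, one per gene.
#' @param min_rate minimum expressing rate (default 0.30).
#' @return list with `retained` (names or indices) and `report` data frame of
#'   per-gene rates and decisions.
#' @export
expressing_rate_filter <- function(curves, min_rate = 0.30) {
  rates <- vapply(curves, function(cv) mean(rowSums(cv$values) > 0), 0)
  keep <- rates >= min_rate
  ids <- names(curves) %||% seq_along(curves)
  list(retained = ids[keep],
       report = data.frame(gene = ids, expressing_rate = rates,
                           retained = keep, row.names = NULL))
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (average-tie) ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default.  The output depends on the input only through ranks, so any
#' strictly increasing transformation of the input leaves it unchanged.
#'
#' @param values n numeric values (n >= 2, not all equal).
#' @param offset rank offset `c` (Blom 3/8 default).
#' @return object of class `scalar_trait` with fields `values` and
#'   `transform_applied = "inverse-normal"`.
#' @export
inverse_normal <- function(values, offset = 3 / 8) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("inverse normal transform needs n >= 2")
  if (max(values) == min(values))
    stop("all values identical: transform undefined")
  r <- rank(values, ties.method = "average")
  scalar_trait(stats::qnorm((r - offset) / (n - 2 * offset + 1)),
               transform = "inverse-normal")
}

#' Scalar expression trait
#'
#' @param values n finite values.
#' @param transform tag recording the transformation applied
#'   (`"none"` or `"inverse-normal"`).
#' @return object of class `scalar_trait`.
#' @export
scalar_trait <- function(values, transform = "none") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("trait values must be finite")
  structure(list(values = values, transform_applied = transform),
            class = "scalar_trait")
}

#' Read a gene-level count TSV
#'
#' Expected columns: `gene`, `length`, then one column per sample.
#'
#' @param path file path.
#' @return a [count_table()] (samples in rows) with gene names attached.
#' @export
read_gene_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  colnames(counts) <- tab[[1]]
  count_table(counts, tab[[2]])
}
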