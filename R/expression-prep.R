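## Expression preprocessing: keep expressed probes of candidate genes,
## flag outlier samples, and reduce to one representative (most connected)
## probe per gene.

#' Keep expressed probes of candidate genes
#'
#' Retains rows mapped to \code{candidate_genes} whose mean value across
#' samples exceeds the median of all rows' means over the entire array
#' (not just the candidates) — the usual "expressed above the array
#' median" filter.
#'
#' @param data an \linkS4class{ExpressionDataset}.
#' @param candidate_genes gene ids to keep probes for.
#' @return the filtered \linkS4class{ExpressionDataset}; the numbers kept
#'   and total are reported with a message.
#' @export
filterExpressed <- function(data, candidate_genes) {
  m <- exprsMatrix(data)
  row_means <- rowMeans(m)
  # the whole-array median is fixed at the first filtering pass and kept in
  # the object's metadata, so re-filtering an already filtered dataset is a
  # no-op rather than a second halving
  array_median <- S4Vectors::metadata(data)$array_median_expression
  if (is.null(array_median)) array_median <- median(row_means)
  keep <- probeGene(data) %in% candidate_genes & row_means > array_median
  message(sum(keep), " of ", nrow(m), " rows kept (candidates expressed above the array median)")
  if (!any(keep))
    stop("no candidate probes above the array median: empty result")
  out <- data[keep, ]
  S4Vectors::metadata(out)$array_median_expression <- array_median
  out
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' Each sample's mean Pearson correlation with every other sample is
#' standardized across samples; samples with z below \code{-z_cut} are
#' flagged. Removal is a separate, explicit step
#' (\code{\link{removeSamples}}) so the flag list stays auditable.
#'
#' @param data an \linkS4class{ExpressionDataset} with at least 4 samples.
#' @param z_cut flagging threshold on the standardized score (default 2.5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detectOutlierSamples <- function(data, z_cut = 2.5) {
  m <- exprsMatrix(data)
  if (ncol(m) < 4L) stop("need at least 4 samples")
  cc <- cor(m)
  diag(cc) <- NA
  mean_cor <- colMeans(cc, na.rm = TRUE)
  s <- sd(mean_cor)
  if (s == 0) return(character())   # perfectly homogeneous: nothing to flag
  z <- (mean_cor - mean(mean_cor)) / s
  flagged <- colnames(m)[z < -z_cut]
  if (length(flagged) == ncol(m)) stop("all samples flagged: pathological input")
  flagged
}

#' @rdname detectOutlierSamples
#' @param samples sample ids to drop.
#' @export
removeSamples <- function(data, samples) {
  keep <- !colnames(data) %in% samples
  if (!any(keep)) stop("removing all samples")
  data[, keep]
}

#' Reduce to the most connected probe per gene
#'
#' For genes represented by several probes, keeps the probe with the
#' highest preliminary total connectivity \eqn{k = \sum_j |cor|^\beta} over
#' all other filtered rows (the same soft-threshold power later used for
#' the network). Ties break by row id; single-probe genes pass through.
#'
#' @param data a filtered \linkS4class{ExpressionDataset} with >= 2 rows.
#' @param beta soft-threshold power for the preliminary connectivity.
#' @return an \linkS4class{ExpressionDataset} with exactly one row per gene.
#' @export
selectProbePerGene <- function(data, beta = 6) {
  m <- exprsMatrix(data)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  a <- abs(cor(t(m)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  gene <- probeGene(data)
  ord <- order(gene, -k, rownames(m))
  keep_rows <- rownames(m)[ord][!duplicated(gene[ord])]
  out <- data[sort(match(keep_rows, rownames(m))), ]
  # rows become genes: rename rows by gene id for downstream stages
  rownames(out) <- unname(probeGene(out))
  out
}
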