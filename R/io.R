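## Readers and writers for the pipeline's file dialects. All tables are
## tab-delimited with a header row; '#' lines are comments. Parsing is
## strict: malformed content is an error naming the file and (where
## possible) the offending line, never a silent drop.

stopIo <- function(path, ...) stop(path, ": ", ..., call. = FALSE)

readTsv <- function(path, ...) {
  if (!file.exists(path)) stopIo(path, "file not found")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read a GWAS summary-statistics table
#'
#' Layout: \code{snp  chrom  pos  p_<trait>...}, tab-delimited with header;
#' positions are 1-based in the file. P-values must be numeric in (0, 1].
#'
#' @param path file path.
#' @return data.frame with columns snp, chrom, pos and one \code{p_<trait>}
#'   column per trait.
#' @export
readGwasTable <- function(path) {
  x <- readTsv(path)
  need <- c("snp", "chrom", "pos")
  if (!all(need %in% names(x)))
    stopIo(path, "missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  pcols <- grep("^p_", names(x), value = TRUE)
  if (!length(pcols)) stopIo(path, "no p_<trait> columns found")
  if (anyDuplicated(x$snp))
    stopIo(path, "duplicate snp id: ", x$snp[duplicated(x$snp)][1])
  if (any(bad <- !is.finite(x$pos) | x$pos < 1))
    stopIo(path, "pos must be >= 1 (line ", which(bad)[1] + 1L, ")")
  for (pc in pcols) {
    v <- x[[pc]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stopIo(path, "non-numeric P in column ", pc)
    if (any(bad <- v <= 0 | v > 1))
      stopIo(path, "P outside (0,1] in column ", pc,
             " (line ", which(bad)[1] + 1L, ")")
  }
  x$chrom <- as.character(x$chrom)
  x
}

#' @rdname readGwasTable
#' @param x GWAS table as returned by \code{readGwasTable}.
#' @export
writeGwasTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pairwise LD records
#'
#' Accepts the PLINK \code{.ld} dialect (whitespace-separated,
#' \code{CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2}) or a minimal
#' \code{snp_a snp_b r2} table. r2 must lie in [0, 1].
#'
#' @param path file path.
#' @return data.frame with columns snp_a, snp_b, r2.
#' @export
readLdTable <- function(path) {
  if (!file.exists(path)) stopIo(path, "file not found")
  x <- utils::read.table(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("SNP_A", "SNP_B", "R2") %in% names(x)))
    x <- data.frame(snp_a = x$SNP_A, snp_b = x$SNP_B, r2 = x$R2,
                    stringsAsFactors = FALSE)
  else if (!all(c("snp_a", "snp_b", "r2") %in% names(x)))
    stopIo(path, "expected PLINK .ld columns or snp_a/snp_b/r2")
  if (!is.numeric(x$r2) || any(!is.finite(x$r2)))
    stopIo(path, "non-numeric r2")
  if (any(bad <- x$r2 < 0 | x$r2 > 1))
    stopIo(path, "r2 outside [0,1] (line ", which(bad)[1] + 1L, ")")
  x
}

#' @rdname readLdTable
#' @param ld data.frame snp_a/snp_b/r2.
#' @param gwas GWAS table supplying chromosome and position per SNP.
#' @export
writeLdTable <- function(ld, gwas, path) {
  ix_a <- match(ld$snp_a, gwas$snp); ix_b <- match(ld$snp_b, gwas$snp)
  if (anyNA(ix_a) || anyNA(ix_b))
    stop("LD records reference SNPs absent from the GWAS table")
  out <- data.frame(CHR_A = gwas$chrom[ix_a], BP_A = gwas$pos[ix_a],
                    SNP_A = ld$snp_a, CHR_B = gwas$chrom[ix_b],
                    BP_B = gwas$pos[ix_b], SNP_B = ld$snp_b, R2 = ld$r2)
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED6 gene annotation
#'
#' Six columns without header: chrom, start, end, name, score, strand;
#' coordinates 0-based half-open (kept as such internally).
#'
#' @param path file path.
#' @return data.frame gene_id, chrom, start, end, strand.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopIo(path, "file not found")
  x <- utils::read.table(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) != 6L) stopIo(path, "expected 6 BED columns, got ", ncol(x))
  names(x) <- c("chrom", "start", "end", "gene_id", "score", "strand")
  if (any(bad <- x$start >= x$end))
    stopIo(path, "start >= end at line ", which(bad)[1])
  if (anyDuplicated(x$gene_id))
    stopIo(path, "duplicate gene_id: ", x$gene_id[duplicated(x$gene_id)][1])
  if (!all(x$strand %in% c("+", "-")))
    stopIo(path, "strand must be + or -")
  data.frame(gene_id = x$gene_id, chrom = as.character(x$chrom),
             start = x$start, end = x$end, strand = x$strand,
             stringsAsFactors = FALSE)
}

#' @rdname readBed
#' @param genes annotation data.frame (gene_id, chrom, start, end, strand).
#' @export
writeBed <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' TSV with a leading \code{row_id} column and one column per sample.
#'
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
readExpression <- function(path) {
  x <- readTsv(path)
  if (names(x)[1] != "row_id") stopIo(path, "first column must be row_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$row_id
  if (!is.numeric(m) || anyNA(m))
    stopIo(path, "expression values must be numeric with no missing entries")
  m
}

#' @rdname readExpression
#' @param m numeric matrix.
#' @export
writeExpression <- function(m, path) {
  out <- data.frame(row_id = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample phenotype table
#'
#' TSV \code{sample  status} with status in {0 = low, 1 = high}.
#'
#' @param path file path.
#' @return integer vector named by sample.
#' @export
readPhenotype <- function(path) {
  x <- readTsv(path)
  if (!all(c("sample", "status") %in% names(x)))
    stopIo(path, "expected columns sample, status")
  if (!all(x$status %in% c(0L, 1L)))
    stopIo(path, "status must be 0 or 1")
  setNames(as.integer(x$status), x$sample)
}

#' @rdname readPhenotype
#' @param phen named integer vector (sample -> 0/1).
#' @export
writePhenotype <- function(phen, path) {
  write.table(data.frame(sample = names(phen), status = unname(phen)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an optional probe-to-gene map
#'
#' TSV \code{probe  gene_id}.
#'
#' @param path file path.
#' @return named character vector (probe -> gene_id).
#' @export
readProbeGene <- function(path) {
  x <- readTsv(path)
  if (!all(c("probe", "gene_id") %in% names(x)))
    stopIo(path, "expected columns probe, gene_id")
  if (anyDuplicated(x$probe)) stopIo(path, "duplicate probe ids")
  setNames(x$gene_id, x$probe)
}

#' Assemble an ExpressionDataset from its files
#'
#' @param expr_path expression TSV (see \code{\link{readExpression}}).
#' @param phen_path phenotype TSV (see \code{\link{readPhenotype}}).
#' @param probe2gene_path optional probe-to-gene TSV.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
readExpressionDataset <- function(expr_path, phen_path,
                                  probe2gene_path = NULL) {
  m <- readExpression(expr_path)
  phen <- readPhenotype(phen_path)
  if (!all(colnames(m) %in% names(phen)))
    stopIo(phen_path, "phenotype missing for samples: ",
           paste(head(setdiff(colnames(m), names(phen)), 5L), collapse = ", "))
  p2g <- if (is.null(probe2gene_path)) NULL else readProbeGene(probe2gene_path)
  ExpressionDataset(m, phen[colnames(m)], p2g)
}

#' Read / write GMT gene-set collections
#'
#' Each GMT line is \code{name<TAB>description<TAB>gene...}.
#'
#' @param path file path.
#' @return named list of gene-id character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stopIo(path, "file not found")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopIo(path, "GMT line ", i, " has fewer than 3 fields")
    sets[[f[1]]] <- f[-(1:2)]
  }
  sets
}

#' @rdname readGmt
#' @param sets named list of gene-id vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "synthetic gene set", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a subnetwork as SIF + node attributes
#'
#' SIF rows are \code{gene_a  tom  gene_b}; node attributes (module,
#' signed gene significance, -log10 GWAS P) go to a companion TSV when
#' provided.
#'
#' @param subgraph list with \code{edges} (gene_a, gene_b, tom) and
#'   \code{nodes} (data.frame with at least gene_id), as returned by
#'   \code{\link{extractSubmodule}}.
#' @param path SIF file path; node attributes are written to
#'   \code{<path>.nodes.tsv} when the subgraph carries annotations.
#' @export
writeSif <- function(subgraph, path) {
  e <- subgraph$edges
  writeLines(sprintf("%s\ttom\t%s", e$gene_a, e$gene_b), path)
  if (!is.null(subgraph$nodes) && ncol(subgraph$nodes) > 1L)
    write.table(subgraph$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an \code{hclust} tree.
#' @param path output file.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Read / write per-gene GWAS score tables
#'
#' Layout: \code{gene_id chrom length_bp n_snps n_clusters unadj_p_<trait>
#' adj_p_<trait>...}.
#'
#' @param path file path.
#' @return the score data.frame.
#' @export
readGeneScores <- function(path) {
  x <- readTsv(path)
  need <- c("gene_id", "chrom", "length_bp", "n_snps", "n_clusters")
  if (!all(need %in% names(x)))
    stopIo(path, "missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  x
}

#' @rdname readGeneScores
#' @param scores score table from \code{\link{genePvalues}}.
#' @export
writeGeneScores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the per-gene network statistics table
#'
#' @param path file path.
#' @return the stats data.frame.
#' @export
readGeneStats <- function(path) {
  x <- readTsv(path)
  need <- c("gene_id", "module", "mm", "gs", "gs_signed", "k_in", "k_total")
  if (!all(need %in% names(x)))
    stopIo(path, "missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  x
}

#' @rdname readGeneStats
#' @param stats stats table from \code{\link{computeGeneStats}}.
#' @export
writeGeneStats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
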