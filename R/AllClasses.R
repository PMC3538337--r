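#' @import methods
#' @importFrom stats cor cor.test sd median fisher.test pnorm qnorm rnorm
#'   runif rbinom hclust cutree as.dist lm coef quantile setNames var
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Expression dataset with a binary phenotype
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{exprs} assay of
#' log-scale normalized intensities (rows = probes or genes, columns =
#' samples), a binary phenotype (0 = low, 1 = high) in \code{colData}, and a
#' probe-to-gene map in \code{rowData} (identity when rows already are
#' genes).
#'
#' @slot .Data inherited SummarizedExperiment content.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else if (anyNA(SummarizedExperiment::assay(object, "exprs")))
    msg <- c(msg, "missing values in 'exprs' are a load error")
  cd <- SummarizedExperiment::colData(object)
  if (!"phenotype" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'phenotype'")
  else if (!all(cd$phenotype %in% c(0L, 1L)))
    msg <- c(msg, "phenotype must be coded 0 (low) / 1 (high) for every sample")
  if (!"gene_id" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'gene_id'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "row ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, rows = probes/genes, columns = samples;
#'   no missing values.
#' @param phenotype integer vector (0 = low, 1 = high), one per sample,
#'   named by sample id or in column order.
#' @param probe2gene named character vector mapping row id to gene id;
#'   defaults to the identity map (rows are genes).
#' @return An \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(values, phenotype, probe2gene = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix must have row ids")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[colnames(values)]
  if (length(phenotype) != ncol(values) || anyNA(phenotype))
    stop("phenotype must be defined for every sample")
  if (is.null(probe2gene))
    probe2gene <- setNames(rownames(values), rownames(values))
  gene <- unname(probe2gene[rownames(values)])
  if (anyNA(gene))
    stop("probe2gene does not cover rows: ",
         paste(head(rownames(values)[is.na(gene)], 5L), collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(gene_id = gene, row.names = rownames(values)),
    colData = S4Vectors::DataFrame(phenotype = as.integer(phenotype),
                                   row.names = colnames(values)))
  new("ExpressionDataset", se)
}

#' @describeIn ExpressionDataset the expression matrix.
#' @param x an ExpressionDataset.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn ExpressionDataset integer phenotype vector named by sample.
#' @export
phenotype <- function(x) {
  setNames(SummarizedExperiment::colData(x)$phenotype, colnames(x))
}

#' @describeIn ExpressionDataset named probe-to-gene map.
#' @export
probeGene <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$gene_id, rownames(x))
}

#' Weighted gene coexpression network
#'
#' Soft-thresholded adjacency and topological overlap over a set of genes,
#' with the module partition and the average-linkage dendrogram used to
#' obtain it. Module labels are WGCNA-style color names assigned by
#' descending module size; \code{"grey"} collects unassigned genes.
#'
#' @slot gene_ids character, the network genes.
#' @slot adjacency symmetric matrix in [0,1], zero diagonal.
#' @slot tom symmetric topological overlap matrix in [0,1], unit diagonal.
#' @slot beta soft-threshold power used.
#' @slot partition named character vector gene -> module label.
#' @slot dendrogram the hclust tree (or NULL before detection).
#' @export
setClass("CoexpressionNetwork",
         representation(gene_ids = "character", adjacency = "matrix",
                        tom = "matrix", beta = "numeric",
                        partition = "character", dendrogram = "ANY"))

setValidity("CoexpressionNetwork", function(object) {
  n <- length(object@gene_ids)
  msg <- character()
  if (!all(dim(object@adjacency) == n))
    msg <- c(msg, "adjacency dimension must match gene_ids")
  if (length(object@tom) && !all(dim(object@tom) == n))
    msg <- c(msg, "tom dimension must match gene_ids")
  if (length(object@partition) &&
      !setequal(names(object@partition), object@gene_ids))
    msg <- c(msg, "partition must label exactly the network genes")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork adjacency matrix accessor.
#' @param x a CoexpressionNetwork.
#' @export
networkAdjacency <- function(x) x@adjacency

#' @describeIn CoexpressionNetwork TOM accessor.
#' @export
networkTom <- function(x) x@tom

#' @describeIn CoexpressionNetwork module partition accessor (named
#'   character vector, gene -> color label).
#' @export
modulePartition <- function(x) x@partition

#' @describeIn CoexpressionNetwork soft-threshold power accessor.
#' @export
softPower <- function(x) x@beta

#' @describeIn CoexpressionNetwork hclust dendrogram accessor.
#' @export
networkDendrogram <- function(x) x@dendrogram

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@gene_ids), "genes, beta =",
      object@beta, "\n")
  if (length(object@partition)) {
    tab <- sort(table(object@partition), decreasing = TRUE)
    cat("modules:\n")
    print(tab)
  } else cat("modules: not yet detected\n")
})

#' Module eigengenes
#'
#' First right singular vectors of the row-standardized module
#' submatrices: one unit-norm, sample-length summary profile per module,
#' oriented so its correlation with the module mean expression is
#' non-negative.
#'
#' @slot eigengenes matrix, samples x modules (column names = module labels).
#' @slot varianceExplained named numeric, share of module variance carried
#'   by the eigengene.
#' @export
setClass("ModuleEigengenes",
         representation(eigengenes = "matrix", varianceExplained = "numeric"))

#' @describeIn ModuleEigengenes samples x modules eigengene matrix.
#' @param x a ModuleEigengenes object.
#' @export
eigengeneMatrix <- function(x) x@eigengenes

#' @describeIn ModuleEigengenes proportion of variance explained per module.
#' @export
varianceExplained <- function(x) x@varianceExplained

setMethod("show", "ModuleEigengenes", function(object) {
  cat("ModuleEigengenes:", ncol(object@eigengenes), "modules x",
      nrow(object@eigengenes), "samples\n")
  print(round(object@varianceExplained, 3))
})

#' Configuration of the synthetic GWAS + expression bundle
#'
#' Defines every parameter of the coupled synthetic datasets: a discovery
#' GWAS with LD blocks and planted associated genes, gene annotation, an
#' expression matrix with planted coexpression modules partially coupled to
#' a binary phenotype, a planted pathway gene set, and a replication GWAS.
#' See \code{\link{simulationConfig}} for defaults and semantics.
#'
#' @export
setClass("SimulationConfig",
  representation(
    n_genes = "integer", n_snps_per_gene = "integer",
    n_ld_blocks_per_gene = "integer", within_block_r2 = "numeric",
    genome_layout = "numeric", gene_length_range = "numeric",
    n_true_genes = "integer", true_gene_effect = "numeric",
    n_samples = "integer", n_modules = "integer", module_sizes = "integer",
    module_factor_sd = "numeric", noise_sd = "numeric",
    phenotype_coupling = "numeric", planted_geneset_module = "integer",
    replication_signal_share = "numeric", n_traits = "integer",
    n_replication_traits = "integer", trait_cor = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (sum(object@module_sizes) > object@n_genes)
    msg <- c(msg, "module_sizes: sum exceeds n_genes")
  if (any(object@module_sizes < 3L))
    msg <- c(msg, "module_sizes: all module sizes must be >= 3")
  if (length(object@module_sizes) != object@n_modules)
    msg <- c(msg, "module_sizes: length must equal n_modules")
  if (object@within_block_r2 < 0 || object@within_block_r2 > 1)
    msg <- c(msg, "within_block_r2: must lie in [0,1]")
  if (length(object@n_snps_per_gene) != 2L ||
      any(object@n_snps_per_gene < 1L) || diff(object@n_snps_per_gene) < 0)
    msg <- c(msg, "n_snps_per_gene: must be an increasing range of counts >= 1")
  if (any(object@phenotype_coupling < -1) || any(object@phenotype_coupling > 1))
    msg <- c(msg, "phenotype_coupling: coefficients must lie in [-1,1]")
  if (length(object@phenotype_coupling) &&
      is.null(names(object@phenotype_coupling)))
    msg <- c(msg, "phenotype_coupling: must be named by module index")
  if (object@n_true_genes > object@n_genes)
    msg <- c(msg, "n_true_genes: exceeds n_genes")
  if (object@n_true_genes < sum(object@module_sizes))
    msg <- c(msg, "n_true_genes: must cover all planted module genes")
  if (object@planted_geneset_module > object@n_modules)
    msg <- c(msg, "planted_geneset_module: not a module index")
  if (object@replication_signal_share < 0 || object@replication_signal_share > 1)
    msg <- c(msg, "replication_signal_share: must lie in [0,1]")
  if (object@trait_cor < 0 || object@trait_cor >= 1)
    msg <- c(msg, "trait_cor: must lie in [0,1)")
  if (length(object@gene_length_range) != 2L ||
      diff(object@gene_length_range) < 0 || any(object@gene_length_range < 1))
    msg <- c(msg, "gene_length_range: must be an increasing bp range")
  if (is.null(names(object@genome_layout)) || any(object@genome_layout < 1))
    msg <- c(msg, "genome_layout: named per-chromosome spacing in bp required")
  if (length(msg)) msg else TRUE
})

#' Coupled synthetic datasets for the whole pipeline
#'
#' @slot gwas discovery GWAS table (snp, chrom, pos, p_<trait>...).
#' @slot ld pairwise LD records (snp_a, snp_b, r2).
#' @slot genes gene annotation (gene_id, chrom, start, end, strand),
#'   0-based half-open.
#' @slot expression an \linkS4class{ExpressionDataset} (genes x samples).
#' @slot genesets named list of gene-id character vectors (GMT-like).
#' @slot replication_gwas second GWAS table in the same layout.
#' @slot truth per-gene truth: gene_id, true_associated, module (integer,
#'   0 = background), pathway_member, replication_planted.
#' @slot config the \linkS4class{SimulationConfig} that produced the bundle.
#' @export
setClass("SyntheticBundle",
  representation(gwas = "data.frame", ld = "data.frame", genes = "data.frame",
                 expression = "ExpressionDataset", genesets = "list",
                 replication_gwas = "data.frame", truth = "data.frame",
                 config = "SimulationConfig"))

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle:", nrow(object@genes), "genes,",
      nrow(object@gwas), "SNPs,", ncol(object@expression), "samples,",
      length(object@genesets), "gene sets (seed", object@config@seed, ")\n")
})
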