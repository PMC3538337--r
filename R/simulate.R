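#' Configure the synthetic GWAS + expression bundle
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults emulate,
#' at desk scale, the study design the pipeline targets: a two-trait
#' bone-mineral-density discovery GWAS over a few hundred genes with LD
#' blocks and SNP counts scaling with gene length, a 24-sample monocyte-like
#' expression matrix (12 low / 12 high phenotype) with three planted
#' coexpression modules of 80/60/50 genes, the first module coupled to the
#' phenotype at c = 0.6, a planted pathway gene set concentrated in that
#' module, and a three-trait replication GWAS whose signal is carried by
#' module co-membership.
#'
#' @param n_genes number of genes.
#' @param n_snps_per_gene integer range c(lo, hi); a gene's SNP count scales
#'   linearly with its length across this range (so gene length and SNP
#'   density are genuine confounders, as in real array GWAS).
#' @param n_ld_blocks_per_gene LD blocks for a gene of average length;
#'   block count scales with gene length (blocks span a roughly constant
#'   genomic scale), which makes length and SNP density genuine
#'   confounders of the unadjusted gene-wide P.
#' @param within_block_r2 pairwise r2 written for SNPs of the same block
#'   (cross-block pairs get r2 < 0.5).
#' @param genome_layout named numeric: per-chromosome spacing in bp between
#'   consecutive genes; genes are distributed contiguously across the named
#'   chromosomes.
#' @param gene_length_range bp range gene lengths are drawn from (uniform).
#' @param n_true_genes number of genes planted with GWAS signal; all module
#'   genes are true genes, the remainder are drawn from the background.
#' @param true_gene_effect normal noncentrality of the block-level
#'   association Z-scores of true genes; SNP Z-scores share their block's
#'   score with correlation sqrt(within_block_r2) and P-values are
#'   two-sided, so null SNP P-values are exactly Uniform(0, 1).
#' @param n_samples expression samples (split as evenly as possible into
#'   phenotype 0 / 1).
#' @param n_modules,module_sizes planted coexpression modules.
#' @param module_factor_sd standard deviation of the module factors.
#' @param noise_sd standard deviation of gene-level expression noise.
#' @param phenotype_coupling named numeric, module index -> coupling
#'   coefficient c in [-1,1]; a coupled module's factor is
#'   c*z + sqrt(1-c^2)*eta with z the standardized binary phenotype.
#' @param planted_geneset_module module receiving the planted pathway genes.
#' @param replication_signal_share fraction of module-member true genes
#'   re-planted with signal in the replication GWAS.
#' @param n_traits discovery traits (default 2, like hip and spine BMD).
#' @param n_replication_traits replication traits (default 3).
#' @param trait_cor correlation of block-level association Z-scores across
#'   traits of the same study (default 0.7; skeletal-site BMD measures are
#'   strongly correlated, so their association statistics are too).
#' @param seed integer seed governing the whole bundle.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n_genes = 900L,
                             n_snps_per_gene = c(2L, 12L),
                             n_ld_blocks_per_gene = 2L,
                             within_block_r2 = 0.9,
                             genome_layout = c("1" = 30000, "2" = 30000,
                                               "3" = 30000),
                             gene_length_range = c(5000, 60000),
                             n_true_genes = 600L,
                             true_gene_effect = 3,
                             n_samples = 24L,
                             n_modules = 3L,
                             module_sizes = c(80L, 60L, 50L),
                             module_factor_sd = 1,
                             noise_sd = 0.55,
                             phenotype_coupling = c("1" = 0.6),
                             planted_geneset_module = 1L,
                             replication_signal_share = 0.6,
                             n_traits = 2L,
                             n_replication_traits = 3L,
                             trait_cor = 0.7,
                             seed = 1L) {
  cfg <- new("SimulationConfig",
    n_genes = as.integer(n_genes),
    n_snps_per_gene = as.integer(n_snps_per_gene),
    n_ld_blocks_per_gene = as.integer(n_ld_blocks_per_gene),
    within_block_r2 = as.numeric(within_block_r2),
    genome_layout = genome_layout,
    gene_length_range = as.numeric(gene_length_range),
    n_true_genes = as.integer(n_true_genes),
    true_gene_effect = as.numeric(true_gene_effect),
    n_samples = as.integer(n_samples),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    module_factor_sd = as.numeric(module_factor_sd),
    noise_sd = as.numeric(noise_sd),
    phenotype_coupling = phenotype_coupling,
    planted_geneset_module = as.integer(planted_geneset_module),
    replication_signal_share = as.numeric(replication_signal_share),
    n_traits = as.integer(n_traits),
    n_replication_traits = as.integer(n_replication_traits),
    trait_cor = as.numeric(trait_cor),
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

discoveryTraits <- function(n) c("hbmd", "sbmd", paste0("trait", seq_len(max(0, n - 2L))))[seq_len(n)]
replicationTraits <- function(n) c("fn", "ls", "tr", paste0("rtrait", seq_len(max(0, n - 3L))))[seq_len(n)]

# Draw one GWAS table over a fixed SNP layout. Association Z-scores are
# drawn per LD block and trait (mean = effect for planted genes, 0
# otherwise) with correlation trait_cor across traits of the same study
# (related clinical traits share association signal); SNP-level Z-scores
# share their block score with correlation sqrt(r2), mirroring how LD
# correlates test statistics. P-values are two-sided, so null SNP
# P-values are exactly Uniform(0,1).
drawGwasP <- function(snps, planted_genes, traits, effect, within_block_r2,
                      trait_cor) {
  r <- sqrt(within_block_r2)
  blocks <- unique(snps$block)
  block_gene <- snps$gene[match(blocks, snps$block)]
  bix <- match(snps$block, blocks)
  mu <- ifelse(block_gene %in% planted_genes, effect, 0)
  w <- rnorm(length(blocks))   # shared across-trait block component
  p <- matrix(NA_real_, nrow(snps), length(traits))
  for (t in seq_along(traits)) {
    zb <- mu + sqrt(trait_cor) * w +
      sqrt(1 - trait_cor) * rnorm(length(blocks))
    z <- r * zb[bix] + sqrt(1 - r^2) * rnorm(nrow(snps))
    p[, t] <- 2 * pnorm(-abs(z))
  }
  p[p <= 0] <- .Machine$double.xmin   # keep P in (0,1]
  colnames(p) <- paste0("p_", traits)
  cbind(snps[c("snp", "chrom", "pos")], as.data.frame(p))
}

#' Simulate a coupled synthetic bundle
#'
#' Generates the discovery GWAS, LD records, gene annotation, expression
#' matrix, gene sets, replication GWAS and truth labels described by a
#' \linkS4class{SimulationConfig}. Expression follows a factor model
#' \eqn{x_{gs} = \mu_g + \lambda_g f_{m(g),s} + \epsilon_{gs}}; factors of
#' phenotype-coupled modules are \eqn{c z_s + \sqrt{1-c^2}\,\eta_s} with
#' \eqn{z} the standardized binary phenotype. A single \code{set.seed} at
#' entry drives all sub-generators in a fixed order, so identical seed and
#' config give identical bundles.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SyntheticBundle}.
#' @export
simulateBundle <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nG <- config@n_genes

  ## --- gene annotation ------------------------------------------------
  chroms <- names(config@genome_layout)
  chrom_of <- rep(chroms, length.out = 0L)
  per <- ceiling(nG / length(chroms))
  chrom_of <- rep(chroms, each = per)[seq_len(nG)]
  len <- as.integer(round(runif(nG, config@gene_length_range[1],
                                config@gene_length_range[2])))
  start <- integer(nG)
  for (ch in chroms) {
    i <- which(chrom_of == ch)
    sp <- config@genome_layout[[ch]]
    s <- cumsum(c(sp, head(len[i], -1) + sp))
    start[i] <- as.integer(s)
  }
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(nG)),
    chrom = chrom_of, start = start, end = start + len,
    strand = sample(c("+", "-"), nG, replace = TRUE),
    stringsAsFactors = FALSE)

  ## --- truth layout ----------------------------------------------------
  perm <- sample(nG)
  module <- integer(nG)
  off <- 0L
  for (m in seq_len(config@n_modules)) {
    module[perm[off + seq_len(config@module_sizes[m])]] <- m
    off <- off + config@module_sizes[m]
  }
  true_assoc <- module > 0L
  n_extra <- config@n_true_genes - sum(true_assoc)
  if (n_extra > 0L) {
    bg <- which(!true_assoc)
    true_assoc[sample(bg, n_extra)] <- TRUE
  }

  ## planted pathway: concentrated in one module, with background spill
  pm <- which(module == config@planted_geneset_module)
  n_in <- min(16L, length(pm))
  pathway <- c(sample(pm, n_in),
               sample(which(module != config@planted_geneset_module),
                      min(14L, sum(module != config@planted_geneset_module))))
  pathway_member <- seq_len(nG) %in% pathway

  ## --- SNPs: count scales with gene length ----------------------------
  lo <- config@n_snps_per_gene[1]; hi <- config@n_snps_per_gene[2]
  frac <- (len - config@gene_length_range[1]) /
    max(1, diff(config@gene_length_range))
  n_snps <- pmin(hi, pmax(lo, lo + round((hi - lo) * frac) +
                            sample(-1:1, nG, replace = TRUE)))
  ## LD blocks span a roughly constant genomic scale, so their number per
  ## gene scales with gene length (n_ld_blocks_per_gene refers to a gene of
  ## average length); this is what makes gene length a genuine confounder
  mean_len <- mean(config@gene_length_range)
  n_blocks <- pmax(1L, pmin(n_snps, as.integer(round(
    config@n_ld_blocks_per_gene * len / mean_len))))
  snp_rows <- vector("list", nG)
  for (g in seq_len(nG)) {
    pos <- sort(sample.int(len[g], n_snps[g], replace = FALSE)) + genes$start[g]
    snp_rows[[g]] <- data.frame(
      snp = sprintf("rs%s_%d", genes$gene_id[g], seq_len(n_snps[g])),
      chrom = genes$chrom[g], pos = pos, gene = genes$gene_id[g],
      block = paste0(genes$gene_id[g], "_b",
                     if (n_blocks[g] == 1L) rep(1L, n_snps[g])
                     else cut(seq_len(n_snps[g]), breaks = n_blocks[g],
                              labels = FALSE)),
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  rownames(snps) <- NULL

  ## --- LD records: exact within-block r2, weak adjacent-block r2 ------
  ld_list <- list()
  for (b in split(snps$snp, snps$block)) {
    if (length(b) >= 2L) {
      idx <- utils::combn(length(b), 2L)
      ld_list[[length(ld_list) + 1L]] <- data.frame(
        snp_a = b[idx[1, ]], snp_b = b[idx[2, ]],
        r2 = config@within_block_r2, stringsAsFactors = FALSE)
    }
  }
  for (g in split(snps, snps$gene)) {
    blocks <- split(g$snp, g$block)
    if (length(blocks) >= 2L) {
      bn <- names(blocks)
      for (k in seq_len(length(bn) - 1L)) {
        ld_list[[length(ld_list) + 1L]] <- data.frame(
          snp_a = blocks[[bn[k]]][1], snp_b = blocks[[bn[k + 1L]]][1],
          r2 = runif(1, 0, 0.45), stringsAsFactors = FALSE)
      }
    }
  }
  ld <- do.call(rbind, ld_list)
  rownames(ld) <- NULL

  ## --- discovery + replication GWAS -----------------------------------
  gwas <- drawGwasP(snps, genes$gene_id[true_assoc],
                    discoveryTraits(config@n_traits), config@true_gene_effect,
                    config@within_block_r2, config@trait_cor)
  module_true <- which(true_assoc & module > 0L)
  n_rep <- round(config@replication_signal_share * length(module_true))
  rep_planted <- logical(nG)
  if (n_rep > 0L)
    rep_planted[sample(module_true, n_rep)] <- TRUE
  replication <- drawGwasP(snps, genes$gene_id[rep_planted],
                           replicationTraits(config@n_replication_traits),
                           config@true_gene_effect, config@within_block_r2,
                           config@trait_cor)

  ## --- expression ------------------------------------------------------
  nS <- config@n_samples
  phen <- rep(c(0L, 1L), c(floor(nS / 2), ceiling(nS / 2)))
  z <- as.numeric(scale(phen))
  factors <- matrix(rnorm(config@n_modules * nS), nrow = config@n_modules)
  for (m in seq_len(config@n_modules)) {
    cc <- unname(config@phenotype_coupling[as.character(m)])
    if (length(cc) && !is.na(cc) && cc != 0) {
      ## noise component orthogonalized against the phenotype in-sample, so
      ## the realized factor-phenotype correlation is the configured c
      eta <- rnorm(nS)
      eta <- as.numeric(scale(eta - z * sum(eta * z) / sum(z * z)))
      factors[m, ] <- cc * z + sqrt(1 - cc^2) * eta
    }
  }
  factors <- factors * config@module_factor_sd
  ## expressed-in-tissue baselines: planted-module genes are abundantly
  ## expressed, other disease (true) genes moderately so, background genes
  ## form the low mode the array-median filter removes
  baseline <- ifelse(module > 0L, rnorm(nG, 9, 1),
                     ifelse(true_assoc, rnorm(nG, 8.5, 1), rnorm(nG, 7, 1.5)))
  ## wide loading range gives modules a realistic membership gradient
  ## (per-module mean MM lands near the 0.6-0.75 seen on real arrays)
  lambda <- runif(nG, 0.4, 1.3)
  expr <- matrix(0, nG, nS,
                 dimnames = list(genes$gene_id, sprintf("S%02d", seq_len(nS))))
  for (g in seq_len(nG)) {
    sig <- if (module[g] > 0L) lambda[g] * factors[module[g], ] +
      rnorm(nS, 0, config@noise_sd)
    else rnorm(nS, 0, config@module_factor_sd)
    expr[g, ] <- baseline[g] + sig
  }
  expression <- ExpressionDataset(expr, setNames(phen, colnames(expr)))

  ## --- gene sets -------------------------------------------------------
  genesets <- list(planted_pathway = genes$gene_id[pathway])
  for (k in 1:3)
    genesets[[paste0("decoy", k)]] <- sample(genes$gene_id, 30L)

  truth <- data.frame(
    gene_id = genes$gene_id, true_associated = true_assoc, module = module,
    pathway_member = pathway_member, replication_planted = rep_planted,
    stringsAsFactors = FALSE)

  new("SyntheticBundle", gwas = gwas, ld = ld, genes = genes,
      expression = expression, genesets = genesets,
      replication_gwas = replication, truth = truth, config = config)
}

#' Write a synthetic bundle to disk
#'
#' Emits every file the pipeline's readers consume: discovery and
#' replication GWAS TSVs, PLINK-style \code{.ld} records, BED6 annotation,
#' expression and phenotype TSVs, a GMT gene-set file and a truth TSV, plus
#' a JSON manifest listing files, row counts and the seed.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param directory output directory (created if absent).
#' @return Invisibly, the manifest as a data.frame (also written as
#'   \code{manifest.json}).
#' @export
writeBundle <- function(bundle, directory) {
  stopifnot(is(bundle, "SyntheticBundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  paths <- c(gwas = "gwas.tsv", replication_gwas = "replication_gwas.tsv",
             ld = "ld.ld", genes = "genes.bed", expression = "expression.tsv",
             phenotype = "phenotype.tsv", genesets = "genesets.gmt",
             truth = "truth.tsv")
  fp <- function(x) file.path(directory, paths[[x]])
  writeGwasTable(bundle@gwas, fp("gwas"))
  writeGwasTable(bundle@replication_gwas, fp("replication_gwas"))
  writeLdTable(bundle@ld, bundle@gwas, fp("ld"))
  writeBed(bundle@genes, fp("genes"))
  writeExpression(exprsMatrix(bundle@expression), fp("expression"))
  writePhenotype(phenotype(bundle@expression), fp("phenotype"))
  writeGmt(bundle@genesets, fp("genesets"))
  write.table(bundle@truth, fp("truth"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rows <- c(nrow(bundle@gwas), nrow(bundle@replication_gwas), nrow(bundle@ld),
            nrow(bundle@genes), nrow(bundle@expression),
            ncol(bundle@expression), length(bundle@genesets),
            nrow(bundle@truth))
  manifest <- data.frame(file = unname(paths), rows = rows,
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = bundle@config@seed, files = manifest),
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a bundle directory back into memory
#'
#' Round-trips the files written by \code{\link{writeBundle}}.
#'
#' @param directory directory written by \code{writeBundle}.
#' @return A list with elements gwas, replication_gwas, ld, genes,
#'   expression (an \linkS4class{ExpressionDataset}), genesets and truth.
#' @export
readBundle <- function(directory) {
  list(
    gwas = readGwasTable(file.path(directory, "gwas.tsv")),
    replication_gwas = readGwasTable(file.path(directory, "replication_gwas.tsv")),
    ld = readLdTable(file.path(directory, "ld.ld")),
    genes = readBed(file.path(directory, "genes.bed")),
    expression = readExpressionDataset(file.path(directory, "expression.tsv"),
                                       file.path(directory, "phenotype.tsv")),
    genesets = readGmt(file.path(directory, "genesets.gmt")),
    truth = read.delim(file.path(directory, "truth.tsv"),
                       stringsAsFactors = FALSE))
}
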