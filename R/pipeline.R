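## End-to-end orchestration: simulate (or accept) inputs, convert SNPs to
## gene scores, select the NSGG, prepare expression, build the network,
## compute metrics, test gene-set enrichment per module, and measure
## replication rates in the second GWAS.

#' Run the full systems-level GWAS analysis
#'
#' Executes the stages in pipeline order: SNP-to-gene conversion of the
#' discovery GWAS, NSGG selection, expression filtering and outlier
#' removal, probe-per-gene reduction, network construction and module
#' detection, eigengenes and per-gene statistics, per-module gene-set
#' enrichment against the expression universe, SNP-to-gene conversion of
#' the replication GWAS, and replication-rate comparison for hub- versus
#' P-value-based gene selection. An empty NSGG stops the run cleanly after
#' the GWAS stage.
#'
#' @param config a \linkS4class{SimulationConfig} used to simulate the
#'   inputs; ignored when \code{bundle} is given.
#' @param bundle a ready \linkS4class{SyntheticBundle} (or a list with the
#'   same element names, e.g. from \code{\link{readBundle}}).
#' @param r2_threshold,upstream_ext,alpha snp2gene parameters.
#' @param beta soft power (default 6, the usual unsigned-network choice at
#'   these sample sizes) or \code{"auto"} to pick the smallest power with a
#'   scale-free fit on the filtered data; the same power is reused for
#'   probe selection and the network.
#' @param min_module_size,cut_height module-detection parameters.
#' @param z_cut outlier-flagging threshold.
#' @param out_dir optional directory; when given, every stage's tables, the
#'   resolved parameters and the manifest are written there.
#' @param tom_edge_threshold TOM cutoff for the exported edge list.
#' @return list with the manifest plus the stage objects: scores, nsgg,
#'   expression (prepared), network, eigengenes, stats, cohesiveness,
#'   mm_gs, enrichment, replication_scores, replication.
#' @export
runFullPipeline <- function(config = simulationConfig(), bundle = NULL,
                            r2_threshold = 0.80, upstream_ext = 1000,
                            alpha = 0.05, beta = 6,
                            min_module_size = 30, cut_height = 0.99,
                            z_cut = 2.5, out_dir = NULL,
                            tom_edge_threshold = 0.15) {
  if (is.null(bundle)) bundle <- simulateBundle(config)
  gwas <- slotOrEl(bundle, "gwas"); ld <- slotOrEl(bundle, "ld")
  genes <- slotOrEl(bundle, "genes")
  expression <- slotOrEl(bundle, "expression")
  genesets <- slotOrEl(bundle, "genesets")
  rep_gwas <- slotOrEl(bundle, "replication_gwas")

  params <- list(r2_threshold = r2_threshold, upstream_ext = upstream_ext,
                 alpha = alpha, beta = beta,
                 min_module_size = min_module_size, cut_height = cut_height,
                 z_cut = z_cut, tom_edge_threshold = tom_edge_threshold)
  manifest <- list(params = params, counts = list())
  note <- function(...) manifest$counts <<- c(manifest$counts, list(...))

  ## --- discovery GWAS -> gene scores -> NSGG ---------------------------
  clusters <- clusterSnpsByLd(gwas, ld, r2_threshold)
  assigned <- assignClustersToGenes(clusters, genes, upstream_ext)
  scores <- genePvalues(assigned, genes)
  nsgg <- suppressWarnings(selectNsgg(scores, alpha))
  note(snps = nrow(gwas), clusters = nrow(clusters),
       genes_scored = nrow(scores), nsgg = length(nsgg))
  if (!length(nsgg)) {
    message("empty NSGG at alpha = ", alpha, "; stopping after the GWAS stage")
    manifest$stopped_at <- "nsgg"
    return(invisible(c(manifest, list(scores = scores, nsgg = nsgg))))
  }

  ## --- expression preparation -----------------------------------------
  filtered <- filterExpressed(expression, nsgg)
  outliers <- detectOutlierSamples(filtered, z_cut)
  if (length(outliers)) filtered <- removeSamples(filtered, outliers)
  if (identical(beta, "auto"))
    beta <- as.numeric(suppressWarnings(pickSoftThreshold(filtered)))
  prepared <- selectProbePerGene(filtered, beta)
  note(probes_kept = nrow(filtered), samples_flagged = length(outliers),
       network_genes = nrow(prepared), beta = beta)

  ## --- network + metrics -----------------------------------------------
  network <- buildNetwork(prepared, beta = beta,
                          min_module_size = min_module_size,
                          cut_height = cut_height)
  part <- modulePartition(network)
  eigengenes <- moduleEigengenes(prepared, part)
  stats <- computeGeneStats(network, eigengenes, prepared, scores = scores)
  cohesion <- moduleCohesiveness(stats)
  mm_gs <- mmGsCorrelation(stats)
  note(modules = sum(colnames(eigengeneMatrix(eigengenes)) != "grey"),
       grey_genes = sum(part == "grey"))

  ## --- enrichment: every set x every module, universe background -------
  background <- unique(probeGene(expression))
  enr <- list()
  for (set_name in names(genesets)) {
    for (md in setdiff(unique(part), "grey")) {
      e <- fisherEnrichment(names(part)[part == md], genesets[[set_name]],
                            background)
      e <- cbind(data.frame(set = set_name, module = md,
                            stringsAsFactors = FALSE), e)
      enr[[length(enr) + 1L]] <- e
    }
  }
  enrichment <- do.call(rbind, enr)

  ## --- replication ------------------------------------------------------
  rep_clusters <- clusterSnpsByLd(rep_gwas, ld, r2_threshold)
  rep_assigned <- assignClustersToGenes(rep_clusters, genes, upstream_ext)
  rep_scores <- genePvalues(rep_assigned, genes)
  sig_mods <- mm_gs$module[!is.na(mm_gs$significant) & mm_gs$significant]
  if (!length(sig_mods)) {
    warning("no MM-GS-significant module; using all non-grey modules for k_in")
    sig_mods <- setdiff(unique(part), "grey")
  }
  replication <- replicationRates(stats, rep_scores, modules_for_kin = sig_mods)
  note(replication_universe = sum(stats$gene_id %in% rep_scores$gene_id),
       kin_modules = length(sig_mods))

  result <- list(manifest = manifest, scores = scores, nsgg = nsgg,
                 expression = prepared, network = network,
                 eigengenes = eigengenes, stats = stats,
                 cohesiveness = cohesion, mm_gs = mm_gs,
                 enrichment = enrichment, replication_scores = rep_scores,
                 replication = replication)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeGeneScores(scores, file.path(out_dir, "gene_scores.tsv"))
    writeGeneScores(rep_scores, file.path(out_dir, "replication_scores.tsv"))
    write.table(data.frame(gene_id = names(part), module = unname(part)),
                file.path(out_dir, "partition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tom <- networkTom(network)
    idx <- which(upper.tri(tom) & tom >= tom_edge_threshold, arr.ind = TRUE)
    write.table(data.frame(gene_a = rownames(tom)[idx[, 1]],
                           gene_b = rownames(tom)[idx[, 2]],
                           tom = tom[idx]),
                file.path(out_dir, "tom_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeExpression(t(eigengeneMatrix(eigengenes)),
                    file.path(out_dir, "eigengenes.tsv"))
    writeGeneStats(stats, file.path(out_dir, "gene_stats.tsv"))
    write.table(enrichment, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(replication, file.path(out_dir, "replication_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeNewick(networkDendrogram(network),
                file.path(out_dir, "dendrogram.nwk"))
    jsonlite::write_json(replication, file.path(out_dir, "replication_rates.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

# accept both S4 bundles and plain lists with the same names
slotOrEl <- function(x, name) if (is.list(x)) x[[name]] else slot(x, name)
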