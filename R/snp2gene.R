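## LD-aware conversion of SNP-level GWAS P-values to gene-wide P-values:
## proxy clusters (connected components at r2 >= threshold), nearest-gene
## assignment with a strand-aware upstream extension, min-P gene scores
## adjusted by SNP count, and selection of the nominally significant GWAS
## gene set (NSGG).

#' Cluster GWAS SNPs into LD proxy clusters
#'
#' Proxy clusters are the connected components of the graph whose edges are
#' SNP pairs with r2 at or above the threshold; SNPs with no qualifying
#' edge become singleton clusters. Each cluster records its minimum P per
#' trait and is anchored at the position of its minimum-P SNP.
#'
#' @param gwas GWAS table (see \code{\link{readGwasTable}}).
#' @param ld LD records (snp_a, snp_b, r2). Records naming SNPs absent from
#'   the GWAS table are ignored with a message.
#' @param r2_threshold clustering threshold, in (0, 1]; default 0.80.
#' @return data.frame, one row per cluster: cluster_id, n_snps, singleton,
#'   rep_snp / rep_chrom / rep_pos (the min-P anchor) and one
#'   \code{min_p_<trait>} column per trait, plus a \code{snps} list column
#'   of member ids.
#' @export
clusterSnpsByLd <- function(gwas, ld, r2_threshold = 0.80) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0,1]")
  known <- ld$snp_a %in% gwas$snp & ld$snp_b %in% gwas$snp
  if (any(!known))
    message(sum(!known), " LD records reference SNPs absent from the GWAS; ignored")
  ld <- ld[known & ld$r2 >= r2_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ld[c("snp_a", "snp_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = gwas$snp))
  comp <- igraph::components(g)$membership[gwas$snp]
  pcols <- grep("^p_", names(gwas), value = TRUE)
  ord <- order(comp)
  idx_by_cluster <- split(seq_len(nrow(gwas))[ord], comp[ord])
  rows <- lapply(seq_along(idx_by_cluster), function(k) {
    ix <- idx_by_cluster[[k]]
    pm <- as.matrix(gwas[ix, pcols, drop = FALSE])
    best_p <- apply(pm, 1L, min)
    anchor <- ix[order(best_p, gwas$pos[ix], gwas$snp[ix])[1L]]
    out <- data.frame(cluster_id = paste0("pc", k), n_snps = length(ix),
                      singleton = length(ix) == 1L,
                      rep_snp = gwas$snp[anchor], rep_chrom = gwas$chrom[anchor],
                      rep_pos = gwas$pos[anchor], stringsAsFactors = FALSE)
    for (pc in pcols) out[[sub("^p_", "min_p_", pc)]] <- min(gwas[ix, pc])
    out$snps <- I(list(gwas$snp[ix]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# strand-aware extended interval: the upstream side gains `ext` bp
extendGenes <- function(genes, upstream_ext) {
  within(genes, {
    ext_start <- ifelse(strand == "+", pmax(0, start - upstream_ext), start)
    ext_end <- ifelse(strand == "-", end + upstream_ext, end)
  })
}

#' Assign proxy clusters to their nearest gene
#'
#' A cluster is placed at its minimum-P SNP. Gene intervals are extended by
#' \code{upstream_ext} bp on the strand-aware upstream side; a cluster
#' whose anchor falls inside an extended interval is assigned to that gene,
#' otherwise to the gene with the smallest base-pair distance on the same
#' chromosome (ties: smaller start coordinate, then lexicographic gene id).
#' Clusters on chromosomes without genes stay unassigned (NA) and are
#' reported with a message.
#'
#' @param clusters output of \code{\link{clusterSnpsByLd}}.
#' @param genes gene annotation (gene_id, chrom, start, end, strand),
#'   0-based half-open; GWAS positions are taken 1-based and converted.
#' @param upstream_ext upstream extension in bp (default 1000).
#' @return the cluster table with an \code{assigned_gene} column.
#' @export
assignClustersToGenes <- function(clusters, genes, upstream_ext = 1000) {
  ext <- extendGenes(genes, upstream_ext)
  assigned <- rep(NA_character_, nrow(clusters))
  for (ch in unique(clusters$rep_chrom)) {
    ci <- which(clusters$rep_chrom == ch)
    gi <- which(ext$chrom == ch)
    if (!length(gi)) next
    g <- ext[gi, ]
    ord <- order(g$start, g$gene_id)   # documented tie-break order
    g <- g[ord, ]
    for (i in ci) {
      p0 <- clusters$rep_pos[i] - 1L   # 1-based file position -> 0-based
      inside <- p0 >= g$ext_start & p0 < g$ext_end
      if (any(inside)) {
        assigned[i] <- g$gene_id[which(inside)[1L]]
      } else {
        d <- pmax(g$ext_start - p0, p0 - (g$ext_end - 1L), 0)
        assigned[i] <- g$gene_id[which.min(d)]   # first = smaller start
      }
    }
  }
  if (anyNA(assigned))
    message(sum(is.na(assigned)), " clusters on chromosomes without genes left unassigned")
  clusters$assigned_gene <- assigned
  clusters
}

#' Gene-wide unadjusted and adjusted P-values
#'
#' Per gene and trait, the unadjusted P is the minimum SNP P over all
#' assigned clusters and singletons; the adjusted P multiplies it by the
#' number of SNPs assigned to the gene (capped at 1). Genes with no
#' assigned SNP are omitted with a message.
#'
#' @param assigned cluster table from \code{\link{assignClustersToGenes}}.
#' @param genes gene annotation.
#' @param multiplier Bonferroni unit for the adjustment: \code{"snps"}
#'   (default) or \code{"clusters"}.
#' @return data.frame: gene_id, chrom, length_bp, n_snps, n_clusters,
#'   snp_density (SNPs per kbp), and per trait \code{unadj_p_<trait>} and
#'   \code{adj_p_<trait>}.
#' @export
genePvalues <- function(assigned, genes, multiplier = c("snps", "clusters")) {
  multiplier <- match.arg(multiplier)
  ok <- !is.na(assigned$assigned_gene)
  assigned <- assigned[ok, , drop = FALSE]
  pcols <- grep("^min_p_", names(assigned), value = TRUE)
  traits <- sub("^min_p_", "", pcols)
  by_gene <- split(assigned, assigned$assigned_gene)
  omitted <- setdiff(genes$gene_id, names(by_gene))
  if (length(omitted))
    message(length(omitted), " genes with zero assigned SNPs omitted")
  gidx <- match(names(by_gene), genes$gene_id)
  rows <- lapply(seq_along(by_gene), function(k) {
    cl <- by_gene[[k]]
    gi <- gidx[k]
    len <- genes$end[gi] - genes$start[gi]
    n_snps <- sum(cl$n_snps)
    mult <- if (multiplier == "snps") n_snps else nrow(cl)
    out <- data.frame(gene_id = names(by_gene)[k], chrom = genes$chrom[gi],
                      length_bp = len, n_snps = n_snps, n_clusters = nrow(cl),
                      snp_density = n_snps / (len / 1000),
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      u <- min(cl[[paste0("min_p_", tr)]])
      out[[paste0("unadj_p_", tr)]] <- u
      out[[paste0("adj_p_", tr)]] <- min(1, u * mult)
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Select the nominally significant GWAS gene set (NSGG)
#'
#' Genes whose adjusted gene-wide P is at or below \code{alpha} for at
#' least one trait.
#'
#' @param scores score table from \code{\link{genePvalues}}.
#' @param alpha significance cutoff (default 0.05).
#' @return sorted character vector of gene ids (possibly empty, with a
#'   warning).
#' @export
selectNsgg <- function(scores, alpha = 0.05) {
  acols <- grep("^adj_p_", names(scores), value = TRUE)
  if (!length(acols)) stop("no adjusted P columns in score table")
  hit <- apply(as.matrix(scores[acols]) <= alpha, 1L, any)
  out <- sort(scores$gene_id[hit])
  if (!length(out)) warning("empty NSGG at alpha = ", alpha)
  out
}

#' Gene length / SNP density bias diagnostics
#'
#' Pearson correlations of the unadjusted and adjusted gene-wide
#' significance (\code{-log10} P, where the min-P confounding is linear)
#' with gene length and SNP density. A strong positive correlation on the
#' unadjusted scale that vanishes after adjustment shows that the SNP-count
#' adjustment removed the confounding. By default the correlation is taken
#' over every scored gene (\code{scope = "all"}): restricting to genes
#' already passing a significance cutoff largely erases the gradient,
#' because the conditional distribution of an exponential-tailed minimum
#' above a threshold barely depends on the number of draws
#' (\code{scope = "significant"} computes that in-set variant, among genes
#' passing \code{alpha} on the respective scale).
#'
#' @param scores score table from \code{\link{genePvalues}}.
#' @param alpha qualifying cutoff for \code{scope = "significant"}
#'   (default 0.05).
#' @param trait trait to diagnose; default the first scored trait.
#' @param scope \code{"all"} (default) or \code{"significant"}.
#' @return data.frame with columns scale (unadjusted/adjusted), covariate
#'   (length/density), r, p, n and flagged (TRUE when the correlation is
#'   undefined, e.g. constant gene length).
#' @export
biasDiagnostics <- function(scores, alpha = 0.05, trait = NULL,
                            scope = c("all", "significant")) {
  scope <- match.arg(scope)
  traits <- sub("^unadj_p_", "", grep("^unadj_p_", names(scores), value = TRUE))
  if (is.null(trait)) trait <- traits[1]
  if (!trait %in% traits) stop("trait not scored: ", trait)
  one <- function(p, covariate) {
    if (length(p) < 3) stop("fewer than 3 qualifying genes: correlation undefined")
    s <- -log10(p)
    if (sd(covariate) == 0 || sd(s) == 0)
      return(c(r = NA_real_, pval = NA_real_, n = length(p), flagged = 1))
    ct <- cor.test(s, covariate)
    c(r = unname(ct$estimate), pval = ct$p.value, n = length(p), flagged = 0)
  }
  u <- if (scope == "all") scores else
    scores[scores[[paste0("unadj_p_", trait)]] <= alpha, ]
  a <- if (scope == "all") scores else
    scores[scores[[paste0("adj_p_", trait)]] <= alpha, ]
  if (nrow(u) < 10 || nrow(a) < 10)
    warning("fewer than 10 qualifying genes; diagnostics are unstable")
  res <- rbind(
    c(scale = "unadjusted", covariate = "length"),
    c(scale = "unadjusted", covariate = "density"),
    c(scale = "adjusted", covariate = "length"),
    c(scale = "adjusted", covariate = "density"))
  vals <- rbind(
    one(u[[paste0("unadj_p_", trait)]], u$length_bp),
    one(u[[paste0("unadj_p_", trait)]], u$snp_density),
    one(a[[paste0("adj_p_", trait)]], a$length_bp),
    one(a[[paste0("adj_p_", trait)]], a$snp_density))
  data.frame(res, r = vals[, "r"], p = vals[, "pval"], n = vals[, "n"],
             flagged = vals[, "flagged"] == 1, stringsAsFactors = FALSE)
}
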