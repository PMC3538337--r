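## Gene-set enrichment of modules: one-sided Fisher's exact tests,
## random-network specificity nulls, TOM-threshold submodule extraction,
## and random-gene-set permutation tests for submodule mean correlation.

#' Fisher's exact enrichment of a gene set in a module
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table
#' [in-module & in-set, in-module & out-set; out-module & in-set,
#' out-module & out-set], built disjointly (module genes removed from the
#' background margin). Because published analyses sometimes leave the
#' module inside the background when quoting the set count, the overlapping
#' construction is also computed and reported as \code{fisher_p_overlap}.
#'
#' @param module_genes gene ids of the module.
#' @param geneset gene ids of the set.
#' @param background gene-id universe (must contain the module genes).
#' @param alternative test sides for the primary P (default "greater").
#' @return one-row data.frame: counts (overlap a, module size, set size in
#'   background, background size), percentages, fold enrichment, fisher_p
#'   (disjoint table), fisher_p_two_sided and fisher_p_overlap.
#' @export
fisherEnrichment <- function(module_genes, geneset, background,
                             alternative = "greater") {
  if (!length(background) || !length(geneset)) stop("empty background or gene set")
  if (!all(module_genes %in% background))
    stop("background must contain every module gene")
  geneset <- intersect(geneset, background)
  a <- length(intersect(module_genes, geneset))
  m <- length(module_genes)
  s <- length(geneset)
  n <- length(background)
  tab <- matrix(c(a, m - a, s - a, n - m - (s - a)), 2, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts: set larger than background")
  p1 <- fisher.test(tab, alternative = alternative)$p.value
  p2 <- fisher.test(tab)$p.value
  tab_overlap <- matrix(c(a, m - a, s, n - s - (m - a)), 2, byrow = TRUE)
  p_ov <- fisher.test(tab_overlap, alternative = alternative)$p.value
  data.frame(overlap = a, module_size = m, set_size = s, background_size = n,
             pct_module = 100 * a / m, pct_background = 100 * s / n,
             fold = (a / m) / (s / n),
             fisher_p = p1, fisher_p_two_sided = p2, fisher_p_overlap = p_ov)
}

#' Enrichment counts from published margins
#'
#' Convenience entry for testing a reported enrichment when only the four
#' counts are available (overlap, module size, set size in background,
#' background size), without gene ids.
#'
#' @param overlap,module_size,set_size,background_size the 2x2 margins;
#'   \code{set_size} is the count of set genes in the full background
#'   (module included).
#' @inheritParams fisherEnrichment
#' @return as \code{\link{fisherEnrichment}}.
#' @export
fisherEnrichmentCounts <- function(overlap, module_size, set_size,
                                   background_size, alternative = "greater") {
  bg <- sprintf("bg%07d", seq_len(background_size))
  mod <- bg[seq_len(module_size)]
  set <- c(bg[seq_len(overlap)],
           bg[module_size + seq_len(set_size - overlap)])
  fisherEnrichment(mod, set, bg, alternative = alternative)
}

#' Random-network specificity of an observed enrichment
#'
#' Rebuilds \code{n_networks} networks from genes drawn at random from the
#' expression universe (same draw size, same filtering, same soft power and
#' module-detection parameters as the observed network), computes every
#' random module's Fisher enrichment P for the gene set, and reports the
#' empirical probability (with the +1 correction) that a random module is
#' at least as enriched as the observed one.
#'
#' @param universe the full \linkS4class{ExpressionDataset} (rows = genes).
#' @param geneset gene-id set tested.
#' @param observed_p the observed module's one-sided Fisher P.
#' @param n_draw genes drawn per random network (the real NSGG draw size).
#' @param n_networks number of random networks (default 100).
#' @param beta fixed soft power reused from the real network.
#' @param min_module_size,cut_height module-detection parameters.
#' @param seed RNG seed.
#' @return list: empirical_p, n_random_modules, random_p (all random module
#'   Fisher Ps).
#' @export
randomNetworkSpecificity <- function(universe, geneset, observed_p, n_draw,
                                     n_networks = 100, beta = 6,
                                     min_module_size = 30, cut_height = 0.99,
                                     seed = 1) {
  if (n_networks < 1) stop("n_networks must be >= 1")
  all_genes <- rownames(universe)
  if (n_draw > length(all_genes)) stop("n_draw exceeds the universe")
  background <- all_genes
  set.seed(seed)
  random_p <- numeric(0)
  for (b in seq_len(n_networks)) {
    drawn <- sample(all_genes, n_draw)
    filt <- tryCatch(suppressMessages(filterExpressed(universe, drawn)),
                     error = function(e) NULL)
    if (is.null(filt) || nrow(filt) < min_module_size) next
    net <- buildNetwork(filt, beta = beta, min_module_size = min_module_size,
                        cut_height = cut_height)
    part <- modulePartition(net)
    for (md in setdiff(unique(part), "grey")) {
      fp <- fisherEnrichment(names(part)[part == md], geneset, background)
      random_p <- c(random_p, fp$fisher_p)
    }
  }
  list(empirical_p = (1 + sum(random_p <= observed_p)) / (1 + length(random_p)),
       n_random_modules = length(random_p), random_p = random_p)
}

#' Extract a TOM-thresholded submodule
#'
#' With no anchor, returns all within-module edges with TOM at or above the
#' threshold and their endpoint nodes; with an anchor gene, only edges
#' incident to the anchor (an ego network). Node annotations (signed GS and
#' -log10 of the best unadjusted GWAS P) are attached when a stats table is
#' supplied, for SIF export.
#'
#' @param network a \linkS4class{CoexpressionNetwork} with a partition.
#' @param module module label to extract from.
#' @param tom_threshold minimum TOM for an edge (default 0.15).
#' @param anchor optional gene id; must belong to the module.
#' @param stats optional table from \code{\link{computeGeneStats}}.
#' @return list: \code{edges} (gene_a, gene_b, tom) and \code{nodes}
#'   (gene_id plus annotations).
#' @export
extractSubmodule <- function(network, module, tom_threshold = 0.15,
                             anchor = NULL, stats = NULL) {
  part <- modulePartition(network)
  genes <- names(part)[part == module]
  if (!is.null(anchor) && !anchor %in% genes)
    stop("anchor ", anchor, " is not in module ", module)
  tom <- networkTom(network)[genes, genes, drop = FALSE]
  idx <- which(upper.tri(tom) & tom >= tom_threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      tom = tom[idx], stringsAsFactors = FALSE)
  if (!is.null(anchor))
    edges <- edges[edges$gene_a == anchor | edges$gene_b == anchor, , drop = FALSE]
  nodes <- data.frame(gene_id = sort(unique(c(edges$gene_a, edges$gene_b))),
                      stringsAsFactors = FALSE)
  if (!is.null(stats) && nrow(nodes)) {
    ix <- match(nodes$gene_id, stats$gene_id)
    nodes$module <- stats$module[ix]
    nodes$gs_signed <- stats$gs_signed[ix]
    ucols <- grep("^unadj_p_", names(stats), value = TRUE)
    if (length(ucols)) {
      best <- do.call(pmin, stats[ix, ucols, drop = FALSE])
      nodes$neglog10_gwas_p <- -log10(best)
    }
  }
  list(edges = edges, nodes = nodes)
}

#' Permutation test for a submodule's mean phenotype correlation
#'
#' Observed statistic: the mean signed GS over the subset. The null draws
#' \code{n_perm} subsets of the same size without replacement from the
#' module and reports the empirical P (with the +1 correction) for the
#' requested tail (default the negative tail: draws with mean at or below
#' the observed).
#'
#' @param module_gs_signed named numeric vector, signed GS for every module
#'   gene.
#' @param subset gene ids of the submodule (>= 2, all in the module).
#' @param n_perm random subsets (default 1e6).
#' @param tail \code{"less"} (default) or \code{"greater"}.
#' @param seed RNG seed.
#' @return list: observed_mean, empirical_p, n_perm, most_extreme (the most
#'   extreme random mean in the tested tail).
#' @export
submoduleMeanCorrelationTest <- function(module_gs_signed, subset,
                                         n_perm = 1e6,
                                         tail = c("less", "greater"),
                                         seed = 1) {
  tail <- match.arg(tail)
  if (length(subset) < 2) stop("subset must contain at least 2 genes")
  if (!all(subset %in% names(module_gs_signed)))
    stop("subset contains genes outside the module")
  if (length(subset) > length(module_gs_signed))
    stop("subset larger than the module")
  observed <- mean(module_gs_signed[subset])
  v <- unname(module_gs_signed)
  k <- length(subset)
  set.seed(seed)
  means <- vapply(seq_len(n_perm),
                  function(i) mean(v[sample.int(length(v), k)]), 0)
  hits <- if (tail == "less") sum(means <= observed) else sum(means >= observed)
  list(observed_mean = observed,
       empirical_p = (1 + hits) / (1 + n_perm),
       n_perm = n_perm,
       most_extreme = if (tail == "less") min(means) else max(means))
}
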