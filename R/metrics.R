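## Per-gene and per-module network statistics: module membership (MM),
## gene significance (GS), intramodular and total connectivity, module
## cohesiveness, half-split robustness and the MM-GS correlation.

sem <- function(x) sd(x) / sqrt(length(x))

#' Per-gene network statistics
#'
#' MM is the Pearson correlation between a gene's expression and its
#' module's eigengene (NA for grey genes); signed GS is the correlation
#' with the binary phenotype and GS its absolute value; k_total and k_in
#' are the gene's adjacency sums over all network genes and over its own
#' module. GWAS gene scores, when supplied, are joined by gene id.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param eigengenes matching \linkS4class{ModuleEigengenes}.
#' @param data the \linkS4class{ExpressionDataset} the network was built on.
#' @param scores optional GWAS score table (\code{\link{genePvalues}});
#'   its P columns are joined onto the output.
#' @return data.frame: gene_id, module, mm, gs, gs_signed, k_in, k_total,
#'   k_in_rank (1 = most intramodularly connected, per module) and any
#'   joined GWAS columns.
#' @export
computeGeneStats <- function(network, eigengenes, data, scores = NULL) {
  m <- exprsMatrix(data)[network@gene_ids, , drop = FALSE]
  phen <- phenotype(data)
  if (sd(phen) == 0) stop("phenotype is constant: GS undefined")
  part <- network@partition[network@gene_ids]
  eg <- eigengeneMatrix(eigengenes)
  a <- network@adjacency
  k_total <- rowSums(a)
  k_in <- vapply(seq_along(network@gene_ids), function(i) {
    same <- part == part[i]
    same[i] <- FALSE
    sum(a[i, same])
  }, 0)
  gs_signed <- as.numeric(cor(t(m), phen))
  mm <- rep(NA_real_, length(part))
  for (md in setdiff(unique(part), "grey")) {
    rows <- which(part == md)
    mm[rows] <- as.numeric(cor(t(m[rows, , drop = FALSE]), eg[, md]))
  }
  stats <- data.frame(gene_id = network@gene_ids, module = unname(part),
                      mm = mm, gs = abs(gs_signed), gs_signed = gs_signed,
                      k_in = k_in, k_total = k_total,
                      stringsAsFactors = FALSE)
  stats$k_in_rank <- NA_integer_
  for (md in unique(part)) {
    rows <- which(stats$module == md)
    stats$k_in_rank[rows] <- rank(-stats$k_in[rows], ties.method = "first")
  }
  if (!is.null(scores))
    stats <- merge(stats, scores, by = "gene_id", all.x = TRUE, sort = FALSE)
  stats[order(match(stats$gene_id, network@gene_ids)), , drop = FALSE]
}

#' Module cohesiveness: mean MM with its standard error
#'
#' @param stats table from \code{\link{computeGeneStats}}.
#' @return data.frame: module, n, mean_mm, sem_mm (non-grey modules only).
#' @export
moduleCohesiveness <- function(stats) {
  s <- stats[stats$module != "grey", ]
  out <- do.call(rbind, lapply(split(s, s$module), function(x)
    data.frame(module = x$module[1], n = nrow(x), mean_mm = mean(x$mm),
               sem_mm = sem(x$mm), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(-out$n), ]
}

#' Half-split robustness of intramodular connectivity
#'
#' Splits the samples at random into halves \code{n_splits} times (an odd
#' sample goes to half 1), recomputes the module-restricted adjacency and
#' k_in in each half, and reports the mean and SEM of the Pearson
#' correlation between the two half-derived k_in vectors. With
#' \code{mode = "real_vs_half"} each half's k_in is instead correlated with
#' the full-data k_in and both correlations enter the average.
#'
#' @param data the \linkS4class{ExpressionDataset} (rows = genes, >= 8
#'   samples).
#' @param partition named module labels.
#' @param module module label to assess (>= 3 genes).
#' @param beta soft-threshold power for the per-half adjacency.
#' @param n_splits number of random splits (default 1000).
#' @param mode \code{"between_halves"} (default) or \code{"real_vs_half"}.
#' @param seed RNG seed.
#' @return list: mean, sem, correlations (length n_splits, or 2*n_splits
#'   for real_vs_half).
#' @export
halfSplitRobustness <- function(data, partition, module, beta = 6,
                                n_splits = 1000, mode = c("between_halves", "real_vs_half"),
                                seed = 1) {
  mode <- match.arg(mode)
  genes <- names(partition)[partition == module]
  if (length(genes) < 3) stop("module ", module, " has fewer than 3 genes")
  m <- exprsMatrix(data)[genes, , drop = FALSE]
  nS <- ncol(m)
  if (nS < 8) stop("need at least 8 samples")
  kin <- function(cols) {
    a <- abs(cor(t(m[, cols, drop = FALSE])))^beta
    diag(a) <- 0
    rowSums(a)
  }
  set.seed(seed)
  k_full <- if (mode == "real_vs_half") kin(seq_len(nS)) else NULL
  cors <- numeric(0)
  for (s in seq_len(n_splits)) {
    h1 <- sample(nS, ceiling(nS / 2))
    h2 <- setdiff(seq_len(nS), h1)
    k1 <- kin(h1); k2 <- kin(h2)
    cors <- c(cors, if (mode == "between_halves") cor(k1, k2)
              else c(cor(k_full, k1), cor(k_full, k2)))
  }
  list(mean = mean(cors), sem = sem(cors), correlations = cors)
}

#' Per-module correlation between MM and GS
#'
#' Pearson correlation of module membership against gene significance
#' within each non-grey module, with a Bonferroni significance threshold
#' of 0.05 divided by the number of modules tested.
#'
#' @param stats table from \code{\link{computeGeneStats}}.
#' @param n_modules_for_bonferroni Bonferroni denominator; defaults to the
#'   number of non-grey modules in \code{stats}.
#' @param min_size smallest module tested (default 5).
#' @return data.frame: module, n, r, p, significant, flagged (TRUE when the
#'   correlation is undefined, e.g. constant GS).
#' @export
mmGsCorrelation <- function(stats, n_modules_for_bonferroni = NULL,
                            min_size = 5) {
  s <- stats[stats$module != "grey", ]
  mods <- unique(s$module)
  if (is.null(n_modules_for_bonferroni))
    n_modules_for_bonferroni <- length(mods)
  thr <- 0.05 / n_modules_for_bonferroni
  rows <- lapply(mods, function(md) {
    x <- s[s$module == md, ]
    if (nrow(x) < min_size)
      return(data.frame(module = md, n = nrow(x), r = NA_real_, p = NA_real_,
                        significant = NA, flagged = TRUE))
    if (sd(x$gs) == 0 || sd(x$mm) == 0)
      return(data.frame(module = md, n = nrow(x), r = NA_real_, p = NA_real_,
                        significant = NA, flagged = TRUE))
    ct <- cor.test(x$mm, x$gs)
    data.frame(module = md, n = nrow(x), r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < thr, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  out
}
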