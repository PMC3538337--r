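## Weighted coexpression network core: soft-threshold selection,
## unsigned adjacency, topological overlap, average-linkage module
## detection with a static branch cut, and SVD module eigengenes.

# WGCNA-style color labels, assigned by descending module size
moduleColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes the connectivity distribution of the
#' unsigned network and the R-squared of the log-log regression of
#' frequency on mean connectivity over 10 bins. Returns the smallest power
#' whose fit reaches \code{target_r2} with a negative slope; if none
#' qualifies, the fallback power is returned with a warning.
#'
#' @param data an \linkS4class{ExpressionDataset} with >= 20 genes.
#' @param candidates powers to try (default 1..20).
#' @param target_r2 required scale-free fit (default 0.8).
#' @param fallback power used when no candidate qualifies (default 6).
#' @return the selected power, with attributes \code{fit} (per-candidate
#'   R-squared and slope) and \code{fallback_used}.
#' @export
pickSoftThreshold <- function(data, candidates = 1:20, target_r2 = 0.8,
                              fallback = 6) {
  m <- exprsMatrix(data)
  if (nrow(m) < 20L) stop("need at least 20 genes to assess scale-free fit")
  ac <- abs(cor(t(m)))
  diag(ac) <- 0
  fit <- data.frame(beta = candidates, r2 = NA_real_, slope = NA_real_)
  for (i in seq_along(candidates)) {
    k <- rowSums(ac^candidates[i])
    if (max(k) - min(k) < .Machine$double.eps^0.5) next
    bin <- cut(k, breaks = 10, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- tapply(k, bin, length) / length(k)
    ok <- is.finite(dk) & dk > 0 & pk > 0
    if (sum(ok) < 3) next
    f <- lm(log10(pk[ok]) ~ log10(dk[ok]))
    fit$slope[i] <- coef(f)[2]
    fit$r2[i] <- summary(f)$r.squared
  }
  qual <- which(!is.na(fit$r2) & fit$r2 >= target_r2 & fit$slope < 0)
  if (length(qual)) {
    beta <- candidates[qual[1]]
    fallback_used <- FALSE
  } else {
    warning("no candidate power reached scale-free fit R2 >= ", target_r2,
            "; using fallback power ", fallback)
    beta <- fallback
    fallback_used <- TRUE
  }
  structure(beta, fit = fit, fallback_used = fallback_used)
}

#' Unsigned soft-thresholded adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with a zero diagonal (self-adjacency
#' is excluded from all connectivity sums).
#'
#' @param data an \linkS4class{ExpressionDataset} with >= 2 samples.
#' @param beta soft-threshold power.
#' @return symmetric matrix in [0,1] with gene ids as dimnames.
#' @export
adjacencyMatrix <- function(data, beta) {
  m <- exprsMatrix(data)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  v <- apply(m, 1L, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(m)[v == 0], 5L), collapse = ", "))
  a <- abs(cor(t(m)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with unit diagonal: two genes overlap
#' strongly when they connect to the same neighbours.
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @return symmetric TOM in [0,1], unit diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules on the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}, a static
#' branch cut at \code{cut_height}, and merging of clusters smaller than
#' \code{min_module_size} into \code{"grey"}. Surviving modules are
#' labelled with color names by descending size (turquoise, blue, brown,
#' ...), so labels are reproducible across runs.
#'
#' @param tom topological overlap matrix.
#' @param min_module_size smallest retained module (default 30; must be
#'   >= 3).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @return list with \code{partition} (named character, gene -> label) and
#'   \code{dendrogram} (the hclust tree).
#' @export
detectModules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    pal <- c(moduleColors, paste0("module", seq_len(max(0, length(keep) - length(moduleColors)))))
    for (i in seq_along(keep))
      labels[cl == as.integer(keep[i])] <- pal[i]
  }
  names(labels) <- rownames(as.matrix(tom))
  list(partition = labels, dendrogram = hc)
}

#' Build a CoexpressionNetwork
#'
#' Convenience constructor running \code{\link{adjacencyMatrix}},
#' \code{\link{topologicalOverlap}} and \code{\link{detectModules}},
#' followed by an eigengene-membership cleanup: genes whose absolute
#' correlation with their module's eigengene (kME) falls below
#' \code{mm_min} are moved to grey. The cleanup is the usual guard against
#' weakly attached genes that a static branch cut sweeps into large
#' modules; set \code{mm_min = 0} to disable it.
#'
#' @param data an \linkS4class{ExpressionDataset} (rows = genes).
#' @param beta soft-threshold power, or \code{"auto"} to call
#'   \code{\link{pickSoftThreshold}}.
#' @param min_module_size,cut_height passed to \code{\link{detectModules}}.
#' @param mm_min minimum absolute module membership retained (default 0.5).
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(data, beta = "auto", min_module_size = 30,
                         cut_height = 0.99, mm_min = 0.5) {
  if (identical(beta, "auto")) beta <- as.numeric(pickSoftThreshold(data))
  a <- adjacencyMatrix(data, beta)
  tom <- topologicalOverlap(a)
  det <- detectModules(tom, min_module_size, cut_height)
  part <- det$partition
  if (mm_min > 0 && any(part != "grey")) {
    eg <- eigengeneMatrix(suppressWarnings(moduleEigengenes(data, part)))
    m <- exprsMatrix(data)
    for (md in setdiff(unique(part), "grey")) {
      rows <- names(part)[part == md]
      kme <- as.numeric(cor(t(m[rows, , drop = FALSE]), eg[, md]))
      part[rows[abs(kme) < mm_min]] <- "grey"
    }
  }
  new("CoexpressionNetwork", gene_ids = rownames(a), adjacency = a,
      tom = tom, beta = as.numeric(beta), partition = part,
      dendrogram = det$dendrogram)
}

#' Module eigengenes by singular value decomposition
#'
#' Each module's eigengene is the first right singular vector of its
#' row-standardized expression submatrix, sign-oriented so its correlation
#' with the module's mean standardized expression is non-negative. A
#' single-gene module falls back to the standardized gene itself, with a
#' warning.
#'
#' @param data an \linkS4class{ExpressionDataset} (rows = genes).
#' @param partition named character vector gene -> module label; grey is
#'   skipped.
#' @return a \linkS4class{ModuleEigengenes}.
#' @export
moduleEigengenes <- function(data, partition) {
  m <- exprsMatrix(data)
  mods <- setdiff(sort(unique(partition)), "grey")
  eg <- matrix(NA_real_, ncol(m), length(mods),
               dimnames = list(colnames(m), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (md in mods) {
    rows <- names(partition)[partition == md]
    x <- m[rows, , drop = FALSE]
    xs <- t(scale(t(x)))   # standardize each gene across samples
    if (nrow(xs) == 1L) {
      warning("module ", md, " has a single gene; eigengene = standardized gene")
      v <- as.numeric(xs)
      v <- v / sqrt(sum(v^2))
      eg[, md] <- v
      ve[md] <- 1
      next
    }
    sv <- svd(xs)
    v <- sv$v[, 1]
    orient <- suppressWarnings(cor(v, colMeans(xs)))
    if (!is.na(orient) && orient < 0) v <- -v
    eg[, md] <- v
    ve[md] <- sv$d[1]^2 / sum(sv$d^2)
  }
  new("ModuleEigengenes", eigengenes = eg, varianceExplained = ve)
}
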