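# Small in-code fixtures shared across the suite.

# expression dataset with planted modules: one factor per module, optional
# phenotype coupling on the first module
plantedExpression <- function(module_sizes = c(12, 10), n_noise = 8,
                              n_samples = 24, coupling = 0, noise_sd = 0.4,
                              seed = 1) {
  set.seed(seed)
  phen <- rep(c(0L, 1L), length.out = n_samples)
  z <- as.numeric(scale(phen))
  n_genes <- sum(module_sizes) + n_noise
  module <- rep(c(seq_along(module_sizes), 0L),
                c(module_sizes, n_noise))
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  for (m in seq_along(module_sizes)) {
    f <- if (m == 1 && coupling != 0)
      coupling * z + sqrt(1 - coupling^2) * rnorm(n_samples)
    else rnorm(n_samples)
    rows <- which(module == m)
    x[rows, ] <- runif(length(rows), 0.8, 1.2) %o% f +
      matrix(rnorm(length(rows) * n_samples, 0, noise_sd),
             length(rows), n_samples)
  }
  rownames(x) <- sprintf("g%03d", seq_len(n_genes))
  colnames(x) <- sprintf("S%02d", seq_len(n_samples))
  ed <- ExpressionDataset(x + 8, setNames(phen, colnames(x)))
  attr(ed, "truth_module") <- setNames(module, rownames(x))
  ed
}

# toy GWAS table with explicit P-values (single trait unless p2 given)
toyGwas <- function(snp, chrom, pos, p, p2 = NULL) {
  out <- data.frame(snp = snp, chrom = as.character(chrom), pos = pos,
                    p_a = p, stringsAsFactors = FALSE)
  if (!is.null(p2)) out$p_b <- p2
  out
}

toyGenes <- function(gene_id, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene_id, chrom = as.character(chrom), start = start,
             end = end, strand = strand, stringsAsFactors = FALSE)
}

# independent union-find oracle for LD clustering
unionFindClusters <- function(snps, ld, r2_threshold = 0.8) {
  parent <- setNames(seq_along(snps), snps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- ld$r2 >= r2_threshold & ld$snp_a %in% snps & ld$snp_b %in% snps
  for (k in which(keep)) {
    ra <- find(match(ld$snp_a[k], snps)); rb <- find(match(ld$snp_b[k], snps))
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_along(snps), find, 0L)
}

# brute-force TOM oracle (triple loop)
tomOracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# exact one-sided Fisher P by hypergeometric enumeration
fisherOracle <- function(a, m, s, n) {
  # P(X >= a) where X ~ Hypergeom(white = s, black = n - s, drawn = m)
  sum(vapply(a:min(m, s), function(x) stats::dhyper(x, s, n - s, m), 0))
}
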