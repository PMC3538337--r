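test_that("proxy clusters are the transitive closure of high-LD pairs", {
  gwas <- toyGwas(paste0("s", 1:3), "1", c(100L, 200L, 300L), c(0.5, 0.1, 0.9))
  ld <- data.frame(snp_a = c("s1", "s2", "s1"), snp_b = c("s2", "s3", "s3"),
                   r2 = c(0.9, 0.85, 0.5))
  cl <- clusterSnpsByLd(gwas, ld)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$snps[[1]], c("s1", "s2", "s3"))
  expect_false(cl$singleton)
  expect_equal(cl$min_p_a, 0.1)
  expect_equal(cl$rep_snp, "s2")   # anchored at the minimum-P SNP
})

test_that("SNPs with no qualifying edge become singletons", {
  gwas <- toyGwas(paste0("s", 1:4), "1", (1:4) * 100L, c(0.5, 0.1, 0.9, 0.3))
  ld <- data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.6)
  cl <- clusterSnpsByLd(gwas, ld)
  expect_equal(nrow(cl), 4L)
  expect_true(all(cl$singleton))
})

test_that("clustering matches an independent union-find oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50L
    snps <- paste0("s", seq_len(n))
    gwas <- toyGwas(snps, "1", seq_len(n) * 10L, runif(n))
    pairs <- t(utils::combn(n, 2L))
    pick <- sample(nrow(pairs), 120L)
    ld <- data.frame(snp_a = snps[pairs[pick, 1]],
                     snp_b = snps[pairs[pick, 2]], r2 = runif(120))
    cl <- clusterSnpsByLd(gwas, ld)
    # partition property
    members <- unlist(cl$snps)
    expect_setequal(members, snps)
    expect_equal(sum(cl$n_snps), n)
    # same components as the oracle
    oracle <- unionFindClusters(snps, ld)
    got <- integer(n)
    for (k in seq_len(nrow(cl))) got[match(cl$snps[[k]], snps)] <- k
    tab <- table(oracle, got)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("LD records for unknown SNPs are ignored with a message", {
  gwas <- toyGwas(c("s1", "s2"), "1", c(100L, 200L), c(0.5, 0.1))
  ld <- data.frame(snp_a = c("s1", "sX"), snp_b = c("s2", "s2"),
                   r2 = c(0.9, 0.95))
  expect_message(cl <- clusterSnpsByLd(gwas, ld), "ignored")
  expect_equal(nrow(cl), 1L)
  expect_error(clusterSnpsByLd(gwas, ld, r2_threshold = 0), "r2_threshold")
})

test_that("clusters go to the containing gene, the 1-kbp upstream extension, or the nearest gene", {
  genes <- toyGenes(c("GIN", "GUP", "GFAR"), "1",
                    c(5000L, 10000L, 40000L), c(9000L, 12000L, 41000L),
                    c("+", "+", "+"))
  gwas <- toyGwas(c("in", "up", "far"), "1", c(5501L, 9401L, 20000L),
                  c(0.01, 0.01, 0.01))
  cl <- assignClustersToGenes(clusterSnpsByLd(gwas, data.frame(
    snp_a = character(), snp_b = character(), r2 = numeric())), genes)
  got <- setNames(cl$assigned_gene, cl$rep_snp)
  expect_equal(got[["in"]], "GIN")
  expect_equal(got[["up"]], "GUP")   # within [9000, 10000): upstream of GUP
  expect_equal(got[["far"]], "GUP")  # nearest interval end
})

test_that("upstream extension is strand-aware and ties break on start coordinate", {
  genes <- toyGenes(c("GMINUS", "GB"), "1", c(10000L, 30001L),
                    c(12000L, 32001L), c("-", "+"))
  gwas <- toyGwas(c("dn", "mid"), "1", c(12500L, 21001L), c(0.01, 0.01))
  cl <- assignClustersToGenes(clusterSnpsByLd(gwas, data.frame(
    snp_a = character(), snp_b = character(), r2 = numeric())), genes)
  got <- setNames(cl$assigned_gene, cl$rep_snp)
  expect_equal(got[["dn"]], "GMINUS")   # minus strand extends [12000, 13000)
  # 21000 (0-based) is 8001 bp from GMINUS's extended interval and 8001 bp
  # from GB's extended start -> equidistant, smaller start coordinate wins
  expect_equal(got[["mid"]], "GMINUS")
})

test_that("clusters on chromosomes without genes stay unassigned", {
  genes <- toyGenes("GA", "1", 100L, 500L)
  gwas <- toyGwas("lost", "2", 100L, 0.01)
  expect_message(
    cl <- assignClustersToGenes(clusterSnpsByLd(gwas, data.frame(
      snp_a = character(), snp_b = character(), r2 = numeric())), genes),
    "unassigned")
  expect_true(is.na(cl$assigned_gene))
})

test_that("gene-wide P-values follow the min-P / SNP-count adjustment rule", {
  genes <- toyGenes("GA", "1", 1000L, 3000L)
  # one 3-SNP cluster (min P 0.01) plus one singleton (P 0.2)
  gwas <- toyGwas(paste0("s", 1:4), "1", c(1100L, 1200L, 1300L, 2500L),
                  c(0.05, 0.01, 0.3, 0.2))
  ld <- data.frame(snp_a = c("s1", "s2"), snp_b = c("s2", "s3"),
                   r2 = c(0.9, 0.9))
  scores <- genePvalues(assignClustersToGenes(clusterSnpsByLd(gwas, ld), genes),
                        genes)
  expect_equal(scores$unadj_p_a, 0.01)
  expect_equal(scores$adj_p_a, 0.04)      # 0.01 x 4 SNPs
  expect_equal(scores$n_snps, 4L)
  expect_equal(scores$n_clusters, 2L)
  expect_equal(scores$length_bp, 2000L)
  expect_equal(scores$snp_density, 2)

  # cluster multiplier option
  s2 <- genePvalues(assignClustersToGenes(clusterSnpsByLd(gwas, ld), genes),
                    genes, multiplier = "clusters")
  expect_equal(s2$adj_p_a, 0.02)          # 0.01 x 2 clusters
})

test_that("single-SNP genes and the P cap behave as documented", {
  genes <- toyGenes(c("G1", "G2"), "1", c(1000L, 9000L), c(2000L, 10000L))
  gwas <- toyGwas(paste0("s", 1:11), "1",
                  c(1500L, 9000L + seq(50L, 950L, by = 100L)),
                  c(0.03, rep(0.2, 10)))
  empty_ld <- data.frame(snp_a = character(), snp_b = character(),
                         r2 = numeric())
  scores <- genePvalues(assignClustersToGenes(clusterSnpsByLd(gwas, empty_ld),
                                              genes), genes)
  g1 <- scores[scores$gene_id == "G1", ]
  expect_equal(g1$unadj_p_a, 0.03)
  expect_equal(g1$adj_p_a, 0.03)          # single SNP: no penalty
  g2 <- scores[scores$gene_id == "G2", ]
  expect_equal(g2$adj_p_a, 1)             # 0.2 x 10 capped at 1
  # invariant: adjusted >= unadjusted
  expect_true(all(scores$adj_p_a >= scores$unadj_p_a))
})

test_that("NSGG selection is the sorted any-trait union", {
  scores <- data.frame(
    gene_id = c("G5", "G1", "G2", "G3", "G4"),
    adj_p_a = c(0.04, 0.06, 0.01, 0.9, 0.050),
    adj_p_b = c(0.90, 0.051, 0.2, 0.04, 0.9))
  expect_equal(selectNsgg(scores), c("G2", "G3", "G4", "G5"))
  expect_warning(out <- selectNsgg(scores, alpha = 1e-12), "empty NSGG")
  expect_equal(out, character())
})

test_that("bias diagnostics flag degenerate inputs and collapse when P-values coincide", {
  scores <- data.frame(
    gene_id = paste0("G", 1:20), chrom = "1",
    length_bp = rep(1000L, 20), n_snps = 1L, n_clusters = 1L,
    snp_density = 1, unadj_p_a = runif(20), stringsAsFactors = FALSE)
  scores$adj_p_a <- scores$unadj_p_a
  d <- suppressWarnings(biasDiagnostics(scores, alpha = 1))
  expect_true(all(d$flagged[d$covariate == "length"]))   # constant length
  # identical unadjusted/adjusted P: identical correlations
  scores$length_bp <- sample(1000:5000, 20)
  d2 <- suppressWarnings(biasDiagnostics(scores, alpha = 1))
  expect_equal(d2$r[d2$scale == "unadjusted"], d2$r[d2$scale == "adjusted"])
  expect_error(suppressWarnings(biasDiagnostics(scores[1:2, ], alpha = 1)),
               "fewer than 3")
})
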