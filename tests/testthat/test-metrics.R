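# small handmade network: expression, adjacency and partition under full
# control
toyNetwork <- function(seed = 21) {
  set.seed(seed)
  f1 <- rnorm(16); f2 <- rnorm(16)
  m <- rbind(
    a1 = f1 + rnorm(16, 0, 0.2), a2 = f1 + rnorm(16, 0, 0.2),
    a3 = f1 + rnorm(16, 0, 0.2), a4 = f1 + rnorm(16, 0, 0.2),
    b1 = f2 + rnorm(16, 0, 0.2), b2 = f2 + rnorm(16, 0, 0.2),
    b3 = f2 + rnorm(16, 0, 0.2), b4 = f2 + rnorm(16, 0, 0.2))
  colnames(m) <- paste0("S", 1:16)
  ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 8), colnames(m)))
  net <- buildNetwork(ed, beta = 6, min_module_size = 3, mm_min = 0)
  list(ed = ed, net = net,
       me = moduleEigengenes(ed, modulePartition(net)))
}

test_that("connectivities match hand-summed adjacency rows", {
  tn <- toyNetwork()
  stats <- computeGeneStats(tn$net, tn$me, tn$ed)
  a <- networkAdjacency(tn$net)
  part <- modulePartition(tn$net)
  for (i in seq_len(nrow(a))) {
    g <- rownames(a)[i]
    expect_equal(stats$k_total[stats$gene_id == g], sum(a[i, -i]),
                 tolerance = 1e-12)
    same <- which(part == part[g] & rownames(a) != g)
    expect_equal(stats$k_in[stats$gene_id == g], sum(a[i, same]),
                 tolerance = 1e-12)
  }
  expect_true(all(stats$k_in <= stats$k_total + 1e-12))
  expect_equal(stats$gs, abs(stats$gs_signed))
  # ranks are a permutation within each module
  for (md in unique(stats$module))
    expect_setequal(stats$k_in_rank[stats$module == md],
                    seq_len(sum(stats$module == md)))
})

test_that("MM and GS hit their exact anchors", {
  tn <- toyNetwork()
  part <- modulePartition(tn$net)
  eg <- eigengeneMatrix(tn$me)
  # a gene whose profile is its module eigengene has MM = 1
  m <- exprsMatrix(tn$ed)
  md <- part[[1]]
  m <- rbind(m, ME = eg[, md])
  ed2 <- ExpressionDataset(m, phenotype(tn$ed))
  net2 <- tn$net
  net2@gene_ids <- rownames(m)
  net2@adjacency <- adjacencyMatrix(ed2, 6)
  net2@partition <- setNames(c(part, md), rownames(m))
  stats <- computeGeneStats(net2, tn$me, ed2)
  expect_equal(stats$mm[stats$gene_id == "ME"], 1, tolerance = 1e-8)
  # a gene equal to the phenotype has GS = 1
  m3 <- rbind(exprsMatrix(tn$ed), PH = phenotype(tn$ed))
  ed3 <- ExpressionDataset(m3, phenotype(tn$ed))
  gs <- abs(as.numeric(cor(t(exprsMatrix(ed3)), phenotype(ed3))))
  expect_equal(gs[rownames(m3) == "PH"], 1)
  # constant phenotype: GS undefined
  edc <- ExpressionDataset(exprsMatrix(tn$ed),
                           setNames(rep(1L, 16), colnames(tn$ed)))
  expect_error(computeGeneStats(tn$net, tn$me, edc), "constant")
})

test_that("module cohesiveness summarizes MM correctly", {
  stats <- data.frame(gene_id = paste0("g", 1:7),
                      module = c("blue", "blue", "red", "red", "red", "grey",
                                 "grey"),
                      mm = c(0.6, 0.8, 1, 1, 1, 0.1, 0.2))
  coh <- moduleCohesiveness(stats)
  blue <- coh[coh$module == "blue", ]
  expect_equal(blue$mean_mm, 0.7)
  expect_equal(blue$sem_mm, 0.1)
  red <- coh[coh$module == "red", ]
  expect_equal(red$mean_mm, 1)
  expect_equal(red$sem_mm, 0)
  expect_false("grey" %in% coh$module)
})

test_that("strongly planted modules are more cohesive than weak ones", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    f1 <- rnorm(20); f2 <- rnorm(20)
    strong <- t(sapply(1:10, function(i) f1 + rnorm(20, 0, 0.2)))
    weak <- t(sapply(1:10, function(i) f2 + rnorm(20, 0, 1.2)))
    m <- rbind(strong, weak)
    dimnames(m) <- list(paste0("g", 1:20), paste0("S", 1:20))
    ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 10), colnames(m)))
    part <- setNames(rep(c("strong", "weak"), each = 10), rownames(m))
    me <- moduleEigengenes(ed, part)
    net <- new("CoexpressionNetwork", gene_ids = rownames(m),
               adjacency = adjacencyMatrix(ed, 6),
               tom = matrix(0, 0, 0), beta = 6, partition = part,
               dendrogram = NULL)
    coh <- moduleCohesiveness(computeGeneStats(net, me, ed))
    wins <- wins + (coh$mean_mm[coh$module == "strong"] >
                      coh$mean_mm[coh$module == "weak"])
  }
  expect_equal(wins, 10L)
})

test_that("half-split robustness separates reproducible from noise modules", {
  set.seed(31)
  prof <- rnorm(36)
  # hub-to-periphery gradient: per-gene noise grows, so the k_in ordering
  # is a stable property a reproducible module shows in any half
  sds <- seq(0.05, 1.5, length.out = 12)
  tight <- t(sapply(1:12, function(i) prof + rnorm(36, 0, sds[i])))
  dimnames(tight) <- list(paste0("g", 1:12), paste0("S", 1:36))
  ed <- ExpressionDataset(tight, setNames(rep(c(0L, 1L), 18),
                                          colnames(tight)))
  part <- setNames(rep("m", 12), rownames(tight))
  hs <- halfSplitRobustness(ed, part, "m", beta = 6, n_splits = 50, seed = 1)
  expect_gte(hs$mean, 0.9)

  set.seed(31)
  noise <- matrix(rnorm(30 * 36), 30, 36,
                  dimnames = list(paste0("n", 1:30), colnames(tight)))
  edn <- ExpressionDataset(noise, phenotype(ed))
  hn <- halfSplitRobustness(edn, setNames(rep("m", 30), rownames(noise)),
                            "m", beta = 6, n_splits = 200, seed = 1)
  expect_lt(abs(hn$mean), 0.1)

  # single-split determinism
  one1 <- halfSplitRobustness(ed, part, "m", n_splits = 1, seed = 99)
  one2 <- halfSplitRobustness(ed, part, "m", n_splits = 1, seed = 99)
  expect_identical(one1$correlations, one2$correlations)
  expect_error(halfSplitRobustness(ed, setNames(rep("m", 2), paste0("g", 1:2)),
                                   "m", n_splits = 1), "fewer than 3")
  # the real-vs-half variant reports two correlations per split
  rv <- halfSplitRobustness(ed, part, "m", n_splits = 5, seed = 1,
                            mode = "real_vs_half")
  expect_length(rv$correlations, 10L)
})

test_that("MM-GS correlation flags exact and degenerate cases", {
  stats <- data.frame(gene_id = paste0("g", 1:12),
                      module = rep(c("a", "b"), each = 6),
                      mm = c(1:6 / 10, 1:6 / 10),
                      gs = c(1:6 / 10, rep(0.3, 6)))
  res <- mmGsCorrelation(stats, n_modules_for_bonferroni = 2)
  expect_equal(res$r[res$module == "a"], 1)
  expect_true(res$significant[res$module == "a"])
  expect_true(res$flagged[res$module == "b"])   # constant GS
  small <- mmGsCorrelation(stats[stats$module == "a", ][1:4, ])
  expect_true(small$flagged[1])                 # below min size
})

test_that("the phenotype-coupled module has the strongest MM-GS correlation", {
  hits <- 0L
  for (s in 1:10) {
    ed <- plantedExpression(module_sizes = c(30, 30), n_noise = 0,
                            n_samples = 24, coupling = 0.7, seed = 2000 + s)
    truth <- attr(ed, "truth_module")
    part <- setNames(paste0("m", truth), names(truth))
    me <- moduleEigengenes(ed, part)
    net <- new("CoexpressionNetwork", gene_ids = rownames(ed),
               adjacency = adjacencyMatrix(ed, 6), tom = matrix(0, 0, 0),
               beta = 6, partition = part, dendrogram = NULL)
    res <- mmGsCorrelation(computeGeneStats(net, me, ed))
    hits <- hits + identical(res$module[which.max(res$r)], "m1")
  }
  expect_gte(hits, 9L)
})
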