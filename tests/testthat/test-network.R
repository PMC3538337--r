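test_that("adjacency matches a brute-force per-pair oracle", {
  set.seed(3)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("S", 1:6)))
  ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 3), colnames(m)))
  a <- adjacencyMatrix(ed, beta = 6)
  for (i in 1:10) for (j in 1:10) {
    want <- if (i == j) 0 else abs(cor(m[i, ], m[j, ]))^6
    expect_equal(a[i, j], want, tolerance = 1e-12)
  }
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, t(a))
})

test_that("perfectly correlated genes reach adjacency one; zero variance is an error", {
  m <- rbind(g1 = 1:6, g2 = (1:6) * 2 + 3, g3 = rep(5, 6))
  colnames(m) <- paste0("S", 1:6)
  ed <- ExpressionDataset(m[1:2, ], setNames(rep(c(0L, 1L), 3), colnames(m)))
  a <- adjacencyMatrix(ed, beta = 7)
  expect_equal(a["g1", "g2"], 1)
  edz <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 3), colnames(m)))
  expect_error(adjacencyMatrix(edz, beta = 6), "g3")
})

test_that("TOM equals the triple-loop oracle and honors its exact cases", {
  # clique: all off-diagonal adjacency 1 -> all TOM 1
  a1 <- matrix(1, 3, 3) - diag(3)
  expect_true(all(topologicalOverlap(a1) == 1))
  # disjoint neighborhoods and a_ij = 0 -> TOM 0
  a2 <- matrix(0, 4, 4)
  a2[1, 2] <- a2[2, 1] <- 1   # gene 1 only connects to 2
  a2[3, 4] <- a2[4, 3] <- 1   # gene 3 only connects to 4
  expect_equal(topologicalOverlap(a2)[1, 3], 0)
  # random instance
  set.seed(9)
  r <- matrix(runif(36), 6, 6)
  a <- (r + t(r)) / 2
  diag(a) <- 0
  tom <- topologicalOverlap(a)
  expect_equal(tom, tomOracle(a), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_identical(tom, t(tom))
})

test_that("soft-threshold selection is consistent with its own fit table", {
  ed <- plantedExpression(module_sizes = c(15, 12, 10), n_noise = 80,
                          n_samples = 24, seed = 2)
  beta <- suppressWarnings(pickSoftThreshold(ed))
  fit <- attr(beta, "fit")
  expect_true(as.numeric(beta) %in% fit$beta)
  qual <- fit$beta[!is.na(fit$r2) & fit$r2 >= 0.8 & fit$slope < 0]
  if (length(qual)) {
    expect_equal(as.numeric(beta), min(qual))
    expect_false(attr(beta, "fallback_used"))
  } else {
    expect_true(attr(beta, "fallback_used"))
  }
  # no candidate on a bounded grid fits pure noise: fallback with warning
  set.seed(4)
  noise <- matrix(rnorm(150 * 24), 150, 24,
                  dimnames = list(paste0("g", 1:150), paste0("S", 1:24)))
  edn <- ExpressionDataset(noise, setNames(rep(c(0L, 1L), 12),
                                           colnames(noise)))
  expect_warning(b2 <- pickSoftThreshold(edn, candidates = 1:6), "fallback")
  expect_equal(as.numeric(b2), 6)
  # threshold limit: with target 0 the first negatively sloped fit wins,
  # which for this decaying-connectivity fixture is the first candidate
  expect_equal(as.numeric(pickSoftThreshold(ed, target_r2 = 0)), 1)
  expect_error(pickSoftThreshold(ed[1:5, ]), "at least 20 genes")
})

test_that("module detection recovers planted blocks exactly and labels by size", {
  ed <- plantedExpression(module_sizes = c(50, 40, 35), n_noise = 0,
                          n_samples = 30, noise_sd = 0.3, seed = 6)
  truth <- attr(ed, "truth_module")
  a <- adjacencyMatrix(ed, 6)
  det <- detectModules(topologicalOverlap(a), min_module_size = 10)
  part <- det$partition
  # exactly three modules, labelled turquoise/blue/brown by descending size
  expect_setequal(unique(part), c("turquoise", "blue", "brown"))
  expect_equal(unname(table(part)[c("turquoise", "blue", "brown")]),
               c(50L, 40L, 35L), ignore_attr = TRUE)
  # one-to-one against truth
  tab <- table(part, truth[names(part)])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_s3_class(det$dendrogram, "hclust")
})

test_that("pure noise is predominantly grey and tiny inputs all grey", {
  grey_frac <- numeric(10)
  for (s in 1:10) {
    set.seed(900 + s)
    m <- matrix(rnorm(100 * 24), 100, 24,
                dimnames = list(sprintf("g%03d", 1:100), paste0("S", 1:24)))
    ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 12), colnames(m)))
    det <- detectModules(topologicalOverlap(adjacencyMatrix(ed, 6)),
                         min_module_size = 30)
    grey_frac[s] <- mean(det$partition == "grey")
  }
  expect_true(all(grey_frac >= 0.8))

  ed <- plantedExpression(module_sizes = c(10, 8), n_noise = 5, seed = 3)
  det <- detectModules(topologicalOverlap(adjacencyMatrix(ed, 6)),
                       min_module_size = 1000)
  expect_true(all(det$partition == "grey"))
  expect_error(detectModules(diag(3), min_module_size = 2), ">= 3")
})

test_that("gene order does not change the network, only its indexing", {
  ed <- plantedExpression(module_sizes = c(15, 12), n_noise = 6, seed = 8)
  net1 <- buildNetwork(ed, beta = 6, min_module_size = 5)
  perm <- sample(nrow(ed))
  m <- exprsMatrix(ed)
  ed2 <- ExpressionDataset(m[perm, ], phenotype(ed))
  net2 <- buildNetwork(ed2, beta = 6, min_module_size = 5)
  g <- rownames(m)
  expect_equal(networkAdjacency(net2)[g, g], networkAdjacency(net1)[g, g])
  expect_equal(networkTom(net2)[g, g], networkTom(net1)[g, g])
  expect_equal(modulePartition(net2)[g], modulePartition(net1)[g])
})

test_that("module eigengenes match the covariance-eigenvector oracle", {
  set.seed(12)
  m <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("S", 1:20)))
  ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 10), colnames(m)))
  part <- setNames(rep("blue", 8), rownames(m))
  me <- moduleEigengenes(ed, part)
  v <- eigengeneMatrix(me)[, "blue"]
  xs <- t(scale(t(m)))
  ev <- eigen(crossprod(xs))$vectors[, 1]
  expect_equal(abs(as.numeric(v)), abs(ev), tolerance = 1e-10)
  expect_equal(sum(v^2), 1)
  ve <- varianceExplained(me)[["blue"]]
  expect_equal(ve, eigen(crossprod(xs))$values[1] / sum(diag(crossprod(xs))),
               tolerance = 1e-10)
})

test_that("eigengene of identical rows is the standardized profile with full variance", {
  prof <- rnorm(12)
  m <- matrix(rep(prof, each = 5), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("S", 1:12)))
  ed <- ExpressionDataset(m, setNames(rep(c(0L, 1L), 6), colnames(m)))
  me <- moduleEigengenes(ed, setNames(rep("m", 5), rownames(m)))
  v <- eigengeneMatrix(me)[, "m"]
  zs <- as.numeric(scale(prof)); zs <- zs / sqrt(sum(zs^2))
  expect_equal(abs(as.numeric(v)), abs(zs), tolerance = 1e-10)
  expect_equal(varianceExplained(me)[["m"]], 1)
  # orientation: cor with the module mean profile is non-negative either way
  expect_gte(cor(v, colMeans(t(scale(t(m))))), 0)
  me2 <- moduleEigengenes(ExpressionDataset(-m, phenotype(ed)),
                          setNames(rep("m", 5), rownames(m)))
  expect_gte(cor(eigengeneMatrix(me2)[, "m"],
                 colMeans(t(scale(t(-m))))), 0)
})
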