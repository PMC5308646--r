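# Signed network construction, TOM, module detection, kME/hubs,
# module-trait correlation, DE stand-in, interaction filter

test_that("stage-specific DE flags stepped genes and not flat ones", {
  fx <- simFixture(1)
  de <- suppressWarnings(stageSpecificGenes(fx$se))
  truth <- fx$truth@geneArchetype
  planted <- names(truth)[truth == "stage_specific"]
  flat <- setdiff(names(truth)[truth == "flat"],
                  c(fx$truth@plantedPairs$gene_a, fx$truth@plantedPairs$gene_b))
  expect_gte(mean(planted %in% de$specific), 0.95)
  expect_lte(mean(flat %in% de$specific), 0.05)
  # closed-form fold change: a 10 -> 100 FPKM step gives log2(101/11)
  m <- matrix(c(rep(10, 3), rep(100, 3)), 1,
              dimnames = list("g1", paste0("c", 1:6)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = m),
    colData = S4Vectors::DataFrame(stage = factor(rep(c("a", "b"), each = 3),
                                                  levels = c("a", "b"))))
  de2 <- stageSpecificGenes(se, method = "welch")
  expect_equal(de2$results$log2_fc, log2(101 / 11))
  expect_equal(de2$results$q_value, 0)   # zero-variance distinct means
  expect_equal(de2$specific, "g1")
})

test_that("two-node TOM equals the adjacency and perfect correlation saturates it", {
  # two genes: TOM_12 = a (L = 0, k = a)
  m2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1.1, 2.2, 2.9, 4.3))
  expect_error(buildNetwork(m2, beta = 5), "at least 3 genes")
  m2 <- rbind(m2, g3 = c(4, 3, 2, 1))
  net <- buildNetwork(m2, beta = 5)
  a <- adjacencyMatrix(net)
  expect_equal(tomMatrix(net), oracleTOM(a), tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-identical genes: adjacency and TOM are all ones
  mId <- matrix(rep(c(1, 5, 2, 8), each = 4), 4, byrow = FALSE)
  mId <- rbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8) * 2, c = c(1, 5, 2, 8) + 3)
  netId <- buildNetwork(mId, beta = 5)
  expect_equal(unname(adjacencyMatrix(netId)), matrix(1, 3, 3))
  expect_equal(unname(tomMatrix(netId)), matrix(1, 3, 3))
  # constant gene rows are named in the error
  mBad <- rbind(ok = c(1, 2, 3), ok2 = c(3, 1, 2), flatg = c(5, 5, 5))
  expect_error(buildNetwork(mBad, beta = 5), "flatg")
})

test_that("TOM matches the brute-force triple loop on random networks", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:20, 1)
    m <- matrix(stats::rnorm(n * 12), n, 12,
                dimnames = list(paste0("g", seq_len(n)), NULL))
    net <- buildNetwork(m, beta = sample(3:7, 1))
    a <- adjacencyMatrix(net)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(a, t(a))
    expect_equal(a, ((1 + net@cor) / 2)^softPower(net) + diag(n) * 0,
                 tolerance = 1e-12, ignore_attr = TRUE)
    tom <- tomMatrix(net)
    expect_equal(tom, oracleTOM(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(diag(tom), rep(1, n), ignore_attr = TRUE)
  }
})

test_that("soft threshold honours overrides, targets and power-law fixtures", {
  fx <- simFixture(1)
  m <- log10(SummarizedExperiment::assay(fx$se, "fpkm") + 1)[1:80, ]
  cm <- stats::cor(t(m))
  expect_equal(pickSoftThreshold(cm, beta = 5)$beta, 5)
  expect_equal(pickSoftThreshold(cm, r2Target = 0)$beta, 1)
  res <- suppressWarnings(pickSoftThreshold(cm))
  expect_true(res$beta %in% 1:20)
  # exact power-law degree sequence fits with R^2 near 1
  set.seed(2)
  k <- round(300 / (1:60)^1.5) + 1
  r2 <- embryoLnc:::.scaleFreeR2(k)
  expect_gt(r2, 0.9)
})

test_that("module detection recovers planted blocks and merges near-duplicates", {
  # two perfectly correlated blocks, cross-correlation ~0
  set.seed(31)
  base1 <- stats::rnorm(20); base2 <- stats::rnorm(20)
  m <- rbind(
    t(sapply(1:8, function(i) i * base1 + i)),
    t(sapply(1:8, function(i) -2 * i * base2 + i)))
  rownames(m) <- paste0("g", 1:16)
  net <- buildNetwork(m, beta = 5)
  ms <- detectModules(net, m, minModuleSize = 5)
  asg <- moduleAssignment(ms)
  expect_equal(length(moduleLabels(ms)), 2L)
  expect_equal(length(unique(asg[1:8])), 1L)
  expect_equal(length(unique(asg[9:16])), 1L)
  expect_false(asg[1] == asg[9])
  # labels come from the color vocabulary by size
  expect_true(all(moduleLabels(ms) %in% c("turquoise", "blue")))
  # near-identical blocks merge under the eigengene rule
  m2 <- rbind(m[1:8, ],
              t(sapply(1:8, function(i) i * base1 + stats::rnorm(20, 0, 0.05))))
  rownames(m2) <- paste0("h", 1:16)
  net2 <- buildNetwork(m2, beta = 5)
  ms2 <- detectModules(net2, m2, minModuleSize = 5, mergeCor = 0.85)
  expect_equal(length(moduleLabels(ms2)), 1L)
})

test_that("planted three-module structure is recovered with high ARI across seeds", {
  aris <- vapply(1:5, function(s) {
    fx <- simFixture(s)
    m <- log10(SummarizedExperiment::assay(fx$se, "fpkm") + 1)
    tr <- fx$truth
    modGenes <- unlist(tr@plantedModules)
    pairGenes <- c(tr@plantedPairs$gene_a, tr@plantedPairs$gene_b)
    flat <- setdiff(names(tr@geneArchetype)[tr@geneArchetype == "flat"],
                    pairGenes)
    sub <- m[c(modGenes, flat[seq_len(30)]), ]
    net <- buildNetwork(sub, beta = 5)
    ms <- detectModules(net, sub, minModuleSize = 15)
    truthLab <- rep(c(names(tr@plantedModules), "none"),
                    c(lengths(tr@plantedModules), 30))
    ari(moduleAssignment(ms)[rownames(sub)], truthLab)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("eigengenes are unit variance, sign-fixed, and drive kME and hubs", {
  set.seed(41)
  traj <- stats::rnorm(30)
  m <- rbind(t(sapply(1:10, function(i) i * traj + stats::rnorm(30, 0, 0.1))),
             t(sapply(1:10, function(i) stats::rnorm(30))))
  rownames(m) <- paste0("g", 1:20)
  net <- buildNetwork(m, beta = 5)
  ms <- detectModules(net, m, minModuleSize = 5)
  me <- moduleEigengenes(ms)
  expect_equal(apply(me, 2, stats::var), rep(1, ncol(me)),
               ignore_attr = TRUE)
  mod <- moduleAssignment(ms)["g1"]
  # sign convention: own-module genes correlate positively on average
  own <- names(moduleAssignment(ms))[moduleAssignment(ms) == mod]
  expect_gt(mean(stats::cor(t(m[own, ]), me[, mod])), 0)
  ms <- kmeAndHubs(m, ms)
  kme <- moduleKME(ms)
  # kME equals a direct correlation computation
  expect_equal(kme["g1", mod], stats::cor(m["g1", ], me[, mod]))
  # a gene proportional to its eigengene has kME 1 and is a hub
  m2 <- rbind(m, proportional = 2 * me[, mod] + 5,
              anti = -me[, mod])
  net2 <- buildNetwork(m2, beta = 5)
  ms2 <- detectModules(net2, m2, minModuleSize = 5)
  ms2 <- kmeAndHubs(m2, ms2, hubKme = 0.9)
  mod2 <- moduleAssignment(ms2)["proportional"]
  expect_gte(moduleKME(ms2)["proportional", mod2], 0.9)
  expect_true("proportional" %in% moduleHubs(ms2)[[mod2]])
  expect_false("anti" %in% unlist(moduleHubs(ms2)))
})

test_that("flipping an eigengene flips kME and the sign convention restores it", {
  set.seed(5)
  traj <- stats::rnorm(25)
  m <- t(sapply(1:8, function(i) i + i * traj + stats::rnorm(25, 0, 0.05)))
  rownames(m) <- paste0("g", 1:8)
  me <- embryoLnc:::.eigengene(m)
  kme <- stats::cor(t(m), me)
  expect_true(all(kme > 0))
  expect_equal(stats::cor(t(m), -me), -kme)
})

test_that("module-trait correlation matches the textbook t reference", {
  set.seed(6)
  x <- stats::rnorm(6)
  traits <- cbind(t1 = x, t2 = stats::rnorm(6), const = rep(1, 6))
  ms <- new("ModuleSet",
            assignment = c(g1 = "blue"),
            eigengenes = matrix((x - mean(x)) / stats::sd(x), 6, 1,
                                dimnames = list(NULL, "blue")),
            kme = matrix(numeric(), 0, 0), traitCor = list(), hubs = list())
  expect_message(ms <- moduleTrait(ms, traits), "const")
  r <- ms@traitCor$r
  expect_equal(unname(r[, "t1"]), 1.0)
  r2 <- unname(r["blue", "t2"])
  tref <- r2 * sqrt((6 - 2) / (1 - r2^2))
  expect_equal(unname(ms@traitCor$p["blue", "t2"]),
               2 * stats::pt(-abs(tref), 4))
  expect_true(ms@traitCor$flag["blue", "t1"])
  expect_false(ms@traitCor$flag["blue", "t2"])
})

test_that("hub edges respect the weight cutoff and drop isolated hubs", {
  set.seed(7)
  m <- matrix(stats::rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), NULL))
  net <- buildNetwork(m, beta = 5)
  tom <- tomMatrix(net)
  hubs <- paste0("g", 1:4)
  # cutoff 0 keeps the complete graph on the hubs
  expect_equal(nrow(hubEdges(net, hubs, weightCutoff = 0)), choose(4, 2))
  # cutoff above the maximum leaves nothing
  expect_equal(nrow(hubEdges(net, hubs, weightCutoff = 1.01)), 0L)
  # mid cutoff matches a hand count
  mx <- max(tom[hubs, hubs][upper.tri(tom[hubs, hubs])])
  e <- hubEdges(net, hubs, weightCutoff = mx)
  expect_equal(nrow(e), sum(tom[hubs, hubs][upper.tri(tom[hubs, hubs])] >= mx))
})

test_that("interaction filtering keeps ndG at or below the cutoff", {
  tab <- data.frame(lnc_id = paste0("l", 1:10), gene_id = paste0("g", 1:10),
                    ndG = c(-0.5, -0.1, -0.05, 0, -0.2, 0.3, -0.11,
                            -0.09, -1, 0.01))
  kept <- filterInteractions(tab)
  expect_equal(nrow(kept), sum(tab$ndG <= -0.1))       # hand tally: 5
  expect_true("l2" %in% kept$lnc_id)                   # boundary inclusive
  expect_false("l3" %in% kept$lnc_id)
  tabBad <- tab; tabBad$ndG <- as.character(tabBad$ndG)
  tabBad$ndG[4] <- "oops"
  expect_error(filterInteractions(tabBad), "row 4")
})
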