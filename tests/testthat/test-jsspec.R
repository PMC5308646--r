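# Jensen-Shannon temporal specificity score and class comparisons

test_that("stage pooling averages cells within stages", {
  fx <- simFixture(1)
  V <- poolStages(fx$se)
  stage <- SummarizedExperiment::colData(fx$se)$stage
  m <- SummarizedExperiment::assay(fx$se, "fpkm")
  g <- rownames(m)[5]
  s <- levels(stage)[3]
  expect_equal(V[g, s], mean(m[g, stage == s]))
  # permuting cell columns leaves the pooled profile unchanged
  perm <- sample(ncol(fx$se))
  V2 <- poolStages(fx$se[, perm])
  expect_equal(V2, V)
  # two-cell toy: mean of 2 and 4 is 3
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = matrix(c(2, 4), 1, 2,
                                dimnames = list("g1", c("c1", "c2")))),
    colData = S4Vectors::DataFrame(stage = factor(c("s1", "s1"))))
  expect_equal(unname(poolStages(se2)[1, 1]), 3)
})

test_that("density normalization follows the log10(FPKM+1) rule", {
  expect_equal(normalizeDensity(c(9, 99)), c(1 / 3, 2 / 3))
  expect_equal(normalizeDensity(rep(7, 5)), rep(0.2, 5))
  expect_true(all(is.na(normalizeDensity(c(0, 0, 0)))))
  m <- rbind(a = c(9, 99), b = c(0, 0))
  dm <- normalizeDensity(m)
  expect_equal(unname(dm["a", ]), c(1 / 3, 2 / 3))
  expect_true(all(is.na(dm["b", ])))
  expect_error(normalizeDensity(c(-1, 2)), ">= 0")
})

test_that("entropy and JS distance reproduce analytic values", {
  expect_equal(shannonEntropy(c(0.5, 0.5)), 1.0)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0.0)
  expect_equal(shannonEntropy(c(0.25, 0.75)), 0.25 * 2 + 0.75 * log2(4 / 3))
  expect_equal(jsDistance(c(0.2, 0.8), c(0.2, 0.8)), 0.0)
  expect_equal(jsDistance(c(1, 0), c(0, 1)), 1.0)
  # uniform over 7 vs point mass, high-precision direct evaluation
  u <- rep(1 / 7, 7); e1 <- c(1, rep(0, 6))
  mHalf <- (u + e1) / 2
  dExp <- sqrt(oracleEntropy(mHalf) - (oracleEntropy(u) + 0) / 2)
  expect_equal(jsDistance(u, e1), dExp, tolerance = 1e-12)
  expect_equal(jsDistance(u, e1), 0.83029, tolerance = 1e-4)
  expect_error(jsDistance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("specificity score has the right extremes, symmetry and tie-break", {
  pr <- rbind(point3 = c(0, 0, 1, 0, 0, 0, 0),
              unif = rep(1 / 7, 7),
              half12 = c(0.5, 0.5, 0, 0, 0, 0, 0))
  colnames(pr) <- paste0("st", 1:7)
  sc <- specificityScore(pr)
  expect_equal(sc$max_score[sc$gene_id == "point3"], 1.0)
  expect_equal(sc$argmax_stage[sc$gene_id == "point3"], "st3")
  expect_equal(sc$max_score[sc$gene_id == "unif"], 0.16971, tolerance = 1e-4)
  # two-way tie resolves to the earliest stage
  expect_equal(sc$argmax_stage[sc$gene_id == "half12"], "st1")
  h <- as.numeric(sc[sc$gene_id == "half12", paste0("js_st", 1:2)])
  expect_equal(h[1], h[2])
  expect_true(all(sc[, paste0("js_st", 1:7)] >= 0 &
                  sc[, paste0("js_st", 1:7)] <= 1))
})

test_that("specificity score matches the independent direct implementation", {
  set.seed(11)
  for (rep in 1:1000) {
    n <- sample(2:8, 1)
    V <- stats::rexp(n, 0.1) * stats::rbinom(n, 1, 0.9)
    if (all(V == 0)) V[1] <- 5
    orc <- oracleSpecificity(V)
    pr <- matrix(normalizeDensity(V), 1, dimnames = list("g", NULL))
    got <- specificityScore(pr)
    expect_equal(got$max_score, orc$max, tolerance = 1e-12)
    expect_equal(unname(as.numeric(got[1, 1 + seq_len(n)])), orc$scores,
                 tolerance = 1e-12)
    expect_equal(got$argmax_stage, paste0("s", orc$argmax))
  }
})

test_that("stage permutation permutes per-stage scores and preserves the max", {
  set.seed(12)
  for (rep in 1:20) {
    V <- stats::rexp(7, 0.1)
    pr <- matrix(normalizeDensity(V), 1, dimnames = list("g", NULL))
    sc <- specificityScore(pr)
    perm <- sample(7)
    prP <- pr[, perm, drop = FALSE]
    scP <- specificityScore(prP)
    expect_equal(as.numeric(scP[1, 1 + 1:7]),
                 as.numeric(sc[1, 1 + 1:7])[perm])
    expect_equal(scP$max_score, sc$max_score)
  }
})

test_that("diluting a point mass with uniform baseline lowers the score", {
  scores <- vapply(seq(0, 0.9, by = 0.1), function(eps) {
    p <- (1 - eps) * c(1, rep(0, 6)) + eps / 7
    specificityScore(matrix(p, 1, dimnames = list("g", NULL)))$max_score
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("class comparison fractions and Fisher p match planted truth and enumeration", {
  # Fisher p equals the exhaustive hypergeometric tail enumeration
  l <- c(rep(0.9, 5), rep(0.1, 5))   # 5 specific of 10
  c_ <- c(rep(0.9, 1), rep(0.1, 9))  # 1 specific of 10
  res <- compareSpecificity(l, c_, cutoff = 0.5)
  expect_equal(res$frac_specific_lnc, 0.5)
  expect_equal(res$frac_specific_coding, 0.1)
  expect_equal(res$fisher_p, oracleFisher2x2(rbind(c(5, 5), c(1, 9))),
               tolerance = 1e-12)
  # identical score multisets: KS p = 1, equal fractions
  same <- compareSpecificity(l, l)
  expect_equal(same$ks_p, 1)
  expect_equal(same$frac_specific_lnc, same$frac_specific_coding)
  # planted recovery: fractions recovered within binomial error
  fx <- simFixture(4)
  sc <- specificityScore(normalizeDensity(poolStages(fx$se)))
  bt <- fx$ann$genes$biotype
  names(bt) <- fx$ann$genes$gene_id
  isSpec <- fx$truth@geneArchetype == "stage_specific"
  for (cls in c("lncRNA", "coding")) {
    ids <- names(bt)[bt == cls]
    planted <- mean(isSpec[ids])
    got <- mean(sc$max_score[match(ids, sc$gene_id)] > 0.5, na.rm = TRUE)
    se3 <- 3 * sqrt(planted * (1 - planted) / length(ids)) + 0.02
    expect_lt(abs(got - planted), se3 + 0.05)
  }
})

test_that("sample-pair Spearman behaves on duplicates and swapped classes", {
  fx <- simFixture(1)
  m <- SummarizedExperiment::assay(fx$se, "fpkm")[1:40, 1:6]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = cbind(m, m[, 1, drop = FALSE])),
    colData = S4Vectors::DataFrame(stage = factor(rep("s", 7))))
  isLnc <- rep(c(TRUE, FALSE), 20)
  res <- samplePairSpearman(se, isLnc)
  # the duplicated column pair has rho exactly 1 in both classes
  expect_true(any(abs(res$rho_lnc - 1) < 1e-12))
  expect_true(any(abs(res$rho_coding - 1) < 1e-12))
  # U statistics of swapped masks are complementary: U1 + U2 = n1 * n2
  res2 <- samplePairSpearman(se, !isLnc)
  expect_equal(res$mw_statistic + res2$mw_statistic,
               length(res$rho_lnc) * length(res$rho_coding))
  # planted stage-specific genes decorrelate cross-stage sample pairs
  # relative to flat genes
  arch <- fx$truth@geneArchetype
  keep <- arch %in% c("stage_specific", "flat")
  seSub <- fx$se[keep, ]
  full <- samplePairSpearman(seSub, arch[keep] == "stage_specific")
  expect_lt(stats::median(full$rho_lnc), stats::median(full$rho_coding))
  expect_lt(full$mw_p, 0.01)
})

test_that("maximal expression is log10-scaled and lncRNAs sit lower", {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = rbind(g1 = c(1, 99), g2 = c(0, 0))),
    colData = S4Vectors::DataFrame(stage = factor(c("a", "b"))))
  res <- maxExpressionDistribution(se, c(TRUE, FALSE))
  expect_equal(unname(res$max_lnc), 2.0)   # log10(99 + 1)
  expect_equal(unname(res$max_coding), 0.0)
  # planted lncExpressionScale pushes the lncRNA distribution down
  fx <- simFixture(2)
  full <- maxExpressionDistribution(fx$se, fx$ann$genes$biotype == "lncRNA")
  expect_lt(stats::median(full$max_lnc), stats::median(full$max_coding))
  expect_lt(full$ks_p, 0.01)
})
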