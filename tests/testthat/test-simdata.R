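# Synthetic-data generator: planted structure, determinism, closure

test_that("configuration invariants are enforced", {
  expect_error(simConfig(cellsPerStage = c(3, 3)), "align")
  expect_error(simConfig(fracLnc = 1.5), "fracLnc")
  expect_error(simConfig(neighborGapBp = 10000), "10000")
  expect_error(simConfig(nGenes = 10), "planted structure")
  expect_s4_class(simConfig(), "SimConfig")
})

test_that("annotation plants pairs with exact gaps and correct orientation geometry", {
  cfg <- simConfig(seed = 11, nNeighborPairsDivergent = 2L,
                   nNeighborPairsUnidirectional = 3L)
  ann <- simulateAnnotation(cfg)
  g <- ann$genes
  truth <- ann$truth
  expect_equal(length(g), cfg@nGenes)
  expect_true(all(lengths(ann$exons) >= 1))
  # biotype fractions near the requested value
  expect_equal(mean(g$biotype == "lncRNA"), cfg@fracLnc, tolerance = 0.05)
  # divergent pairs are head-to-head: left gene minus, right gene plus
  for (i in which(truth@plantedPairs$orientation == "divergent")) {
    a <- g[truth@plantedPairs$gene_a[i]]
    b <- g[truth@plantedPairs$gene_b[i]]
    left <- if (GenomicRanges::start(a) < GenomicRanges::start(b)) a else b
    right <- if (GenomicRanges::start(a) < GenomicRanges::start(b)) b else a
    expect_equal(as.character(GenomicRanges::strand(left)), "-")
    expect_equal(as.character(GenomicRanges::strand(right)), "+")
    expect_equal(GenomicRanges::start(right) - GenomicRanges::end(left),
                 cfg@neighborGapBp)
  }
  # unidirectional pairs share a strand
  for (i in which(truth@plantedPairs$orientation == "unidirectional")) {
    a <- g[truth@plantedPairs$gene_a[i]]
    b <- g[truth@plantedPairs$gene_b[i]]
    expect_equal(as.character(GenomicRanges::strand(a)),
                 as.character(GenomicRanges::strand(b)))
  }
  # neighbor finder recovers exactly the planted pairs
  nb <- findNeighbors(g)
  expect_equal(nrow(nb), 5L)
})

test_that("planted-truth closure holds and gene count scales exactly", {
  fx <- simFixture(1)
  truth <- fx$truth
  ids <- fx$ann$genes$gene_id
  expect_setequal(names(truth@geneArchetype), ids)
  expect_true(all(unlist(truth@plantedModules) %in% ids))
  expect_true(all(c(truth@plantedPairs$gene_a, truth@plantedPairs$gene_b)
                  %in% ids))
  expect_false(anyDuplicated(unlist(truth@plantedModules)) > 0)
  expect_true(all(names(truth@specificStage) %in% ids))
  # doubling nGenes doubles the record count exactly
  n1 <- length(simulateAnnotation(simConfig(nGenes = 300L, seed = 2))$genes)
  n2 <- length(simulateAnnotation(simConfig(nGenes = 600L, seed = 2))$genes)
  expect_equal(n2, 2L * n1)
})

test_that("noise-free expression honours the planted archetypes exactly", {
  cfg <- simConfig(seed = 8, noiseSd = 0, dropoutRate = 0)
  ann <- simulateAnnotation(cfg)
  se <- simulateExpression(ann, ann$truth, cfg)
  V <- poolStages(se)
  truth <- ann$truth
  # stage-specific genes peak exactly at their planted stage
  for (gid in names(truth@specificStage)[1:10]) {
    expect_equal(colnames(V)[which.max(V[gid, ])],
                 unname(truth@specificStage[gid]))
  }
  # module members are perfectly pairwise correlated at the cell level
  # (log10-FPKM scale, where the planted relation is affine)
  m <- log10(SummarizedExperiment::assay(se, "fpkm"))
  g5 <- truth@plantedModules[[1]][1:5]
  cc <- stats::cor(t(m[g5, ]))
  expect_equal(unname(cc), matrix(1, 5, 5), tolerance = 1e-9)
  # planted pairs correlate perfectly when rho = 1
  cfg1 <- simConfig(seed = 8, noiseSd = 0, dropoutRate = 0, neighborRho = 1)
  ann1 <- simulateAnnotation(cfg1)
  se1 <- simulateExpression(ann1, ann1$truth, cfg1)
  V1 <- poolStages(se1)
  pp <- ann1$truth@plantedPairs
  for (i in seq_len(nrow(pp)))
    expect_equal(stats::cor(V1[pp$gene_a[i], ], V1[pp$gene_b[i], ]), 1.0,
                 tolerance = 1e-9)
  # FPKM is non-negative everywhere
  expect_true(all(SummarizedExperiment::assay(se, "fpkm") >= 0))
})

test_that("lncRNAs are lower expressed and dropout injects zeros at rate", {
  fx <- simFixture(1)
  m <- SummarizedExperiment::assay(fx$se, "fpkm")
  bt <- fx$ann$genes$biotype
  arch <- fx$truth@geneArchetype
  flat <- arch == "flat"
  expect_lt(stats::median(m[bt == "lncRNA" & flat, ]),
            stats::median(m[bt == "coding" & flat, ]))
  zeroRate <- mean(m[flat & bt == "coding", ] == 0)
  expect_equal(zeroRate, fx$cfg@dropoutRate, tolerance = 0.02)
})

test_that("identical seeds give byte-identical files, different seeds differ", {
  cfg <- simConfig(seed = 5, nGenes = 80L, nModules = 1L, moduleSize = 20L,
                   nSpecificGenes = 10L, nNeighborPairsDivergent = 2L,
                   nNeighborPairsUnidirectional = 2L)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  for (d in c(d1, d2)) {
    ann <- simulateAnnotation(cfg)
    se <- simulateExpression(ann, ann$truth, cfg)
    writeSimulation(ann, se, d)
    fx <- simulateAssemblyFixture(ann, cfg)
    writeAssemblyFixture(fx, d)
  }
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  cfg2 <- simConfig(seed = 6, nGenes = 80L, nModules = 1L, moduleSize = 20L,
                    nSpecificGenes = 10L, nNeighborPairsDivergent = 2L,
                    nNeighborPairsUnidirectional = 2L)
  ann2 <- simulateAnnotation(cfg2)
  expect_false(identical(GenomicRanges::start(ann2$genes),
                         GenomicRanges::start(simulateAnnotation(cfg)$genes)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulation does not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateAnnotation(simConfig(nGenes = 80L, nModules = 1L,
                                         moduleSize = 20L,
                                         nSpecificGenes = 10L, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("assembly fixture classes have the planted geometry", {
  fx <- simulateAssemblyFixture(simFixture(1)$ann, simFixture(1)$cfg)
  lab <- fx$truth@assemblyLabels
  # every emitted transcript has a truth label and vice versa
  expect_setequal(lab$transcript_id, names(fx$setA))
  expect_setequal(lab$transcript_id, names(fx$setB))
  ts <- lab$transcript_id[lab$class == "too_short"]
  expect_true(all(sum(IRanges::width(fx$setA[ts])) <= 200))
  se1 <- lab$transcript_id[lab$class == "single_exon"]
  expect_true(all(lengths(fx$setA[se1]) == 1))
  nv <- lab$transcript_id[lab$class == "novel_lnc"]
  expect_true(all(lengths(fx$setA[nv]) >= 2))
  expect_true(all(sum(IRanges::width(fx$setA[nv])) > 200))
  # novel transcripts keep identical intron chains across assemblers
  keyA <- embryoLnc:::.chainKeys(fx$setA[nv])
  keyB <- embryoLnc:::.chainKeys(fx$setB[nv])
  expect_identical(keyA, keyB)
  # coverage distributions are separated between labels
  cov <- fx$coverage
  expect_gt(min(cov$coverage[cov$label == "good"]),
            max(cov$coverage[cov$label == "bad"]))
  # planted novel lncRNAs carry unanimous noncoding calls
  calls <- fx$calls
  rownames(calls) <- calls$transcript_id
  expect_true(all(as.matrix(calls[nv, -1]) == "noncoding"))
  cl <- lab$transcript_id[lab$class == "coding_like"]
  expect_true(all(rowSums(as.matrix(calls[cl, -1]) == "coding") >= 1))
})
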