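#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Construct a simulation configuration
#'
#' Returns a validated [SimConfig-class]. The defaults describe a 7-stage
#' human pre-implantation design: metaphase II oocyte, zygote, 2-cell,
#' 4-cell, 8-cell, morula and late blastocyst, with 3, 3, 6, 12, 20, 16 and
#' 30 cells respectively (90 single cells in total), so that the
#' statistical power of downstream analyses resembles real single-cell
#' embryo studies of that design. lncRNAs are simulated at a quarter of the
#' coding mean FPKM and are enriched among planted stage-specific genes,
#' mirroring the lower expression and higher temporal specificity of
#' lncRNAs relative to protein-coding genes.
#'
#' @param nChromosomes number of chromosomes.
#' @param nGenes total gene count.
#' @param fracLnc fraction of genes given the lncRNA biotype.
#' @param stages ordered stage names.
#' @param cellsPerStage cells per stage (aligned with \code{stages}).
#' @param nModules,moduleSize planted co-expression modules and their size.
#' @param nSpecificGenes planted stage-specific genes.
#' @param nNeighborPairsDivergent,nNeighborPairsUnidirectional planted
#'   lncRNA-coding neighbor pairs (head-to-head and same-strand).
#' @param neighborGapBp gap between planted pair gene bodies, bp (< 10000).
#' @param neighborRho latent correlation of planted pairs on the log scale.
#' @param lncExpressionScale multiplicative lncRNA mean-FPKM factor (< 1).
#' @param noiseSd SD of the per-cell Gaussian noise on log10 FPKM
#'   (multiplicative lognormal noise on FPKM).
#' @param dropoutRate per-cell zero-inflation probability.
#' @param seed integer seed driving every stochastic draw.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 100, seed = 7)
#' cfg
#' @export
simConfig <- function(nChromosomes = 3L,
                      nGenes = 400L,
                      fracLnc = 0.3,
                      stages = c("oocyte", "zygote", "2cell", "4cell",
                                 "8cell", "morula", "blastocyst"),
                      cellsPerStage = c(3L, 3L, 6L, 12L, 20L, 16L, 30L),
                      nModules = 3L,
                      moduleSize = 40L,
                      nSpecificGenes = 60L,
                      nNeighborPairsDivergent = 10L,
                      nNeighborPairsUnidirectional = 10L,
                      neighborGapBp = 5000L,
                      neighborRho = 0.8,
                      lncExpressionScale = 0.25,
                      noiseSd = 0.2,
                      dropoutRate = 0.1,
                      seed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      nGenes = as.integer(nGenes),
      fracLnc = fracLnc,
      stages = as.character(stages),
      cellsPerStage = as.integer(cellsPerStage),
      nModules = as.integer(nModules),
      moduleSize = as.integer(moduleSize),
      nSpecificGenes = as.integer(nSpecificGenes),
      nNeighborPairsDivergent = as.integer(nNeighborPairsDivergent),
      nNeighborPairsUnidirectional = as.integer(nNeighborPairsUnidirectional),
      neighborGapBp = as.integer(neighborGapBp),
      neighborRho = neighborRho,
      lncExpressionScale = lncExpressionScale,
      noiseSd = noiseSd,
      dropoutRate = dropoutRate,
      seed = as.integer(seed))
}

# exon structure for one gene: returns IRanges of exons relative to a
# body starting at `start` (1-based), plus the body end.
.geneExons <- function(start, nExons, exonW, intronW) {
  s <- integer(nExons); e <- integer(nExons)
  pos <- start
  for (i in seq_len(nExons)) {
    s[i] <- pos
    e[i] <- pos + exonW[i] - 1L
    if (i < nExons) pos <- e[i] + intronW[i] + 1L
  }
  IRanges(start = s, end = e)
}

#' Simulate a gene annotation with planted neighbor structure
#'
#' Places \code{nGenes} multi-exon genes across chromosomes. Genes are
#' spaced at least 20 kb apart so that no unintended neighbor pairs
#' (gap < 10 kb) arise; the requested divergent (head-to-head, opposite
#' strands) and unidirectional (same strand) lncRNA-coding pairs are
#' planted with a gene-body gap of exactly \code{neighborGapBp}.
#' Coordinates follow the 1-based inclusive GTF convention.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements \code{genes} (a \code{GRanges} of gene
#'   bodies with \code{gene_id} and \code{biotype} columns), \code{exons}
#'   (a \code{GRangesList} of exons per gene, one transcript per gene) and
#'   \code{truth} (a [SyntheticTruth-class]).
#' @examples
#' ann <- simulateAnnotation(simConfig(nGenes = 60, seed = 1))
#' ann$genes
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  withSeed(config@seed, .simulateAnnotationImpl(config))
}

.simulateAnnotationImpl <- function(config) {
  nG <- config@nGenes
  ids <- sprintf("G%04d", seq_len(nG))

  # role layout: pairs first, then module genes, stage-specific, flat
  nDiv <- config@nNeighborPairsDivergent
  nUni <- config@nNeighborPairsUnidirectional
  nPairGenes <- 2L * (nDiv + nUni)
  nMod <- config@nModules * config@moduleSize
  nSpec <- config@nSpecificGenes

  role <- rep("flat", nG)
  pairIdx <- seq_len(nPairGenes)
  modIdx <- seq_len(nMod) + nPairGenes
  specIdx <- seq_len(nSpec) + nPairGenes + nMod
  role[modIdx] <- "module"
  role[specIdx] <- "stage_specific"

  # biotype: planted pairs are lncRNA + coding; stage-specific slots are
  # lncRNA-enriched (rate 2 * fracLnc, capped at 1); remaining genes fill
  # the global lncRNA quota
  biotype <- rep(NA_character_, nG)
  if (nPairGenes) {
    aPos <- pairIdx[seq(1L, nPairGenes, by = 2L)]
    biotype[aPos] <- "lncRNA"
    biotype[aPos + 1L] <- "coding"
  }
  if (nSpec) {
    pLnc <- min(1, 2 * config@fracLnc)
    biotype[specIdx] <- ifelse(stats::runif(nSpec) < pLnc, "lncRNA", "coding")
  }
  rest <- which(is.na(biotype))
  nLncTarget <- round(config@fracLnc * nG)
  nLncLeft <- max(0L, nLncTarget - sum(biotype == "lncRNA", na.rm = TRUE))
  lncPick <- if (length(rest)) sample(rest, min(nLncLeft, length(rest))) else integer()
  biotype[rest] <- "coding"
  biotype[lncPick] <- "lncRNA"

  # placement units: a planted pair occupies one unit, other genes one each
  unitFirst <- c(pairIdx[seq(1L, length.out = nDiv + nUni, by = 2L)],
                 setdiff(seq_len(nG), pairIdx))
  nUnits <- length(unitFirst)
  unitChrom <- rep(seq_len(config@nChromosomes), length.out = nUnits)

  chrom <- character(nG); strand <- character(nG)
  exonList <- vector("list", nG)
  gstart <- integer(nG); gend <- integer(nG)
  cursor <- rep(1L, config@nChromosomes)
  maxLen <- 250000000L

  placeGene <- function(i, chr, start, str) {
    nEx <- sample(2:5, 1L)
    exW <- sample(100:400, nEx, replace = TRUE)
    inW <- if (nEx > 1L) sample(500:2000, nEx - 1L, replace = TRUE) else integer()
    ex <- .geneExons(start, nEx, exW, inW)
    chrom[i] <<- chr; strand[i] <<- str
    exonList[[i]] <<- ex
    gstart[i] <<- min(IRanges::start(ex)); gend[i] <<- max(IRanges::end(ex))
    gend[i]
  }

  for (u in seq_len(nUnits)) {
    i <- unitFirst[u]
    ch <- unitChrom[u]
    chr <- paste0("chr", ch)
    start <- cursor[ch] + 20000L + sample(0:10000, 1L)
    if (i %in% pairIdx) {
      k <- (match(i, pairIdx) + 1L) %/% 2L   # pair index
      divergent <- k <= nDiv
      sA <- if (divergent) "-" else "+"
      sB <- "+"
      endA <- placeGene(i, chr, start, sA)
      placeGene(i + 1L, chr, endA + config@neighborGapBp, sB)
      cursor[ch] <- gend[i + 1L]
    } else {
      placeGene(i, chr, start, sample(c("+", "-"), 1L))
      cursor[ch] <- gend[i]
    }
    if (cursor[ch] > maxLen)
      stop("chromosome length insufficient for requested gene count",
           call. = FALSE)
  }

  seqlen <- cursor + 50000L
  names(seqlen) <- paste0("chr", seq_len(config@nChromosomes))
  genes <- GRanges(chrom, IRanges(gstart, gend), strand = strand,
                   gene_id = ids, biotype = biotype,
                   seqlengths = seqlen)
  names(genes) <- ids
  exons <- GRangesList(lapply(seq_len(nG), function(i)
    GRanges(chrom[i], exonList[[i]], strand = strand[i],
            seqlengths = seqlen)))
  names(exons) <- ids

  # truth
  specStage <- character()
  if (nSpec) {
    specStage <- sample(config@stages, nSpec, replace = TRUE)
    names(specStage) <- ids[specIdx]
  }
  mods <- list()
  if (config@nModules > 0L) {
    mods <- split(ids[modIdx],
                  rep(seq_len(config@nModules), each = config@moduleSize))
    names(mods) <- paste0("M", seq_len(config@nModules))
  }
  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      orientation = character(), gap_bp = integer(),
                      rho = numeric(), stringsAsFactors = FALSE)
  if (nDiv + nUni > 0L) {
    aPos <- pairIdx[seq(1L, nPairGenes, by = 2L)]
    pairs <- data.frame(
      gene_a = ids[aPos], gene_b = ids[aPos + 1L],
      orientation = rep(c("divergent", "unidirectional"), c(nDiv, nUni)),
      gap_bp = config@neighborGapBp,
      rho = config@neighborRho, stringsAsFactors = FALSE)
  }
  arch <- role
  names(arch) <- ids
  truth <- new("SyntheticTruth", geneArchetype = arch,
               specificStage = specStage, plantedModules = mods,
               plantedPairs = pairs,
               assemblyLabels = data.frame())
  list(genes = genes, exons = exons, truth = truth)
}

#' Simulate a stage-structured FPKM expression matrix
#'
#' Generates per-cell FPKM values from stage-level means defined on the
#' log10-FPKM scale: a flat gene has a stage-constant mean; a planted
#' stage-specific gene is near-silent off stage and strongly induced
#' (well above 8-fold in FPKM) in its assigned stage only; genes of a
#' planted module follow that module's latent stage trajectory (an affine
#' transform of the trajectory per gene on the log scale, so members are
#' perfectly correlated in the noise-free limit); planted neighbor pairs
#' share a latent stage trajectory with correlation \code{neighborRho} on
#' the log scale. Cell-level noise is multiplicative lognormal
#' (Gaussian of SD \code{noiseSd} on log10 FPKM), lncRNA means are scaled
#' by \code{lncExpressionScale} in FPKM, and zeros are injected at
#' \code{dropoutRate}.
#'
#' @param annotation,truth output of [simulateAnnotation()].
#' @param config the same [SimConfig-class].
#' @return A \code{SummarizedExperiment} with assay \code{"fpkm"}
#'   (genes x cells), \code{colData} column \code{stage} (ordered factor)
#'   and \code{rowData} columns \code{gene_id} and \code{biotype}.
#' @examples
#' cfg <- simConfig(nGenes = 60, seed = 1)
#' ann <- simulateAnnotation(cfg)
#' se <- simulateExpression(ann, ann$truth, cfg)
#' se
#' @export
simulateExpression <- function(annotation, truth, config) {
  validObject(config)
  withSeed(config@seed + 1L, .simulateExpressionImpl(annotation, truth, config))
}

.simulateExpressionImpl <- function(annotation, truth, config) {
  genes <- annotation$genes
  ids <- genes$gene_id
  nG <- length(ids)
  nS <- length(config@stages)
  stageOfCell <- rep(config@stages, config@cellsPerStage)
  cellIds <- sprintf("%s_c%02d", stageOfCell,
                     unlist(lapply(config@cellsPerStage, seq_len)))
  nC <- length(cellIds)

  # base mean on the log10-FPKM scale (FPKM ~ 5-60 for coding genes);
  # lncRNA means scaled multiplicatively in FPKM space
  mu <- stats::runif(nG, 0.7, 1.8)
  isLnc <- genes$biotype == "lncRNA"
  mu[isLnc] <- mu[isLnc] + log10(config@lncExpressionScale)

  # per-gene stage mean matrix (genes x stages), log10-FPKM scale
  M <- matrix(mu, nG, nS)

  # stage-specific genes are near-silent off stage and strongly induced in
  # their stage (>= 8x in FPKM by construction, typically far more), the
  # pattern that makes a gene temporally specific on the density scale
  specIds <- names(truth@specificStage)
  if (length(specIds)) {
    si <- match(specIds, ids)
    st <- match(truth@specificStage, config@stages)
    offFpkm <- stats::runif(length(si), 0.01, 0.1)
    onFpkm <- stats::runif(length(si), 20, 60)
    if (any(isLnc[si])) {
      offFpkm[isLnc[si]] <- offFpkm[isLnc[si]] * config@lncExpressionScale
      onFpkm[isLnc[si]] <- onFpkm[isLnc[si]] * config@lncExpressionScale
    }
    M[si, ] <- log10(offFpkm)
    M[cbind(si, st)] <- log10(onFpkm)
  }

  amp <- 0.6
  if (length(truth@plantedModules)) {
    peaks <- round(seq(1, nS, length.out = length(truth@plantedModules) + 2))
    peaks <- peaks[-c(1, length(peaks))]
    for (k in seq_along(truth@plantedModules)) {
      traj <- exp(-((seq_len(nS) - peaks[k])^2) / 2)
      traj <- as.numeric(scale(traj))
      gi <- match(truth@plantedModules[[k]], ids)
      loading <- stats::runif(length(gi), 0.8, 1.2)
      M[gi, ] <- mu[gi] + outer(loading, amp * traj)
    }
  }

  if (nrow(truth@plantedPairs)) {
    for (p in seq_len(nrow(truth@plantedPairs))) {
      ia <- match(truth@plantedPairs$gene_a[p], ids)
      ib <- match(truth@plantedPairs$gene_b[p], ids)
      rho <- truth@plantedPairs$rho[p]
      L <- as.numeric(scale(stats::rnorm(nS)))
      Mx <- as.numeric(scale(stats::rnorm(nS)))
      M[ia, ] <- mu[ia] + amp * L
      M[ib, ] <- mu[ib] + amp * (rho * L + sqrt(1 - rho^2) * Mx)
    }
  }

  # lognormal cell-level noise: FPKM = stage-mean FPKM * 10^N(0, noiseSd),
  # i.e. additive Gaussian noise on log10 FPKM, so silence stays silent and
  # planted affine relationships between log profiles are exact
  stIdx <- match(stageOfCell, config@stages)
  meanFpkm <- 10^M[, stIdx, drop = FALSE]
  fpkm <- meanFpkm
  if (config@noiseSd > 0)
    fpkm <- meanFpkm * 10^matrix(stats::rnorm(nG * nC, 0, config@noiseSd),
                                 nG, nC)
  if (config@dropoutRate > 0) {
    drop <- matrix(stats::runif(nG * nC) < config@dropoutRate, nG, nC)
    fpkm[drop] <- 0
  }
  dimnames(fpkm) <- list(ids, cellIds)

  SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = DataFrame(cell_id = cellIds,
                        stage = factor(stageOfCell, levels = config@stages),
                        row.names = cellIds),
    rowData = DataFrame(gene_id = ids, biotype = genes$biotype,
                        row.names = ids))
}

# trim a transcript's exons (GRanges) so the retained exonic bases are
# ~ frac of the original, dropping from the 3' side on the + convention
.trimExons <- function(ex, frac) {
  ex <- sort(ex)
  w <- IRanges::width(ex)
  target <- max(1L, ceiling(frac * sum(w)))
  # keep at least one base of the second exon so the trimmed model stays
  # multi-exon (callers sample >= 3-exon sources, keeping recovery < 0.75)
  if (length(w) >= 2L) target <- max(target, w[1] + 1L)
  keepW <- pmin(w, pmax(0L, target - c(0L, cumsum(w))[seq_along(w)]))
  ex <- ex[keepW > 0L]
  keepW <- keepW[keepW > 0L]
  IRanges::end(ex) <- IRanges::start(ex) + keepW - 1L
  ex
}

#' Simulate a transcript-assembly fixture
#'
#' Builds two assembled transcript sets (emulating two independent
#' assemblers) plus a reference, with four planted transcript classes:
#' \itemize{
#'   \item \code{annotated}: copies of reference transcripts, trimmed so
#'     that a known subset recovers at least 75\% of the reference exonic
#'     bases (label \code{good}) and the rest less than that (\code{bad});
#'   \item \code{too_short}: novel multi-exon transcripts of total exonic
#'     length at most 200 bp;
#'   \item \code{single_exon}: novel single-exon transcripts;
#'   \item \code{novel_lnc} and \code{coding_like}: novel intergenic
#'     multi-exon transcripts > 200 bp, differing in their planted
#'     coding-potential calls.
#' }
#' Novel transcripts appear in both sets with identical intron chains.
#' Read coverages are drawn from two separated distributions for good vs
#' bad transcripts.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config the [SimConfig-class] (its seed, offset, drives draws).
#' @param nNovel,nCodingLike,nAnnotated,nTooShort,nSingleExon planted class
#'   sizes.
#' @param goodCoverage,badCoverage length-2 numeric ranges the good and bad
#'   read coverages are drawn from (reads per base).
#' @param callNoncodingProb probability that a pseudo-tool calls a planted
#'   novel lncRNA noncoding (tool agreement; 1 = unanimous).
#' @return A list with \code{setA}, \code{setB}, \code{reference}
#'   (GRangesLists of exons per transcript), \code{referenceCategory}
#'   (named \code{coding}/\code{noncoding} vector), \code{coverage}
#'   (data.frame: transcript_id, coverage, label, category), \code{calls}
#'   (data.frame: transcript_id + 4 tool columns) and \code{truth}
#'   (the input [SyntheticTruth-class] with \code{assemblyLabels} filled).
#' @export
simulateAssemblyFixture <- function(annotation, config,
                                    nNovel = 10L, nCodingLike = 5L,
                                    nAnnotated = 10L, nTooShort = 6L,
                                    nSingleExon = 6L,
                                    goodCoverage = c(10, 30),
                                    badCoverage = c(0.2, 2),
                                    callNoncodingProb = 1) {
  withSeed(config@seed + 2L,
           .simulateAssemblyImpl(annotation, config, nNovel, nCodingLike,
                                 nAnnotated, nTooShort, nSingleExon,
                                 goodCoverage, badCoverage,
                                 callNoncodingProb))
}

.simulateAssemblyImpl <- function(annotation, config, nNovel, nCodingLike,
                                  nAnnotated, nTooShort, nSingleExon,
                                  goodCoverage, badCoverage,
                                  callNoncodingProb) {
  genes <- annotation$genes
  refExons <- annotation$exons
  ids <- genes$gene_id
  category <- ifelse(genes$biotype == "coding", "coding", "noncoding")
  names(category) <- ids

  setA <- list(); setB <- list()
  class_ <- character(); label <- character(); tid <- character()

  # annotated class: trimmed copies of reference transcripts, stratified
  # by category (coding / noncoding reference) and split within each into
  # good (recovery >= 0.75) and bad (< 0.75), so both ROC categories are
  # non-degenerate; both assemblers emit the identical model so the pair
  # survives intersection
  pick <- integer()
  nHalf <- c(ceiling(nAnnotated / 2), floor(nAnnotated / 2))
  multiExon <- lengths(refExons) >= 3L
  for (ci in 1:2) {
    pool <- which(category == c("coding", "noncoding")[ci] & multiExon)
    nTake <- min(nHalf[ci], length(pool))
    catPick <- sample(pool, nTake)
    for (j in seq_along(catPick)) {
      g <- catPick[j]
      good <- j %% 2L == 1L   # alternate: >= 1 good and >= 1 bad per category
      frac <- if (good) stats::runif(1, 0.8, 1.0) else stats::runif(1, 0.3, 0.6)
      ex <- .trimExons(refExons[[g]], frac)
      id <- sprintf("ASM%04d", length(tid) + 1L)
      tid <- c(tid, id); class_ <- c(class_, "annotated")
      label <- c(label, if (good) "good" else "bad")
      setA[[id]] <- ex; setB[[id]] <- ex
      pick <- c(pick, g)
    }
  }

  # novel placement region: beyond the genes on chr1
  chr <- "chr1"
  pos <- max(IRanges::end(genes[seqnames(genes) == chr])) + 50000L

  addNovel <- function(nEx, exW, cls) {
    inW <- if (nEx > 1L) sample(500:1500, nEx - 1L, replace = TRUE) else integer()
    ex <- GRanges(chr, .geneExons(pos, nEx, exW, inW), strand = "+")
    pos <<- max(IRanges::end(ex)) + 20000L
    id <- sprintf("ASM%04d", length(tid) + 1L)
    tid <<- c(tid, id); class_ <<- c(class_, cls); label <<- c(label, "bad")
    setA[[id]] <<- ex
    if (nEx > 1L) {
      # same intron chain, jittered terminal exon ends in assembler B
      exB <- ex
      IRanges::start(exB)[1] <- max(1L, IRanges::start(exB)[1] - sample(0:50, 1L))
      IRanges::end(exB)[nEx] <- IRanges::end(exB)[nEx] + sample(0:50, 1L)
      setB[[id]] <<- exB
    } else setB[[id]] <<- ex
    id
  }

  for (i in seq_len(nNovel)) {
    nEx <- sample(2:4, 1L)
    addNovel(nEx, sample(150:400, nEx, replace = TRUE), "novel_lnc")
  }
  for (i in seq_len(nCodingLike))
    addNovel(3L, sample(150:400, 3L, replace = TRUE), "coding_like")
  for (i in seq_len(nTooShort)) addNovel(2L, c(80L, 100L), "too_short")
  for (i in seq_len(nSingleExon)) addNovel(1L, 500L, "single_exon")

  setA <- GRangesList(setA); setB <- GRangesList(setB)
  # assembled GTFs carry no sequence sizes; novel transcripts extend past
  # the annotated span, so inherited seqlengths would be misleading
  seqlengths(setA) <- NA
  seqlengths(setB) <- NA

  # coverage: annotated transcripts only carry meaningful good/bad labels
  annIdx <- which(class_ == "annotated")
  cov <- data.frame(
    transcript_id = tid[annIdx],
    coverage = ifelse(label[annIdx] == "good",
                      stats::runif(length(annIdx), goodCoverage[1], goodCoverage[2]),
                      stats::runif(length(annIdx), badCoverage[1], badCoverage[2])),
    label = label[annIdx],
    category = category[ids[pick]],
    stringsAsFactors = FALSE)

  # coding-potential calls by 4 pseudo-tools
  tools <- paste0("tool", 1:4)
  calls <- matrix("noncoding", length(tid), 4,
                  dimnames = list(tid, tools))
  for (id in tid[class_ == "novel_lnc"])
    calls[id, ] <- ifelse(stats::runif(4) < callNoncodingProb,
                          "noncoding", "coding")
  for (id in tid[class_ == "coding_like"]) {
    cc <- ifelse(stats::runif(4) < 0.7, "coding", "noncoding")
    cc[sample(4, 1L)] <- "coding"   # guarantee >= 1 coding call
    calls[id, ] <- cc
  }
  callsDf <- data.frame(transcript_id = tid, calls,
                        stringsAsFactors = FALSE, row.names = NULL)

  truth <- annotation$truth
  truth@assemblyLabels <- data.frame(
    transcript_id = tid, class = class_, label = label,
    stringsAsFactors = FALSE)

  list(setA = setA, setB = setB, reference = refExons,
       referenceCategory = category, coverage = cov, calls = callsDf,
       truth = truth)
}
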