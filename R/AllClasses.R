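#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' Simulation configuration
#'
#' Parameters for the synthetic embryo transcriptome generator. Defaults
#' emulate a 7-stage human pre-implantation design (oocyte through late
#' blastocyst) with 3, 3, 6, 12, 20, 16 and 30 cells per stage, lncRNAs
#' expressed at a fraction of coding-gene levels, and planted structure
#' (stage-specific genes, co-expression modules, cis neighbor pairs) that
#' downstream analyses are expected to recover.
#'
#' @slot nChromosomes number of chromosomes genes are placed on.
#' @slot nGenes total number of genes.
#' @slot fracLnc fraction of genes assigned the lncRNA biotype, in [0,1].
#' @slot stages ordered character vector of developmental stage names.
#' @slot cellsPerStage integer vector of cells per stage, aligned to
#'   \code{stages}.
#' @slot nModules number of planted co-expression modules.
#' @slot moduleSize genes per planted module.
#' @slot nSpecificGenes number of planted stage-specific genes.
#' @slot nNeighborPairsDivergent planted head-to-head lncRNA-coding pairs.
#' @slot nNeighborPairsUnidirectional planted same-strand lncRNA-coding pairs.
#' @slot neighborGapBp gap in bp between planted pair gene bodies (< 10000).
#' @slot neighborRho latent-factor correlation of planted pairs, in [0,1].
#' @slot lncExpressionScale multiplicative factor (< 1) applied to lncRNA
#'   mean FPKM relative to coding genes.
#' @slot noiseSd standard deviation of per-cell noise on the
#'   log10(FPKM + 1) scale.
#' @slot dropoutRate per-cell probability of an injected zero.
#' @slot seed integer seed; all stochastic draws derive from it.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    nChromosomes = "integer",
    nGenes = "integer",
    fracLnc = "numeric",
    stages = "character",
    cellsPerStage = "integer",
    nModules = "integer",
    moduleSize = "integer",
    nSpecificGenes = "integer",
    nNeighborPairsDivergent = "integer",
    nNeighborPairsUnidirectional = "integer",
    neighborGapBp = "integer",
    neighborRho = "numeric",
    lncExpressionScale = "numeric",
    noiseSd = "numeric",
    dropoutRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@cellsPerStage) != length(object@stages))
    msg <- c(msg, "cellsPerStage must align with stages")
  if (any(object@cellsPerStage < 1L))
    msg <- c(msg, "cellsPerStage entries must be positive")
  if (object@fracLnc < 0 || object@fracLnc > 1)
    msg <- c(msg, "fracLnc must lie in [0, 1]")
  if (object@neighborRho < 0 || object@neighborRho > 1)
    msg <- c(msg, "neighborRho must lie in [0, 1]")
  if (object@neighborGapBp >= 10000L)
    msg <- c(msg, "neighborGapBp must be < 10000 so planted pairs are neighbors")
  if (object@lncExpressionScale <= 0 || object@lncExpressionScale >= 1)
    msg <- c(msg, "lncExpressionScale must lie in (0, 1)")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(c(object@nGenes, object@nModules, object@moduleSize,
            object@nSpecificGenes, object@nNeighborPairsDivergent,
            object@nNeighborPairsUnidirectional) < 0L))
    msg <- c(msg, "counts must be >= 0")
  nPlanted <- object@nModules * object@moduleSize + object@nSpecificGenes +
    2L * (object@nNeighborPairsDivergent + object@nNeighborPairsUnidirectional)
  if (nPlanted > object@nGenes)
    msg <- c(msg, "planted structure requires more genes than nGenes provides")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a simulation
#'
#' Records which archetype each simulated gene was drawn from, the planted
#' module memberships, the planted neighbor pairs, and labels for assembly
#' fixtures, so that recovery tests can compare analysis output against
#' construction.
#'
#' @slot geneArchetype named character vector, gene id to one of
#'   \code{"flat"}, \code{"stage_specific"} or \code{"module"}.
#' @slot specificStage named character vector, stage label for each
#'   stage-specific gene.
#' @slot plantedModules named list, module id to character vector of gene ids
#'   (disjoint sets).
#' @slot plantedPairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{orientation}, \code{gap_bp}, \code{rho}.
#' @slot assemblyLabels data.frame of transcript-level labels for assembly
#'   fixtures (filled by [simulateAssemblyFixture()]).
#' @export
setClass("SyntheticTruth",
  representation(
    geneArchetype = "character",
    specificStage = "character",
    plantedModules = "list",
    plantedPairs = "data.frame",
    assemblyLabels = "data.frame"
  )
)

setValidity("SyntheticTruth", function(object) {
  mods <- unlist(object@plantedModules, use.names = FALSE)
  if (anyDuplicated(mods))
    return("planted module gene sets must be disjoint")
  if (length(mods) && !all(mods %in% names(object@geneArchetype)))
    return("planted module genes must carry an archetype label")
  TRUE
})

#' Signed weighted co-expression network
#'
#' Holds the Pearson correlation matrix of a gene subset, the signed
#' adjacency a_ij = ((1 + cor_ij) / 2)^beta, and its topological overlap
#' matrix (TOM). The dissimilarity 1 - TOM is the clustering substrate for
#' module detection.
#'
#' @slot genes character vector of gene ids (row/column order of matrices).
#' @slot cor gene x gene Pearson correlation matrix.
#' @slot beta soft-thresholding power.
#' @slot adjacency signed adjacency matrix, entries in [0,1], unit diagonal.
#' @slot tom topological overlap matrix, symmetric, unit diagonal.
#' @export
setClass("CoexpressionNetwork",
  representation(
    genes = "character",
    cor = "matrix",
    beta = "numeric",
    adjacency = "matrix",
    tom = "matrix"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  n <- length(object@genes)
  for (nm in c("cor", "adjacency", "tom")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      return(sprintf("%s must be %d x %d", nm, n, n))
    if (max(abs(m - t(m))) > 1e-8)
      return(sprintf("%s must be symmetric", nm))
  }
  a <- object@adjacency
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
    return("adjacency entries must lie in [0, 1]")
  if (max(abs(diag(a) - 1)) > 1e-12)
    return("adjacency diagonal must be 1")
  if (max(abs(diag(object@tom) - 1)) > 1e-12)
    return("TOM diagonal must be 1")
  TRUE
})

#' Module decomposition of a co-expression network
#'
#' Gene-to-module assignment (label \code{"grey"} reserved for unassigned
#' genes), module eigengenes (first principal component of the standardized
#' module expression, unit variance, sign fixed so that the mean module
#' membership of own-module genes is positive), the gene x module kME
#' (module membership) matrix, module-trait correlations, and hub gene sets.
#'
#' @slot assignment named character vector, gene id to module label.
#' @slot eigengenes samples x modules numeric matrix of eigengene profiles.
#' @slot kme genes x modules matrix of module membership correlations.
#' @slot traitCor list with elements \code{r} and \code{p}
#'   (modules x traits matrices), filled by [moduleTrait()].
#' @slot hubs named list, module to character vector of hub gene ids,
#'   filled by [kmeAndHubs()].
#' @export
setClass("ModuleSet",
  representation(
    assignment = "character",
    eigengenes = "matrix",
    kme = "matrix",
    traitCor = "list",
    hubs = "list"
  )
)

setValidity("ModuleSet", function(object) {
  mods <- setdiff(unique(object@assignment), "grey")
  if (ncol(object@eigengenes) > 0 &&
      !all(sort(colnames(object@eigengenes)) == sort(mods)))
    return("eigengene columns must match the non-grey module labels")
  if (ncol(object@eigengenes) > 0) {
    v <- apply(object@eigengenes, 2, stats::var)
    if (any(abs(v - 1) > 1e-6))
      return("eigengenes must have unit variance")
  }
  TRUE
})
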