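#' @include AllClasses.R
NULL

#' Accessors for network and module objects
#'
#' @param x a [CoexpressionNetwork-class] or [ModuleSet-class] object.
#' @return \code{networkGenes}: character vector of gene ids.
#'   \code{adjacencyMatrix}, \code{tomMatrix}: numeric matrices.
#'   \code{softPower}: the soft-thresholding power.
#'   \code{moduleAssignment}: named character vector gene -> module.
#'   \code{moduleEigengenes}: samples x modules matrix.
#'   \code{moduleKME}: genes x modules kME matrix.
#'   \code{moduleHubs}: named list of hub gene ids per module.
#'   \code{moduleLabels}: character vector of non-grey module labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))
#' @rdname accessors
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))
#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setGeneric("moduleKME", function(x) standardGeneric("moduleKME"))
#' @rdname accessors
#' @export
setGeneric("moduleHubs", function(x) standardGeneric("moduleHubs"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
setMethod("networkGenes", "CoexpressionNetwork", function(x) x@genes)
#' @rdname accessors
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)
#' @rdname accessors
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)
#' @rdname accessors
setMethod("softPower", "CoexpressionNetwork", function(x) x@beta)
#' @rdname accessors
setMethod("moduleAssignment", "ModuleSet", function(x) x@assignment)
#' @rdname accessors
setMethod("moduleEigengenes", "ModuleSet", function(x) x@eigengenes)
#' @rdname accessors
setMethod("moduleKME", "ModuleSet", function(x) x@kme)
#' @rdname accessors
setMethod("moduleHubs", "ModuleSet", function(x) x@hubs)
#' @rdname accessors
setMethod("moduleLabels", "ModuleSet", function(x) {
  setdiff(unique(x@assignment), "grey")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes (",
      round(100 * object@fracLnc), "% lncRNA ) on",
      object@nChromosomes, "chromosomes\n")
  cat("  stages: ", paste(object@stages, collapse = ", "), "\n", sep = "")
  cat("  cells/stage: ", paste(object@cellsPerStage, collapse = ", "),
      "  (", sum(object@cellsPerStage), " cells)\n", sep = "")
  cat("  planted:", object@nModules, "modules x", object@moduleSize,
      "genes;", object@nSpecificGenes, "stage-specific;",
      object@nNeighborPairsDivergent, "divergent +",
      object@nNeighborPairsUnidirectional, "unidirectional pairs\n")
  cat("  noiseSd:", object@noiseSd, " dropout:", object@dropoutRate,
      " seed:", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@geneArchetype)
  cat("SyntheticTruth:", length(object@geneArchetype), "genes (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  planted modules:", length(object@plantedModules),
      " neighbor pairs:", nrow(object@plantedPairs), "\n")
  if (nrow(object@assemblyLabels))
    cat("  assembly fixture transcripts:", nrow(object@assemblyLabels), "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@genes),
      "genes, signed adjacency beta =", object@beta, "\n")
  off <- object@tom[upper.tri(object@tom)]
  cat("  TOM range:", sprintf("[%.4f, %.4f]", min(off), max(off)), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  tab <- sort(table(object@assignment), decreasing = TRUE)
  cat("ModuleSet:", length(object@assignment), "genes in",
      length(setdiff(names(tab), "grey")), "modules\n")
  print(tab)
  if (length(object@hubs))
    cat("  hubs:", paste(names(object@hubs),
        vapply(object@hubs, length, 1L), sep = "=", collapse = ", "), "\n")
})
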