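#' @importFrom rtracklayer export import
#' @importFrom jsonlite write_json
NULL

# Build a GTF-shaped GRanges (gene/transcript/exon features) from exons
# grouped per transcript. `geneIds` maps transcript -> gene; `biotype`
# maps gene -> biotype (optional).
.gtfFeatures <- function(exonsByTx, geneIds, biotype = NULL) {
  txIds <- names(exonsByTx)
  feats <- list()
  for (i in seq_along(exonsByTx)) {
    ex <- sort(exonsByTx[[i]])
    tx <- range(ex)
    gid <- geneIds[i]
    bt <- if (!is.null(biotype)) unname(biotype[gid]) else NA_character_
    mk <- function(gr, type) {
      mcols(gr) <- DataFrame(type = type, gene_id = gid,
                             transcript_id = txIds[i],
                             gene_biotype = bt)
      gr
    }
    feats[[length(feats) + 1L]] <- mk(tx, "transcript")
    feats[[length(feats) + 1L]] <- mk(ex, "exon")
  }
  out <- unlist(GRangesList(feats))
  names(out) <- NULL
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the annotation as GTF (gene_id, transcript_id and gene_biotype
#' attributes; 1-based inclusive coordinates), the FPKM matrix as TSV
#' (rows = genes, columns = cells), a sample sheet TSV (cell_id, stage)
#' and the planted truth as JSON.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param se the \code{SummarizedExperiment} from [simulateExpression()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSimulation <- function(annotation, se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genes <- annotation$genes
  bt <- genes$biotype
  names(bt) <- genes$gene_id
  txIds <- paste0(genes$gene_id, ".t1")
  ex <- annotation$exons
  names(ex) <- txIds
  gid <- genes$gene_id
  names(gid) <- txIds
  feats <- .gtfFeatures(ex, gid, bt)
  paths <- c(annotation = file.path(dir, "annotation.gtf"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  rtracklayer::export(feats, paths["annotation"], format = "gtf")
  fpkm <- assay(se, "fpkm")
  utils::write.table(data.frame(gene_id = rownames(fpkm),
                                signif(fpkm, 6), check.names = FALSE),
                     paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(colData(se))[, c("cell_id", "stage")],
                     paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- annotation$truth
  jsonlite::write_json(list(
    gene_archetype = as.list(truth@geneArchetype),
    specific_stage = as.list(truth@specificStage),
    planted_modules = truth@plantedModules,
    planted_pairs = truth@plantedPairs),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write an assembly fixture to disk
#'
#' @param fixture output of [simulateAssemblyFixture()].
#' @param dir output directory.
#' @return Invisibly, the named vector of paths written (set A and B GTFs,
#'   reference GTF, coverage TSV, coding-call TSV).
#' @export
writeAssemblyFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(setA = file.path(dir, "assembler_A.gtf"),
             setB = file.path(dir, "assembler_B.gtf"),
             reference = file.path(dir, "reference.gtf"),
             coverage = file.path(dir, "coverage.tsv"),
             calls = file.path(dir, "coding_calls.tsv"))
  for (s in c("setA", "setB", "reference")) {
    ex <- fixture[[s]]
    gid <- names(ex)
    names(gid) <- names(ex)
    rtracklayer::export(.gtfFeatures(ex, gid), paths[s], format = "gtf")
  }
  utils::write.table(fixture$coverage, paths["coverage"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$calls, paths["calls"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read transcript models from a GTF file
#'
#' Parses exon features and groups them per transcript.
#'
#' @param path GTF file path.
#' @return A \code{GRangesList} of exons, one element per transcript,
#'   named by \code{transcript_id}.
#' @export
readTranscriptsGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  split(granges(ex), ex$transcript_id)
}

#' Read an expression matrix and sample sheet into a SummarizedExperiment
#'
#' @param matrixPath TSV with a \code{gene_id} column followed by one
#'   column per cell.
#' @param samplesPath TSV with columns \code{cell_id} and \code{stage}.
#' @param stages optional ordered stage levels; defaults to order of first
#'   appearance in the sample sheet.
#' @return A \code{SummarizedExperiment} with assay \code{"fpkm"}.
#' @export
readExpression <- function(matrixPath, samplesPath, stages = NULL) {
  m <- utils::read.delim(matrixPath, check.names = FALSE)
  rownames(m) <- m$gene_id
  m <- as.matrix(m[, -1, drop = FALSE])
  ss <- utils::read.delim(samplesPath)
  if (is.null(stages)) stages <- unique(ss$stage)
  ss <- ss[match(colnames(m), ss$cell_id), ]
  SummarizedExperiment(
    assays = list(fpkm = m),
    colData = DataFrame(cell_id = ss$cell_id,
                        stage = factor(ss$stage, levels = stages),
                        row.names = colnames(m)))
}

#' Read a GMT-style gene-set file
#'
#' Each line: set id, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write a novel transcript set as GTF and BED
#'
#' GTF uses 1-based inclusive coordinates with \code{gene_id} and
#' \code{transcript_id} attributes; BED12 uses 0-based half-open blocks.
#'
#' @param transcripts \code{GRangesList} of exons per transcript (e.g.
#'   the \code{novel} element of [runLncPipeline()]).
#' @param gtfPath,bedPath output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
writeNovelTranscripts <- function(transcripts, gtfPath = NULL,
                                  bedPath = NULL) {
  written <- character()
  if (!is.null(gtfPath)) {
    gid <- names(transcripts)
    names(gid) <- names(transcripts)
    rtracklayer::export(.gtfFeatures(transcripts, gid), gtfPath,
                        format = "gtf")
    written <- c(written, gtfPath)
  }
  if (!is.null(bedPath)) {
    rtracklayer::export(transcripts, bedPath, format = "bed")
    written <- c(written, bedPath)
  }
  invisible(written)
}
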