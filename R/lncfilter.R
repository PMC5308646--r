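# Novel-lncRNA detection pipeline: assembler intersection, annotation
# overlap removal, size/exon filter, coding-potential consensus.

#' @importFrom IRanges overlapsAny
NULL

# canonical intron-chain key of a transcript (exons as GRanges);
# NA for single-exon transcripts, which can never match
.intronChainKey <- function(ex) {
  ex <- sort(ex)
  if (length(ex) < 2L) return(NA_character_)
  istart <- IRanges::end(ex)[-length(ex)] + 1L
  iend <- IRanges::start(ex)[-1] - 1L
  paste(as.character(seqnames(ex)[1]), as.character(strand(ex)[1]),
        paste(istart, iend, sep = "-", collapse = ";"), sep = "|")
}

.chainKeys <- function(txs) {
  vapply(as.list(txs), .intronChainKey, "")
}

#' Intersect two assembler outputs
#'
#' Retains transcripts of set A whose chromosome, strand and intron chain
#' exactly match some transcript of set B (terminal exon ends may differ;
#' A's coordinates are kept). Single-exon transcripts have no intron chain
#' and never match.
#'
#' @param setA,setB \code{GRangesList}s of exons per transcript.
#' @return The retained subset of \code{setA}.
#' @export
intersectAssemblies <- function(setA, setB) {
  if (!length(setA) || !length(setB)) {
    warning("empty assembler input; intersection is empty")
    return(setA[integer()])
  }
  keysA <- .chainKeys(setA)
  keysB <- .chainKeys(setB)
  setA[!is.na(keysA) & keysA %in% keysB[!is.na(keysB)]]
}

#' Remove transcripts overlapping annotated exons
#'
#' A transcript is removed when at least one of its exons overlaps (by at
#' least 1 bp, strand-agnostically) at least one annotated exon from any
#' provided annotation set. A transcript lying entirely within an intron
#' of an annotated gene is retained.
#'
#' @param transcripts \code{GRangesList} of exons per transcript.
#' @param annotations a list of \code{GRangesList}s (or \code{GRanges}) of
#'   annotated exons; may be empty.
#' @return The unannotated subset of \code{transcripts}.
#' @export
removeAnnotatedOverlaps <- function(transcripts, annotations) {
  if (!length(annotations)) return(transcripts)
  annEx <- do.call(c, lapply(annotations, function(a) {
    if (is(a, "GRangesList")) unlist(a, use.names = FALSE) else a
  }))
  hit <- overlapsAny(transcripts, annEx, ignore.strand = TRUE)
  transcripts[!hit]
}

#' Size and exon-count filter
#'
#' Keeps transcripts whose summed exonic length is strictly greater than
#' \code{minLength} and whose exon count is at least \code{minExons}.
#'
#' @param transcripts \code{GRangesList} of exons per transcript.
#' @param minLength minimum exonic length in bp (strict; default 200, the
#'   conventional lncRNA size bound).
#' @param minExons minimum exon count (default 2, discarding single-exon
#'   fragments).
#' @return The filtered subset.
#' @export
sizeExonFilter <- function(transcripts, minLength = 200L, minExons = 2L) {
  len <- sum(IRanges::width(transcripts))
  nEx <- lengths(transcripts)
  transcripts[len > minLength & nEx >= minExons]
}

#' Coding-potential consensus filter
#'
#' Integrates noncoding/coding calls of four prediction tools: with rule
#' \code{"all"} a transcript is kept only when all four tools call it
#' noncoding, with \code{"majority"} when at least three do.
#'
#' @param transcripts \code{GRangesList} of exons per transcript.
#' @param calls data.frame with a \code{transcript_id} column and four
#'   tool columns holding \code{"coding"}/\code{"noncoding"}.
#' @param rule consensus rule, \code{"all"} (default) or \code{"majority"}.
#' @return The noncoding subset.
#' @export
codingPotentialConsensus <- function(transcripts, calls,
                                     rule = c("all", "majority")) {
  rule <- match.arg(rule)
  ids <- names(transcripts)
  row <- match(ids, calls$transcript_id)
  toolCols <- setdiff(colnames(calls), "transcript_id")
  stopifnot2(length(toolCols) == 4L, "calls must have exactly 4 tool columns")
  callMat <- as.matrix(calls[row, toolCols])
  missing <- which(is.na(row) | is.na(callMat), arr.ind = TRUE)
  if (length(missing)) {
    bad <- if (is.matrix(missing)) missing[1, ] else c(missing[1], 1L)
    stop("missing coding-potential call for transcript ", ids[bad[1]],
         " (", toolCols[bad[2]], ")", call. = FALSE)
  }
  nNc <- rowSums(callMat == "noncoding")
  keep <- if (rule == "all") nNc == 4L else nNc >= 3L
  transcripts[keep]
}

#' Run the full novel-lncRNA detection pipeline
#'
#' Applies, in order: (1) assembler intersection, (2) removal of
#' transcripts with exonic overlap to any annotation set, (3) size and
#' exon-count filtering, (4) coding-potential consensus. Produces stage
#' counts and a complete per-transcript audit trail, attributing each
#' eliminated transcript to the first stage that removed it.
#'
#' @param setA,setB assembler outputs (\code{GRangesList}s of exons).
#' @param annotations list of annotated exon sets (possibly empty).
#' @param calls coding-potential call table (see
#'   [codingPotentialConsensus()]).
#' @param minLength,minExons,rule stage parameters.
#' @return list with \code{novel} (the surviving \code{GRangesList}),
#'   \code{report} (named stage counts: input_A, input_B, intersected,
#'   unannotated, size_exon_pass, novel_lncrna) and \code{audit}
#'   (data.frame: transcript_id, status, stage of elimination or
#'   \code{"kept"}).
#' @export
runLncPipeline <- function(setA, setB, annotations, calls,
                           minLength = 200L, minExons = 2L,
                           rule = c("all", "majority")) {
  rule <- match.arg(rule)
  s1 <- intersectAssemblies(setA, setB)
  s2 <- removeAnnotatedOverlaps(s1, annotations)
  s3 <- sizeExonFilter(s2, minLength = minLength, minExons = minExons)
  s4 <- codingPotentialConsensus(s3, calls, rule = rule)

  ids <- union(names(setA), names(setB))
  stage <- rep("kept", length(ids))
  names(stage) <- ids
  stage[!(ids %in% names(s1))] <- "intersection"
  el2 <- setdiff(names(s1), names(s2))
  stage[el2] <- "annotation_overlap"
  el3 <- setdiff(names(s2), names(s3))
  stage[el3] <- "size_exon"
  el4 <- setdiff(names(s3), names(s4))
  stage[el4] <- "coding_potential"
  audit <- data.frame(transcript_id = ids,
                      status = ifelse(stage == "kept", "kept", "eliminated"),
                      stage = unname(stage), stringsAsFactors = FALSE)

  report <- c(input_A = length(setA), input_B = length(setB),
              intersected = length(s1), unannotated = length(s2),
              size_exon_pass = length(s3), novel_lncrna = length(s4))
  list(novel = s4, report = report, audit = audit)
}
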