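#' Label assembled transcripts by reference recovery
#'
#' An assembled transcript is matched to the reference transcript with
#' which it shares the most exonic bases; it is labeled \code{good} when
#' that overlap covers at least \code{minRecovery} of the reference exonic
#' length (the annotation is the denominator), otherwise \code{bad}.
#' Transcripts without any reference overlap are labeled \code{bad}.
#'
#' @param assembled,reference \code{GRangesList}s of exons per transcript.
#' @param coverage named numeric vector of read coverages (reads per base)
#'   for the assembled transcripts.
#' @param referenceCategory named character vector mapping reference
#'   transcript ids to \code{"coding"} or \code{"noncoding"}.
#' @param minRecovery recovery fraction calling a transcript good
#'   (boundary inclusive).
#' @return data.frame with columns \code{transcript_id}, \code{coverage},
#'   \code{label}, \code{category}, \code{recovery}, \code{best_reference}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000)))
#' labelByRecovery(ex, ex, coverage = c(t1 = 5),
#'                 referenceCategory = c(t1 = "coding"))
#' @export
labelByRecovery <- function(assembled, reference, coverage,
                            referenceCategory, minRecovery = 0.75) {
  refLen <- sum(IRanges::width(IRanges::reduce(reference)))
  asmRed <- IRanges::reduce(assembled)
  hits <- findOverlaps(asmRed, IRanges::reduce(reference),
                       ignore.strand = TRUE)
  # overlap bases per (assembled, reference) pair
  n <- length(assembled)
  recovery <- numeric(n)
  bestRef <- rep(NA_character_, n)
  refIds <- names(reference)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ovBases <- vapply(seq_along(qh), function(k) {
      sum(IRanges::width(GenomicRanges::intersect(
        asmRed[[qh[k]]], IRanges::reduce(reference[[sh[k]]]),
        ignore.strand = TRUE)))
    }, 0)
    for (i in unique(qh)) {
      sel <- which(qh == i)
      best <- sel[which.max(ovBases[sel])]
      recovery[i] <- ovBases[best] / refLen[sh[best]]
      bestRef[i] <- refIds[sh[best]]
    }
  }
  ids <- names(assembled)
  noHit <- is.na(bestRef)
  if (any(noHit))
    message(sum(noHit), " assembled transcript(s) had no reference overlap; labeled bad")
  data.frame(
    transcript_id = ids,
    coverage = unname(coverage[ids]),
    label = ifelse(!noHit & recovery >= minRecovery, "good", "bad"),
    category = ifelse(noHit, NA_character_,
                      unname(referenceCategory[bestRef])),
    recovery = recovery,
    best_reference = bestRef,
    stringsAsFactors = FALSE)
}

#' Empirical ROC curve over coverage thresholds
#'
#' Candidate thresholds are the sorted unique observed coverages plus one
#' sentinel below the minimum, under the decision rule "predict good if
#' coverage >= t". Sensitivity at t is the fraction of good transcripts
#' with coverage >= t; specificity is the fraction of bad transcripts with
#' coverage strictly below t.
#'
#' @param coverage numeric vector of read coverages.
#' @param label character vector, \code{"good"}/\code{"bad"}, aligned with
#'   \code{coverage}.
#' @return data.frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}.
#' @examples
#' rocCurve(c(10, 12, 1, 2), c("good", "good", "bad", "bad"))
#' @export
rocCurve <- function(coverage, label) {
  stopifnot2(length(coverage) == length(label),
             "coverage and label must align")
  stopifnot2(all(coverage >= 0), "coverage must be >= 0")
  good <- coverage[label == "good"]
  bad <- coverage[label == "bad"]
  if (!length(good) || !length(bad))
    stop("degenerate ROC: need at least one good and one bad transcript",
         call. = FALSE)
  u <- sort(unique(coverage))
  sentinel <- if (u[1] > 0) u[1] / 2 else -1
  thr <- c(sentinel, u)
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(good >= t), 0),
    specificity = vapply(thr, function(t) mean(bad < t), 0))
}

#' Optimal coverage threshold from a ROC curve
#'
#' Picks the threshold minimizing the squared Euclidean distance to the
#' perfect classifier corner,
#' (1 - sensitivity)^2 + (1 - specificity)^2. Ties are broken toward the
#' smallest (most permissive) threshold.
#'
#' @param roc data.frame from [rocCurve()].
#' @return list with \code{i_star} (index into the candidate set),
#'   \code{t_star} (the optimal threshold) and \code{distance2} (the
#'   minimized squared distance).
#' @examples
#' optimalThreshold(rocCurve(c(10, 12, 1, 2), c("good", "good", "bad", "bad")))
#' @export
optimalThreshold <- function(roc) {
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  iStar <- which.min(d2)   # first minimum = smallest threshold
  list(i_star = iStar, t_star = roc$threshold[iStar], distance2 = d2[iStar])
}

#' Combined coverage threshold over coding and noncoding transcripts
#'
#' Computes the category-wise optimal thresholds and returns their
#' arithmetic mean, emulating the practice of averaging the optima derived
#' from coding and noncoding reference transcripts.
#'
#' @param labeled data.frame with columns \code{coverage}, \code{label}
#'   and \code{category} (\code{"coding"}/\code{"noncoding"}), e.g. from
#'   [labelByRecovery()] or a simulated coverage table.
#' @return list with \code{t_coding}, \code{t_noncoding},
#'   \code{t_combined} and the two per-category [optimalThreshold()]
#'   results.
#' @export
combinedThreshold <- function(labeled) {
  res <- lapply(c("coding", "noncoding"), function(cat) {
    sub <- labeled[!is.na(labeled$category) & labeled$category == cat, ]
    if (!nrow(sub))
      stop("no transcripts in category ", cat, call. = FALSE)
    optimalThreshold(rocCurve(sub$coverage, sub$label))
  })
  names(res) <- c("coding", "noncoding")
  list(t_coding = res$coding$t_star,
       t_noncoding = res$noncoding$t_star,
       t_combined = (res$coding$t_star + res$noncoding$t_star) / 2,
       coding = res$coding, noncoding = res$noncoding)
}
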