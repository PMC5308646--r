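# Entropy / Jensen-Shannon temporal-specificity scoring and the
# lncRNA-vs-coding class comparison statistics.

#' Pool cells into per-stage expression profiles
#'
#' @param se \code{SummarizedExperiment} with assay \code{"fpkm"} and a
#'   \code{stage} column in \code{colData}.
#' @param fun pooling statistic across the cells of a stage
#'   (\code{"mean"}, the default, or \code{"median"}).
#' @return genes x stages matrix of pooled FPKM.
#' @export
poolStages <- function(se, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  stage <- colData(se)$stage
  stopifnot2(!any(is.na(stage)), "every cell needs a stage label")
  lv <- levels(stage)
  if (any(table(stage)[lv] == 0) || any(!lv %in% stage))
    stop("stage with zero cells", call. = FALSE)
  m <- assay(se, "fpkm")
  out <- vapply(lv, function(s) f(m[, stage == s, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(NULL, lv))
  rownames(out) <- rownames(m)
  out
}

#' Normalize a stage expression vector to a density
#'
#' Each raw FPKM entry v_i is transformed to log10(v_i + 1) and the vector
#' is rescaled to sum to one. An all-zero vector cannot be normalized and
#' is flagged unexpressed (a row of \code{NA}) rather than raising an
#' error.
#'
#' @param V numeric vector of raw stage FPKM, or a genes x stages matrix.
#' @return A density vector summing to 1 (or a matrix of row densities);
#'   unexpressed rows are all-\code{NA}.
#' @examples
#' normalizeDensity(c(9, 99))   # log10 terms 1 and 2 -> (1/3, 2/3)
#' @export
normalizeDensity <- function(V) {
  if (is.matrix(V)) {
    lg <- log10p1(V)
    tot <- rowSums(lg)
    out <- lg / tot
    out[tot == 0, ] <- NA_real_
    return(out)
  }
  stopifnot2(all(V >= 0), "expression must be >= 0")
  lg <- log10p1(V)
  if (sum(lg) == 0) return(rep(NA_real_, length(V)))
  lg / sum(lg)
}

#' Shannon entropy of a discrete density (bits)
#'
#' @param p density vector (non-negative, summing to 1); the convention
#'   0 * log(0) = 0 applies.
#' @param base logarithm base (2, the default, measures in bits and bounds
#'   the Jensen-Shannon divergence by 1).
#' @return Entropy H(p) = -sum p_i log(p_i).
#' @examples
#' shannonEntropy(c(0.5, 0.5))   # 1 bit
#' @export
shannonEntropy <- function(p, base = 2) {
  stopifnot2(all(p >= 0), "density entries must be >= 0")
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Jensen-Shannon distance between two densities
#'
#' The Jensen-Shannon divergence
#' H((p + q)/2) - (H(p) + H(q))/2 computed with base-2 entropies lies in
#' [0, 1]; its square root is a metric and is returned by default. Set
#' \code{sqrt = FALSE} for the raw divergence.
#'
#' @param p,q density vectors of equal length.
#' @param sqrt return the metric (square-root) form (default TRUE).
#' @return Distance in [0, 1].
#' @examples
#' jsDistance(c(1, 0), c(0, 1))   # maximal: 1
#' @export
jsDistance <- function(p, q, sqrt = TRUE) {
  stopifnot2(length(p) == length(q), "density lengths differ")
  d <- shannonEntropy((p + q) / 2) -
    (shannonEntropy(p) + shannonEntropy(q)) / 2
  d <- max(0, d)   # clamp tiny negative rounding
  if (sqrt) base::sqrt(d) else d
}

#' Temporal specificity scores of stage expression profiles
#'
#' For each gene, the score against stage s is
#' 1 - JSdist(e, e^s) where e is the gene's normalized stage density and
#' e^s the point-mass pattern of exclusive expression in stage s. The
#' reported score is the maximum over stages; the argmax stage (earliest
#' stage on ties) localizes the specificity. A gene is called temporally
#' specific when its maximal score exceeds \code{cutoff}.
#'
#' @param profiles genes x stages density matrix from
#'   [normalizeDensity()] (unexpressed rows all-\code{NA} are excluded).
#' @param cutoff specificity call threshold (default 0.5).
#' @param sqrt use the metric form of the Jensen-Shannon distance
#'   (default TRUE; FALSE uses the raw divergence).
#' @return data.frame with \code{gene_id}, one \code{js_<stage>} column
#'   per stage, \code{max_score}, \code{argmax_stage} and
#'   \code{is_specific}.
#' @examples
#' pr <- rbind(point = c(1, 0, 0), unif = rep(1/3, 3))
#' specificityScore(pr)
#' @export
specificityScore <- function(profiles, cutoff = 0.5, sqrt = TRUE) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  expressed <- !apply(is.na(profiles), 1, any)
  pr <- profiles[expressed, , drop = FALSE]
  nS <- ncol(pr)
  stages <- colnames(profiles)
  if (is.null(stages)) stages <- paste0("s", seq_len(nS))
  scores <- matrix(NA_real_, nrow(pr), nS)
  for (s in seq_len(nS)) {
    es <- numeric(nS); es[s] <- 1
    scores[, s] <- 1 - apply(pr, 1, jsDistance, q = es, sqrt = sqrt)
  }
  maxScore <- apply(scores, 1, max)
  argmax <- apply(scores, 1, which.max)   # earliest stage on ties
  out <- data.frame(gene_id = rownames(pr), scores,
                    max_score = maxScore,
                    argmax_stage = stages[argmax],
                    is_specific = maxScore > cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[1 + seq_len(nS)] <- paste0("js_", stages)
  out
}

#' Compare specificity between lncRNAs and coding genes
#'
#' Two-sided Kolmogorov-Smirnov test on the maximal-score distributions
#' and a two-sided Fisher exact test on the 2x2 table of
#' specific/non-specific by class.
#'
#' @param lncScores,codingScores [specificityScore()] outputs (or numeric
#'   vectors of maximal scores).
#' @param cutoff specificity cutoff for the contingency table.
#' @return list with the per-class specific fractions, the 2x2 table, and
#'   the KS and Fisher test results.
#' @export
compareSpecificity <- function(lncScores, codingScores, cutoff = 0.5) {
  getMax <- function(x) if (is.data.frame(x)) x$max_score else x
  l <- getMax(lncScores); c_ <- getMax(codingScores)
  stopifnot2(length(l) > 0 && length(c_) > 0, "both classes must be non-empty")
  ks <- suppressWarnings(stats::ks.test(l, c_))
  tab <- rbind(lncRNA = c(specific = sum(l > cutoff), other = sum(l <= cutoff)),
               coding = c(specific = sum(c_ > cutoff), other = sum(c_ <= cutoff)))
  fi <- stats::fisher.test(tab)
  list(frac_specific_lnc = mean(l > cutoff),
       frac_specific_coding = mean(c_ > cutoff),
       table = tab,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       fisher_odds_ratio = unname(fi$estimate), fisher_p = fi$p.value)
}

#' Sample-pair Spearman correlations per gene class
#'
#' For every unordered pair of cells, the Spearman rank correlation over
#' the genes of each class; the two resulting correlation distributions
#' are compared with a two-sided Mann-Whitney U test. Pairs with a
#' constant expression column in a class are dropped (with a message) for
#' that class.
#'
#' @param se \code{SummarizedExperiment} with assay \code{"fpkm"}.
#' @param isLnc logical vector over genes (TRUE = lncRNA class).
#' @return list with \code{rho_lnc}, \code{rho_coding} (per-pair
#'   correlations), and the Mann-Whitney statistic and p-value.
#' @export
samplePairSpearman <- function(se, isLnc) {
  m <- assay(se, "fpkm")
  stopifnot2(ncol(m) >= 2, "need at least two samples")
  stopifnot2(sum(isLnc) >= 3 && sum(!isLnc) >= 3,
             "need at least 3 genes per class")
  pairRho <- function(sub) {
    rc <- suppressWarnings(stats::cor(sub, method = "spearman"))
    r <- rc[upper.tri(rc)]
    if (anyNA(r)) {
      message(sum(is.na(r)), " sample pair(s) with constant column dropped")
      r <- r[!is.na(r)]
    }
    r
  }
  rl <- pairRho(m[isLnc, , drop = FALSE])
  rc <- pairRho(m[!isLnc, , drop = FALSE])
  mw <- suppressWarnings(stats::wilcox.test(rl, rc))
  list(rho_lnc = rl, rho_coding = rc,
       mw_statistic = unname(mw$statistic), mw_p = mw$p.value)
}

#' Maximal expression per gene and class comparison
#'
#' Per-gene maximum of log10(FPKM + 1) over all cells, compared between
#' classes with a two-sided Kolmogorov-Smirnov test.
#'
#' @param se \code{SummarizedExperiment} with assay \code{"fpkm"}.
#' @param isLnc logical vector over genes.
#' @return list with \code{max_lnc}, \code{max_coding} and the KS result.
#' @export
maxExpressionDistribution <- function(se, isLnc) {
  mx <- apply(log10p1(assay(se, "fpkm")), 1, max)
  ks <- suppressWarnings(stats::ks.test(mx[isLnc], mx[!isLnc]))
  list(max_lnc = mx[isLnc], max_coding = mx[!isLnc],
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}
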