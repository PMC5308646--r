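# cis neighbor-gene analysis: neighbor pair discovery, orientation
# classification, expression correlation against a random coding-pair
# null, and the per-module neighbor-fraction test.

#' Find neighboring gene pairs
#'
#' Two genes are neighbors when they lie on the same chromosome and the
#' distance between their gene bodies, gap = max(0, later.start -
#' earlier.end), is strictly below \code{maxGap}; overlapping bodies (gap
#' 0) count as neighbors. Orientation is \code{divergent} when the genes
#' sit head-to-head on opposite strands (leftmost gene on minus),
#' \code{convergent} when tail-to-tail (leftmost on plus), and
#' \code{unidirectional} on the same strand. The pair class is derived
#' from the biotypes (\code{lnc_coding}, \code{coding_coding},
#' \code{lnc_lnc}).
#'
#' @param genes \code{GRanges} of gene bodies with \code{gene_id} and
#'   \code{biotype} metadata columns and defined strands.
#' @param maxGap maximum gap in bp (exclusive; default 10000).
#' @return data.frame with \code{gene_a}, \code{gene_b} (a before b by
#'   position), \code{gap_bp}, \code{orientation}, \code{pair_class}.
#' @export
findNeighbors <- function(genes, maxGap = 10000L) {
  noStrand <- as.character(strand(genes)) == "*"
  if (any(noStrand)) {
    message(sum(noStrand), " gene(s) without strand excluded")
    genes <- genes[!noStrand]
  }
  ord <- order(as.character(seqnames(genes)), start(genes), end(genes))
  genes <- genes[ord]
  hits <- findOverlaps(genes, maxgap = as.integer(maxGap),
                       ignore.strand = TRUE, drop.self = TRUE,
                       drop.redundant = TRUE)
  if (!length(hits))
    return(data.frame(gene_a = character(), gene_b = character(),
                      gap_bp = integer(), orientation = character(),
                      pair_class = character(), stringsAsFactors = FALSE))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  # orient so a is the earlier gene
  swap <- start(genes)[j] < start(genes)[i]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  gap <- pmax(0L, start(genes)[b] - end(genes)[a])
  keep <- gap < maxGap
  a <- a[keep]; b <- b[keep]; gap <- gap[keep]
  sa <- as.character(strand(genes))[a]
  sb <- as.character(strand(genes))[b]
  orientation <- ifelse(sa == sb, "unidirectional",
                        ifelse(sa == "-", "divergent", "convergent"))
  bt <- genes$biotype
  isLncA <- bt[a] == "lncRNA"; isLncB <- bt[b] == "lncRNA"
  pairClass <- ifelse(isLncA & isLncB, "lnc_lnc",
                      ifelse(!isLncA & !isLncB, "coding_coding",
                             "lnc_coding"))
  data.frame(gene_a = genes$gene_id[a], gene_b = genes$gene_id[b],
             gap_bp = as.integer(gap), orientation = orientation,
             pair_class = pairClass, stringsAsFactors = FALSE)
}

#' Correlate expression of gene pairs
#'
#' Pearson correlation between the density-normalized stage profiles of
#' the two genes of each pair, with a t-distribution p-value and a
#' significance flag at \code{pCutoff}. Pairs where either profile is
#' constant or unexpressed get \code{NA} correlation and are flagged
#' undefined (they stay in the output but should be excluded from
#' distribution summaries).
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b} (e.g. from
#'   [findNeighbors()]).
#' @param profiles genes x stages density matrix from
#'   [normalizeDensity()].
#' @param pCutoff significance threshold (default 0.05).
#' @return The input with added \code{pearson_r}, \code{p_value},
#'   \code{significant}, \code{defined} columns.
#' @export
pairCorrelation <- function(pairs, profiles, pCutoff = 0.05) {
  n <- ncol(profiles)
  r <- p <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- profiles[pairs$gene_a[k], ]
    y <- profiles[pairs$gene_b[k], ]
    if (anyNA(x) || anyNA(y) || stats::sd(x) == 0 || stats::sd(y) == 0)
      next
    r[k] <- stats::cor(x, y)
    p[k] <- corPValue(r[k], n)
  }
  pairs$pearson_r <- r
  pairs$p_value <- p
  pairs$significant <- !is.na(p) & p <= pCutoff
  pairs$defined <- !is.na(r)
  pairs
}

#' Sample random coding-coding gene pairs
#'
#' Draws \code{n} distinct unordered pairs of protein-coding genes,
#' excluding any pair that is a true neighbor pair, to serve as the null
#' distribution for neighbor-pair correlations. When fewer distinct pairs
#' exist than requested, all of them are returned with a warning.
#'
#' @param genes \code{GRanges} of gene bodies with \code{gene_id} and
#'   \code{biotype} columns.
#' @param n number of pairs (default 10000).
#' @param seed integer seed (draws do not disturb the caller's RNG).
#' @param excludeNeighbors data.frame of pairs to exclude (e.g.
#'   [findNeighbors()] output); optional.
#' @return data.frame with \code{gene_a}, \code{gene_b}.
#' @export
randomCodingPairs <- function(genes, n = 10000L, seed = 1L,
                              excludeNeighbors = NULL) {
  coding <- genes$gene_id[genes$biotype == "coding"]
  stopifnot2(length(coding) >= 2, "need at least two coding genes")
  nc <- length(coding)
  nAll <- nc * (nc - 1) / 2
  banned <- character()
  if (!is.null(excludeNeighbors) && nrow(excludeNeighbors))
    banned <- paste(pmin(excludeNeighbors$gene_a, excludeNeighbors$gene_b),
                    pmax(excludeNeighbors$gene_a, excludeNeighbors$gene_b))
  withSeed(seed, {
    if (n >= nAll) {
      if (n > nAll) warning("requested ", n, " pairs but only ", nAll,
                            " exist; returning all")
      idx <- utils::combn(nc, 2)
      df <- data.frame(gene_a = coding[idx[1, ]], gene_b = coding[idx[2, ]],
                       stringsAsFactors = FALSE)
    } else {
      seen <- character(); ga <- character(); gb <- character()
      while (length(ga) < n) {
        need <- n - length(ga)
        i <- sample.int(nc, 2 * need, replace = TRUE)
        j <- sample.int(nc, 2 * need, replace = TRUE)
        ok <- i != j
        lo <- pmin(i, j)[ok]; hi <- pmax(i, j)[ok]
        key <- paste(coding[lo], coding[hi])
        new <- !(key %in% seen) & !duplicated(key) & !(key %in% banned)
        seen <- c(seen, key[new])
        ga <- c(ga, coding[lo][new]); gb <- c(gb, coding[hi][new])
      }
      df <- data.frame(gene_a = ga[seq_len(n)], gene_b = gb[seq_len(n)],
                       stringsAsFactors = FALSE)
    }
    key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
    df[!(key %in% banned), , drop = FALSE]
  })
}

# Cohen's d with pooled SD
.cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare neighbor-pair correlations with a null pair set
#'
#' Two-sided Welch t-test and Kolmogorov-Smirnov test between the
#' correlation distributions of lncRNA-coding neighbor pairs and random
#' coding-coding pairs, with Cohen's d (pooled SD) as effect size;
#' computed overall and within the divergent and unidirectional strata.
#'
#' @param lncPairs,nullPairs [pairCorrelation()] outputs; rows with
#'   undefined correlation are dropped.
#' @return list with overall statistics (\code{mean_lnc},
#'   \code{mean_null}, \code{t_p}, \code{ks_p}, \code{cohens_d}) and a
#'   \code{strata} list keyed by orientation.
#' @export
comparePairClasses <- function(lncPairs, nullPairs) {
  rl <- lncPairs$pearson_r[lncPairs$defined]
  rn <- nullPairs$pearson_r[nullPairs$defined]
  stopifnot2(length(rl) >= 3 && length(rn) >= 3,
             "need >= 3 defined correlations per class")
  one <- function(x, y) {
    tt <- stats::t.test(x, y)
    ks <- suppressWarnings(stats::ks.test(x, y))
    list(mean_lnc = mean(x), mean_null = mean(y),
         t_statistic = unname(tt$statistic), t_p = tt$p.value,
         ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         cohens_d = .cohensD(x, y), n_lnc = length(x), n_null = length(y))
  }
  out <- one(rl, rn)
  strata <- list()
  for (ori in c("divergent", "unidirectional")) {
    rs <- lncPairs$pearson_r[lncPairs$defined & lncPairs$orientation == ori]
    if (length(rs) >= 3) strata[[ori]] <- one(rs, rn)
    else message("stratum ", ori, " skipped (fewer than 3 pairs)")
  }
  out$strata <- strata
  out
}

#' Summary statistics of per-module neighbor percentages
#'
#' Given the percentage of coding genes per module that neighbor an
#' lncRNA, reports mean, SD, and the two equivalent t-tests: one-sample
#' against 50 and paired on (neighbor, 100 - neighbor). They coincide
#' because each module's two percentages sum to 100.
#'
#' @param pct numeric vector of per-module neighbor percentages.
#' @return list with \code{mean}, \code{sd}, \code{t_statistic},
#'   \code{p_value}, \code{t_paired}, \code{p_paired}.
#' @examples
#' neighborFractionSummary(c(56.23, 59.46, 54.13, 55.20, 52.81, 63.21,
#'                           57.43, 47.37, 56.57))
#' @export
neighborFractionSummary <- function(pct) {
  stopifnot2(length(pct) >= 2, "need at least two modules")
  if (stats::sd(pct) == 0)
    return(list(mean = mean(pct), sd = 0, t_statistic = NA_real_,
                p_value = NA_real_, t_paired = NA_real_,
                p_paired = NA_real_))
  tt <- stats::t.test(pct, mu = 50)
  tp <- stats::t.test(pct, 100 - pct, paired = TRUE)
  list(mean = mean(pct), sd = stats::sd(pct),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       t_paired = unname(tp$statistic), p_paired = tp$p.value)
}

#' Per-module neighbor-fraction test
#'
#' For each module, the percentage of its coding genes that are neighbors
#' of at least one lncRNA versus those that are not (the two percentages
#' sum to 100). Because of that constraint, the paired t-test on
#' (neighbor - non-neighbor) differences is identical to the one-sample t
#' of the neighbor percentages against 50; both are reported.
#'
#' @param modules named list, module label to character vector of gene
#'   ids.
#' @param neighborFlag named logical vector over coding genes, TRUE when
#'   the gene has at least one lncRNA within the neighbor gap.
#' @return list with \code{table} (per-module percentages), \code{mean},
#'   \code{sd}, \code{t_statistic}, \code{p_value} and the paired-test
#'   duplicates \code{t_paired}, \code{p_paired}.
#' @examples
#' neighborFractionTest(
#'   modules = list(m1 = c("g1", "g2"), m2 = c("g3", "g4")),
#'   neighborFlag = c(g1 = TRUE, g2 = TRUE, g3 = TRUE, g4 = FALSE))
#' @export
neighborFractionTest <- function(modules, neighborFlag) {
  pct <- vapply(names(modules), function(m) {
    g <- intersect(modules[[m]], names(neighborFlag))
    if (!length(g)) return(NA_real_)
    100 * mean(neighborFlag[g])
  }, 0)
  if (anyNA(pct)) {
    warning(sum(is.na(pct)), " module(s) without coding genes excluded")
    pct <- pct[!is.na(pct)]
  }
  stopifnot2(length(pct) >= 2, "need at least two modules")
  tab <- data.frame(module = names(pct), pct_neighbor_coding = unname(pct),
                    pct_non_neighbor_coding = 100 - unname(pct),
                    stringsAsFactors = FALSE)
  if (stats::sd(pct) == 0)
    warning("all modules have identical percentages; t undefined")
  c(list(table = tab), neighborFractionSummary(unname(pct)))
}
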