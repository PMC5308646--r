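# Signed weighted co-expression network: stage-specific gene selection,
# soft-threshold choice, adjacency and topological overlap.

#' Stage-specific genes by consecutive-stage differential expression
#'
#' For every pair of consecutive developmental stages, a per-gene
#' differential test on log10(FPKM + 1) with Benjamini-Hochberg correction
#' across genes within each pair; the log2 fold change uses a +1
#' pseudocount on the stage mean FPKM. A gene is stage-specific when some
#' consecutive pair has q < \code{qCutoff} and |log2 FC| >
#' \code{lfcCutoff}. The default engine is the limma moderated t
#' (variance shrinkage matters at the 3-cell early stages); a plain Welch
#' t-test is available via \code{method = "welch"}.
#'
#' @param se \code{SummarizedExperiment} with assay \code{"fpkm"} and a
#'   \code{stage} factor in \code{colData}.
#' @param lfcCutoff log2 fold-change cutoff (default 1).
#' @param qCutoff BH-adjusted p cutoff (default 0.01).
#' @param method test engine, \code{"limma"} (default) or \code{"welch"}.
#' @return list with \code{results} (data.frame: gene_id, stage_pair,
#'   log2_fc, p_value, q_value) and \code{specific} (character vector of
#'   stage-specific gene ids).
#' @export
stageSpecificGenes <- function(se, lfcCutoff = 1, qCutoff = 0.01,
                               method = c("limma", "welch")) {
  method <- match.arg(method)
  m <- log10p1(assay(se, "fpkm"))
  fpkm <- assay(se, "fpkm")
  stage <- colData(se)$stage
  lv <- levels(stage)
  usable <- table(stage)[lv] >= 2
  for (k in seq_len(length(lv) - 1L))
    if (!usable[k] || !usable[k + 1L])
      warning("stage pair ", lv[k], " -> ", lv[k + 1L],
              " skipped: fewer than 2 cells in a stage")

  pMat <- NULL
  if (method == "limma") {
    safe <- make.names(lv)
    design <- stats::model.matrix(~ 0 + stage)
    colnames(design) <- safe
    fit <- limma::lmFit(m[, !is.na(stage), drop = FALSE], design)
    cons <- vapply(seq_len(length(lv) - 1L), function(k)
      paste0(safe[k + 1L], "-", safe[k]), "")
    cm <- limma::makeContrasts(contrasts = cons, levels = design)
    fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
    pMat <- fit2$p.value
  }

  res <- list()
  for (k in seq_len(length(lv) - 1L)) {
    if (!usable[k] || !usable[k + 1L]) next
    s1 <- lv[k]; s2 <- lv[k + 1L]
    i1 <- stage == s1; i2 <- stage == s2
    p <- if (method == "limma") pMat[, k] else
      vapply(seq_len(nrow(m)), function(g) {
        x <- m[g, i1]; y <- m[g, i2]
        if (stats::sd(x) == 0 && stats::sd(y) == 0)
          return(if (mean(x) == mean(y)) 1 else 0)
        tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      }, 0)
    lfc <- log2((rowMeans(fpkm[, i2, drop = FALSE]) + 1) /
                  (rowMeans(fpkm[, i1, drop = FALSE]) + 1))
    res[[k]] <- data.frame(gene_id = rownames(m),
                           stage_pair = paste(s1, s2, sep = "->"),
                           log2_fc = unname(lfc), p_value = unname(p),
                           q_value = stats::p.adjust(p, method = "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  hit <- !is.na(res$q_value) & res$q_value < qCutoff &
    abs(res$log2_fc) > lfcCutoff
  list(results = res, specific = unique(res$gene_id[hit]))
}

# signed adjacency from a correlation matrix
.signedAdjacency <- function(corMat, beta) {
  a <- ((1 + corMat) / 2)^beta
  diag(a) <- 1
  a
}

# scale-free topology fit R^2 for a connectivity vector
.scaleFreeR2 <- function(k, nBins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(log10(km[ok]), log10(pk[ok]))^2
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, the signed adjacency is formed, connectivity
#' k_i = sum_{j != i} a_ij computed, and the scale-free topology fit
#' measured as the squared correlation of log10 p(k) against log10 k over
#' connectivity bins. Returns the smallest power reaching
#' \code{r2Target}; when none does, the best-fitting power with a
#' warning.
#'
#' @param corMat gene x gene Pearson correlation matrix.
#' @param candidates candidate powers (default 1:20).
#' @param r2Target scale-free fit target (default 0.9).
#' @param beta optional override; returned unchanged when supplied.
#' @return list with \code{beta} and \code{fit} (data.frame of power,
#'   r_squared).
#' @export
pickSoftThreshold <- function(corMat, candidates = 1:20, r2Target = 0.9,
                              beta = NULL) {
  if (!is.null(beta))
    return(list(beta = beta, fit = data.frame(power = beta,
                                              r_squared = NA_real_)))
  r2 <- vapply(candidates, function(b) {
    a <- .signedAdjacency(corMat, b)
    k <- rowSums(a) - 1
    .scaleFreeR2(k)
  }, 0)
  fit <- data.frame(power = candidates, r_squared = r2)
  ok <- which(!is.na(r2) & r2 >= r2Target)
  if (length(ok)) return(list(beta = candidates[min(ok)], fit = fit))
  if (all(is.na(r2))) {
    warning("scale-free fit undefined for all powers; using the smallest candidate")
    return(list(beta = candidates[1], fit = fit))
  }
  warning("no power reaches R^2 >= ", r2Target,
          "; using the best-fitting power")
  list(beta = candidates[which.max(r2)], fit = fit)
}

#' Build a signed weighted co-expression network
#'
#' Pearson correlations across samples, signed adjacency
#' a_ij = ((1 + cor_ij)/2)^beta, and the topological overlap matrix
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu, which
#' dampens noise and spurious pairwise associations by rewarding shared
#' neighborhoods.
#'
#' @param exprMat genes x samples matrix of expression values (the
#'   network is built on whatever scale is supplied; log10(FPKM + 1) is
#'   conventional).
#' @param beta soft-thresholding power (default 5).
#' @return A [CoexpressionNetwork-class] object.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 6, 10,
#'             dimnames = list(paste0("g", 1:6), NULL))
#' buildNetwork(m, beta = 5)
#' @export
buildNetwork <- function(exprMat, beta = 5) {
  stopifnot2(nrow(exprMat) >= 3 && ncol(exprMat) >= 3,
             "need at least 3 genes and 3 samples")
  sds <- apply(exprMat, 1, stats::sd)
  if (any(sds == 0))
    stop("constant expression rows: ",
         paste(rownames(exprMat)[sds == 0], collapse = ", "),
         call. = FALSE)
  corMat <- stats::cor(t(exprMat))
  a <- .signedAdjacency(corMat, beta)
  k <- rowSums(a) - 1
  # L_ij = (A %*% A)_ij - 2 a_ij  (removes u = i and u = j terms; a_ii = 1)
  L <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  new("CoexpressionNetwork", genes = rownames(exprMat), cor = corMat,
      beta = beta, adjacency = a, tom = tom)
}

#' Extract edges among hub genes
#'
#' Returns the topological-overlap edges among hub genes at or above a
#' weight cutoff; hubs with no retained connection are omitted from the
#' edge view.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param hubGenes character vector of hub gene ids.
#' @param weightCutoff minimum TOM weight (default 0.1, inclusive).
#' @return data.frame with \code{source}, \code{target}, \code{weight}.
#' @export
hubEdges <- function(network, hubGenes, weightCutoff = 0.1) {
  idx <- match(hubGenes, network@genes)
  stopifnot2(!anyNA(idx), "unknown hub gene id")
  tom <- network@tom[idx, idx, drop = FALSE]
  n <- length(idx)
  if (n < 2)
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  ut <- which(upper.tri(tom) & tom >= weightCutoff, arr.ind = TRUE)
  data.frame(source = hubGenes[ut[, 1]], target = hubGenes[ut[, 2]],
             weight = tom[ut], stringsAsFactors = FALSE)
}

#' Filter an RNA-RNA interaction table by normalized free energy
#'
#' Retains predicted lncRNA-mRNA interactions whose normalized binding
#' free energy (ndG) is at or below the cutoff (more negative = stronger
#' predicted binding); ndG <= -0.1 is the conventional interaction call.
#'
#' @param table data.frame with columns \code{lnc_id}, \code{gene_id},
#'   \code{ndG}.
#' @param cutoff ndG cutoff, inclusive (default -0.1).
#' @return The retained rows.
#' @export
filterInteractions <- function(table, cutoff = -0.1) {
  ndg <- suppressWarnings(as.numeric(table$ndG))
  bad <- which(is.na(ndg) & !is.na(table$ndG))
  if (length(bad))
    stop("non-numeric ndG at row ", bad[1], call. = FALSE)
  table[!is.na(ndg) & ndg <= cutoff, , drop = FALSE]
}
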