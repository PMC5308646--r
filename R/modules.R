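# Module detection on the topological overlap, eigengenes, merging,
# module-trait correlation, kME and hub identification.

# WGCNA-style color vocabulary for module labels, assigned by size
.moduleColors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue",
                   "saddlebrown", "steelblue", "paleturquoise", "violet")

# first principal component of the standardized module expression,
# rescaled to unit variance, sign fixed so own-module genes correlate
# positively on average
.eigengene <- function(exprMat) {
  z <- t(scale(t(exprMat)))
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  me <- me / stats::sd(me)
  if (mean(stats::cor(t(exprMat), me)) < 0) me <- -me
  me
}

.eigengeneMatrix <- function(exprMat, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  me <- vapply(mods, function(m)
    .eigengene(exprMat[names(assignment)[assignment == m], , drop = FALSE]),
    numeric(ncol(exprMat)))
  colnames(me) <- mods
  rownames(me) <- colnames(exprMat)
  me
}

# static height cut chosen by weighted modularity of the adjacency graph,
# keeping branches of at least minSize genes
.bestHeightCut <- function(hc, adjacency, minSize) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  qs <- stats::quantile(hc$height, probs = seq(0.05, 0.98, by = 0.03))
  best <- NULL; bestQ <- -Inf
  for (h in unique(qs)) {
    cl <- stats::cutree(hc, h = h)
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= minSize])
    if (!length(keep)) next
    # genes in small branches become singleton communities for scoring
    memb <- ifelse(cl %in% keep, match(cl, keep),
                   length(keep) + seq_along(cl))
    q <- igraph::modularity(g, membership = memb,
                            weights = igraph::E(g)$weight)
    if (q > bestQ) { bestQ <- q; best <- list(cl = cl, keep = keep) }
  }
  best
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' 1 - TOM, followed by a hybrid tree cut: a static height cut chosen to
#' maximize the weighted modularity of the adjacency graph among branches
#' of at least \code{minModuleSize} genes, then an iterated
#' module-membership refinement: every gene is reassigned to the module
#' of its highest kME when that kME is at least \code{kmeReassign}
#' (otherwise grey), with eigengenes recomputed between passes and
#' modules falling below the size minimum dissolved. Modules whose
#' eigengenes
#' correlate above \code{mergeCor} are merged iteratively until no such
#' pair remains. Modules are labeled from a fixed color vocabulary by
#' decreasing size; unassigned genes are \code{"grey"}.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param exprMat genes x samples expression matrix used for eigengenes
#'   (same genes as the network).
#' @param minModuleSize smallest admissible module (default 30).
#' @param mergeCor eigengene correlation above which modules merge
#'   (default 0.85).
#' @param kmeReassign minimum kME for rescuing an unassigned gene
#'   (default 0.3).
#' @return A [ModuleSet-class] object.
#' @export
detectModules <- function(network, exprMat, minModuleSize = 30L,
                          mergeCor = 0.85, kmeReassign = 0.3) {
  genes <- network@genes
  exprMat <- exprMat[genes, , drop = FALSE]
  dissTom <- 1 - network@tom
  hc <- stats::hclust(stats::as.dist(dissTom), method = "average")
  cut <- .bestHeightCut(hc, network@adjacency, minModuleSize)
  assignment <- rep("grey", length(genes))
  names(assignment) <- genes
  if (is.null(cut)) {
    warning("no branch reaches the minimum module size; all genes grey")
    return(new("ModuleSet", assignment = assignment,
               eigengenes = matrix(numeric(), ncol(exprMat), 0),
               kme = matrix(numeric(), length(genes), 0),
               traitCor = list(), hubs = list()))
  }
  for (k in seq_along(cut$keep))
    assignment[cut$cl == cut$keep[k]] <- paste0("mod", k)

  # hybrid refinement: every gene joins the module of its highest module
  # membership when that kME clears the threshold, otherwise grey; two
  # passes let the eigengenes stabilize on the refined membership
  for (iter in 1:2) {
    mods <- setdiff(unique(assignment), "grey")
    if (!length(mods)) break
    me <- .eigengeneMatrix(exprMat, assignment)
    kme <- stats::cor(t(exprMat), me)
    bi <- apply(kme, 1, which.max)
    bv <- kme[cbind(seq_len(nrow(kme)), bi)]
    assignment[] <- ifelse(bv >= kmeReassign, colnames(me)[bi], "grey")
    sizes <- table(assignment[assignment != "grey"])
    small <- names(sizes)[sizes < minModuleSize]
    if (length(small)) assignment[assignment %in% small] <- "grey"
  }
  if (!any(assignment != "grey")) {
    warning("hybrid refinement left all genes grey")
    return(new("ModuleSet", assignment = assignment,
               eigengenes = matrix(numeric(), ncol(exprMat), 0),
               kme = matrix(numeric(), length(genes), 0),
               traitCor = list(), hubs = list()))
  }

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2) break
    me <- .eigengeneMatrix(exprMat, assignment)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= mergeCor) break
    assignment[assignment == colnames(cc)[mx[2]]] <- colnames(cc)[mx[1]]
  }

  # relabel by decreasing size with the color vocabulary
  mods <- setdiff(unique(assignment), "grey")
  sizes <- sort(table(assignment[assignment != "grey"]), decreasing = TRUE)
  labels <- .moduleColors[seq_along(sizes)]
  names(labels) <- names(sizes)
  assignment[assignment != "grey"] <- labels[assignment[assignment != "grey"]]

  me <- if (length(mods)) .eigengeneMatrix(exprMat, assignment)
        else matrix(numeric(), ncol(exprMat), 0)
  kme <- if (ncol(me)) stats::cor(t(exprMat), me)
         else matrix(numeric(), length(genes), 0)
  new("ModuleSet", assignment = assignment, eigengenes = me, kme = kme,
      traitCor = list(), hubs = list())
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of every eigengene with every trait column, with
#' p-values from the Student t reference with n - 2 degrees of freedom,
#' and a "highly correlated" flag at r > \code{rFlag} and
#' p < \code{pFlag}. Stage indicator traits are typically one-hot columns
#' plus an ordinal time column (stage index).
#'
#' @param modules a [ModuleSet-class] with eigengenes.
#' @param traits per-sample numeric data.frame or matrix (rows aligned
#'   with the eigengene rows).
#' @param rFlag,pFlag flag thresholds (defaults 0.6 and 1e-4).
#' @return The input \code{modules} with \code{traitCor} filled: a list
#'   of matrices \code{r}, \code{p}, \code{flag}.
#' @export
moduleTrait <- function(modules, traits, rFlag = 0.6, pFlag = 1e-4) {
  me <- modules@eigengenes
  traits <- as.matrix(traits)
  keep <- apply(traits, 2, stats::sd) > 0
  if (!all(keep)) {
    message("zero-variance trait column(s) skipped: ",
            paste(colnames(traits)[!keep], collapse = ", "))
    traits <- traits[, keep, drop = FALSE]
  }
  n <- nrow(me)
  r <- stats::cor(me, traits)
  p <- corPValue(r, n)
  modules@traitCor <- list(r = r, p = p, flag = r > rFlag & p < pFlag)
  modules
}

#' Module membership (kME) and hub genes
#'
#' kME of gene i in module q is the Pearson correlation of the gene's
#' expression with the module eigengene. Hubs of a module are its own
#' genes with kME at or above \code{hubKme} and correlation p-value below
#' \code{pMax}. With small sample sizes very stringent p thresholds are
#' unattainable; the default does not constrain p.
#'
#' @param exprMat genes x samples expression matrix.
#' @param modules a [ModuleSet-class].
#' @param hubKme kME hub cutoff (default 0.9, inclusive).
#' @param pMax correlation p-value ceiling for hubs (default 1 = no
#'   constraint; the stringent convention is 1e-22 at large n).
#' @return The input \code{modules} with \code{kme} and \code{hubs}
#'   filled.
#' @export
kmeAndHubs <- function(exprMat, modules, hubKme = 0.9, pMax = 1) {
  me <- modules@eigengenes
  stopifnot2(ncol(me) > 0, "modules must carry eigengenes")
  exprMat <- exprMat[names(modules@assignment), , drop = FALSE]
  sds <- apply(exprMat, 1, stats::sd)
  ok <- sds > 0
  if (!all(ok))
    message(sum(!ok), " constant gene(s) excluded from kME")
  kme <- matrix(NA_real_, nrow(exprMat), ncol(me),
                dimnames = list(rownames(exprMat), colnames(me)))
  kme[ok, ] <- stats::cor(t(exprMat[ok, , drop = FALSE]), me)
  n <- ncol(exprMat)
  hubs <- lapply(colnames(me), function(q) {
    own <- names(modules@assignment)[modules@assignment == q]
    v <- kme[own, q]
    p <- corPValue(v, n)
    own[!is.na(v) & v >= hubKme & p < pMax]
  })
  names(hubs) <- colnames(me)
  modules@kme <- kme
  modules@hubs <- hubs
  modules
}

#' One-hot stage traits plus ordinal time
#'
#' Convenience builder of the trait table used for module-trait
#' correlation: one indicator column per stage and an ordinal
#' \code{time} column (stage index).
#'
#' @param se \code{SummarizedExperiment} with a \code{stage} factor.
#' @return samples x traits numeric matrix.
#' @export
stageTraits <- function(se) {
  stage <- colData(se)$stage
  lv <- levels(stage)
  m <- vapply(lv, function(s) as.numeric(stage == s), numeric(length(stage)))
  cbind(m, time = as.numeric(stage))
}
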