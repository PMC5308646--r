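# Cross-species module preservation and gene-set enrichment, both by
# upper-tail hypergeometric tests.

#' Map genes through an ortholog table
#'
#' Applies a strict one-to-one policy: rows whose gene appears more than
#' once in either column of the table (one-to-many or many-to-one
#' relations, including duplicate conflicting rows) are excluded, so the
#' retained map is a bijection on its domain.
#'
#' @param genes character vector in species-A identifier space.
#' @param orthologTable data.frame with two columns, species-A gene and
#'   species-B gene.
#' @return list with \code{mapped} (named character vector A -> B for the
#'   mappable input genes), \code{unmapped} (input genes without a
#'   one-to-one ortholog) and \code{n_dropped_rows} (table rows excluded
#'   by the policy).
#' @export
mapOrthologs <- function(genes, orthologTable) {
  a <- as.character(orthologTable[[1]])
  b <- as.character(orthologTable[[2]])
  dup <- duplicated(paste(a, b))      # exact duplicate rows collapse
  a <- a[!dup]; b <- b[!dup]
  multi <- a %in% a[duplicated(a)] | b %in% b[duplicated(b)]
  map <- b[!multi]
  names(map) <- a[!multi]
  hit <- genes %in% names(map)
  list(mapped = map[genes[hit]], unmapped = genes[!hit],
       n_dropped_rows = sum(multi) + sum(dup))
}

#' Hypergeometric module overlap between two module sets
#'
#' For every module pair (A from one species, B from the other, both
#' restricted to a shared ortholog-mapped universe), the overlap count and
#' the upper-tail hypergeometric probability
#' P(X >= |A intersect B|) with population size |universe|, |A| successes
#' and |B| draws. The test is symmetric in A and B.
#'
#' @param modulesA,modulesB named lists of gene id vectors (same
#'   identifier space).
#' @param universe character vector of genes eligible for both analyses.
#' @return data.frame with \code{module_a}, \code{module_b},
#'   \code{n_a}, \code{n_b}, \code{n_overlap}, \code{p},
#'   \code{neg_log10_p}.
#' @export
moduleOverlap <- function(modulesA, modulesB, universe) {
  universe <- unique(universe)
  N <- length(universe)
  stopifnot2(N > 0, "empty universe")
  mA <- lapply(modulesA, intersect, universe)
  mB <- lapply(modulesB, intersect, universe)
  grid <- expand.grid(module_a = names(mA), module_b = names(mB),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    A <- mA[[grid$module_a[i]]]; B <- mB[[grid$module_b[i]]]
    k <- length(intersect(A, B))
    p <- stats::phyper(k - 1, length(A), N - length(A), length(B),
                       lower.tail = FALSE)
    data.frame(module_a = grid$module_a[i], module_b = grid$module_b[i],
               n_a = length(A), n_b = length(B), n_overlap = k, p = p,
               neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test of each gene set against the module
#' within a universe; reported rows satisfy the overlap minimum and the
#' p cutoff on the raw p-value, with BH-adjusted q-values across all
#' tested terms added for reference.
#'
#' @param moduleGenes character vector of module gene ids.
#' @param universe character vector of background gene ids (superset of
#'   the module).
#' @param geneSets named list of gene id vectors (e.g. from
#'   [readGmt()]).
#' @param pCutoff raw p-value cutoff (default 0.05).
#' @param minCount minimum module-in-term overlap (default 5).
#' @return data.frame with \code{term}, \code{n_module_in_term},
#'   \code{n_universe_in_term}, \code{p}, \code{bh_q}, ordered by p.
#' @export
geneSetEnrichment <- function(moduleGenes, universe, geneSets,
                              pCutoff = 0.05, minCount = 5L) {
  universe <- unique(universe)
  moduleGenes <- intersect(moduleGenes, universe)
  N <- length(universe)
  n <- length(moduleGenes)
  rows <- lapply(names(geneSets), function(tm) {
    K <- length(intersect(geneSets[[tm]], universe))
    if (K == 0) return(NULL)   # term absent from universe
    k <- length(intersect(geneSets[[tm]], moduleGenes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_module_in_term = k, n_universe_in_term = K,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res))
    return(data.frame(term = character(), n_module_in_term = integer(),
                      n_universe_in_term = integer(), p = numeric(),
                      bh_q = numeric(), stringsAsFactors = FALSE))
  res$bh_q <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$n_module_in_term >= minCount & res$p <= pCutoff, ,
             drop = FALSE]
  res[order(res$p), , drop = FALSE]
}
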