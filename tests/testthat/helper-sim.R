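# Shared fixtures built in code. Simulations are cached per seed so the
# suite pays for each one once.

.simCache <- new.env(parent = emptyenv())

simFixture <- function(seed = 1L, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  cfg <- simConfig(seed = seed, ...)
  ann <- simulateAnnotation(cfg)
  se <- simulateExpression(ann, ann$truth, cfg)
  out <- list(cfg = cfg, ann = ann, truth = ann$truth, se = se)
  .simCache[[key]] <- out
  out
}

# Build a transcript (GRanges of exons) from exon (start, end) pairs.
tx <- function(..., chrom = "chr1", strand = "+") {
  ex <- rbind(...)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(ex[, 1], ex[, 2]),
                         strand = strand)
}

txSet <- function(...) GenomicRanges::GRangesList(...)

# A gene-body GRanges with ids and biotypes for neighbor tests.
geneSet <- function(starts, ends, strands, biotypes,
                    chrom = "chr1", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_along(starts))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strands, gene_id = ids,
                         biotype = biotypes)
}

# Random density vector of length n (for oracle-equivalence sweeps).
randomDensity <- function(n) {
  v <- stats::runif(n)
  v / sum(v)
}
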