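# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation calls do not perturb
# user-level randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# log10(FPKM + 1) transform used throughout.
log10p1 <- function(x) log10(x + 1)

# Pearson correlation p-value from the Student-t reference distribution
# with n - 2 degrees of freedom.
corPValue <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)   # keeps r's dim attributes
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

stopifnot2 <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
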