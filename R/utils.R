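# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# One-sided hypergeometric tail: P(X >= q) for q successes observed when
# drawing n from a genome of N containing K marked genes. Both the term
# overrepresentation and TF-target modules delegate to this.
hypergeom_tail <- function(q, K, N, n) {
  stats::phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
}

# Restore the caller's RNG stream after a seeded computation so generators
# are deterministic without clobbering the session seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
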