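# Seed plumbing for replicated simulation studies.
#
# Replicated studies need replicate k to be invariant to the total number of
# replicates, and the two members of a paired experiment to have independent
# death times while sharing one draw of strain effects. Both contracts are
# met by spawning a deterministic child seed per (replicate, stream) from the
# master seed, rather than consuming one global stream.

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash of a master seed and any number of integer
#' indices (replicate number, pair member, ...). Results lie in
#' `[0, 2^31 - 1]` and are invariant to how many other children are spawned.
#'
#' @param seed Master seed (single integer).
#' @param ... Integer indices identifying the child stream.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  # splitmix-style mixing in double arithmetic, kept exact below 2^53
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in idx) {
    s <- (s * 48271 + (as.double(k) + 1) * 30269) %% 2147483647
    s <- (s * 69621) %% 2147483647
  }
  as.integer(s %% 2147483648)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
# seed = NULL means: use the current global stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
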