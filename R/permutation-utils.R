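## Shared permutation-inference conventions.
##
## All permutation tests in the package use the same two rules:
##  * add-one correction, p = (1 + #extreme) / (nPerm + 1), so p is never 0;
##  * two-sidedness by doubling the smaller tail, capped at 1.

## Run expr with a temporary RNG state seeded by `seed` (NULL = use the
## current stream untouched).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## Two-sided permutation p-value with add-one correction, plus tails.
permPvalues <- function(obs, perm) {
  n <- length(perm)
  pG <- (1 + sum(perm >= obs)) / (n + 1)
  pL <- (1 + sum(perm <= obs)) / (n + 1)
  list(p = min(1, 2 * min(pG, pL)), pGreater = pG, pLess = pL)
}

## Stable 31-bit string hash (polynomial, base 31, mod 2^31 - 1); used to
## derive independent per-(direction, scope, test) seed substreams from the
## master seed so that results do not depend on execution order.
stringHash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (x in v) h <- (h * 31 + x) %% m
  h
}

substreamSeed <- function(masterSeed, ...) {
  key <- paste(..., sep = "|")
  as.integer((masterSeed + stringHash(key)) %% 2147483647)
}
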