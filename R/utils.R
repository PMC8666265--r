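#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so simulation helpers do not perturb
## the global stream.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Deterministic 31-bit string hash (iterated polynomial, mod 2^31 - 1).
## Used to derive independent child seeds from (master seed, condition, sim);
## guarantees that adding models or conditions never shifts another
## condition's random stream.
hash_seed <- function(...) {
  key <- paste(..., sep = "|")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Sample skewness (method-of-moments, b1).
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

stop_arg <- function(...) stop(..., call. = FALSE)
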