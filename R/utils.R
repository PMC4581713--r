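#' @useDynLib brcarisk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp runif quantile setNames uniroot binomial glm
#'   pchisq coef vcov qnorm sd pnorm
#' @importFrom graphics hist
NULL

# Number of days in the 10-year risk horizon used throughout.
DAYS_10Y <- 3652L
DAYS_PER_YEAR <- 365.25

#' Derive a reproducible substream seed from a master seed
#'
#' Every source of randomness in the package draws its seed from a master seed
#' through a named substream, so any intermediate object (a genotype replicate,
#' a fold assignment, a bootstrap) can be regenerated in isolation.  The
#' derivation is a fixed integer hash of the stream name mixed with the master
#' seed; it is stable across sessions and platforms.
#'
#' @param master integer master seed.
#' @param key character stream name, e.g. `"genotypes/rep7"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "cohort")
#' derive_seed(1L, "genotypes/rep1")
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds valid R integers
  h <- as.numeric(master) %% m
  for (cp in utf8ToInt(key)) {
    h <- (h * 131 + cp) %% m
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
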