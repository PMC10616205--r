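#' @import methods
#' @importFrom stats cor fisher.test glm median p.adjust pnorm prcomp pt
#'   quantile rbinom rlnorm rnbinom rpois runif sd setNames binomial predict
#'   hclust cutree as.dist complete.cases
#' @importFrom utils head read.delim read.table tail write.table combn
NULL

# Half-up rounding to `digits` decimals; base round() is banker's rounding,
# printed summary percentages require 0.05 -> 0.1.
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Vectorised reverse complement on plain character vectors.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Benjamini-Hochberg wrapper kept in one place (NA-safe).
bhAdjust <- function(p) p.adjust(p, method = "BH")

# sample() misbehaves on scalar x; these never do.
pickOne <- function(x) x[sample.int(length(x), 1L)]
shuffle <- function(x) x[sample.int(length(x))]
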