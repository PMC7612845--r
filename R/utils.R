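#' @import methods
#' @importFrom stats binom.test median p.adjust pchisq pnorm pwilcox qchisq
#'   qnorm quantile rbinom rlnorm rmultinom rnbinom runif uniroot glm coef
#'   binomial optimize setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a top-level seed and a label
#'
#' All stochastic steps in the package draw their randomness from one
#' top-level integer seed. Stage- or signature-specific seeds are derived
#' deterministically by hashing a label path into the seed, so that adding or
#' disabling one stage never perturbs the random stream of another.
#'
#' @param seed Integer top-level seed.
#' @param ... Character labels (coerced) identifying the consumer, e.g. a
#'   stage name and a signature name.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "score", "EryP")
#' @export
deriveSeed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- 0
  for (v in utf8ToInt(labels)) h <- (h * 31 + v) %% 2147483647
  s <- ((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647
  as.integer(max(1, s))
}

## run expr under a local RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.checkScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    .stopf("'%s' must be a single nonnegative integer", name)
  as.integer(x)
}
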