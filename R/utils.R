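#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm plogis predict qlogis qnorm rbinom residuals
#'   rmultinom rnorm runif setNames rlnorm fitted simulate
#' @importFrom graphics plot lines
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# logit/inverse-logit on (0,1); inputs are validated/clamped by callers
.logit <- function(p) qlogis(p)
.inv_logit <- function(x) plogis(x)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# set the RNG reproducibly when a seed is supplied; otherwise leave the
# caller's RNG stream alone
.seed_rng <- function(rng_seed) {
  if (!is.null(rng_seed)) {
    if (!.is_count(rng_seed)) .stopf("rng_seed must be a single non-negative integer")
    set.seed(as.integer(rng_seed))
  }
  invisible(NULL)
}

# deterministic fan-out of one global seed into per-stage seeds (kept < 2^31)
.stage_seed <- function(seed, stage) {
  stages <- c("screen", "competition", "qpcr", "filter", "utr", "assays")
  i <- match(stage, stages)
  if (is.na(i)) .stopf("unknown stage '%s'", stage)
  (as.integer(seed) + 7919L * i) %% .Machine$integer.max
}

# normalize a nucleotide string: uppercase, RNA U -> DNA T
.as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
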