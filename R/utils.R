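#' @importFrom data.table data.table as.data.table setDT setorder := .N .SD
#' @importFrom stats rbinom rpois rnorm runif quantile var sd cor approx dhyper
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "start", "end", "n_snps", "qual",
  "gt_parentA", "gt_parentB", "keep", "depth_high", "depth_low"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half-up to a fixed number of decimals
#'
#' Base R `round()` rounds half to even; genomic interval sizes are
#' conventionally reported with ordinary half-up rounding, which this
#' helper provides (a tiny epsilon guards against binary representation
#' of decimal ties).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# derive a deterministic per-operation seed from a base seed; keeps the
# result a valid 32-bit integer whatever small integer the caller passes
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

set_op_seed <- function(seed, offset) {
  s <- derive_seed(seed, offset)
  if (!is.null(s)) set.seed(s)
  invisible(s)
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
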