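#' SNP-index per bulk and their difference
#'
#' The SNP-index of a bulk is the fraction of its reads carrying the
#' focal (thick-parent) allele; `delta = high - low`, so values near +1
#' indicate thick-bulk fixation for thick-parent alleles and values
#' near -1 the converse.
#'
#' @param n_focal_high,n_other_high,n_focal_low,n_other_low read counts
#'   of the 2x2 allele-depth table (vectorized).
#' @return data.table: `snp_index_high`, `snp_index_low`,
#'   `delta_snp_index`.
#' @examples
#' snp_index(90, 10, 10, 90)   # 0.9, 0.1, 0.8
#' @export
snp_index <- function(n_focal_high, n_other_high, n_focal_low,
                      n_other_low) {
  th <- n_focal_high + n_other_high
  tl <- n_focal_low + n_other_low
  if (any(th == 0) || any(tl == 0))
    stopf("zero-depth bulk at %d site(s); filter on depth first",
          sum(th == 0 | tl == 0))
  hi <- n_focal_high / th
  lo <- n_focal_low / tl
  data.table(snp_index_high = hi, snp_index_low = lo,
             delta_snp_index = hi - lo)
}

#' Euclidean distance between bulk allele-frequency vectors
#'
#' With focal-allele frequencies `f` (high bulk) and `g` (low bulk), the
#' biallelic frequency vectors are `(f, 1-f)` and `(g, 1-g)`, so
#' `ed = sqrt(2) * |f - g|`. `ed_squared` is the usual plotting scale;
#' `signed_ed = sign(f - g) * ed` keeps the direction of divergence.
#'
#' @inheritParams snp_index
#' @return data.table: `ed`, `ed_squared`, `signed_ed`.
#' @export
euclidean_distance <- function(n_focal_high, n_other_high, n_focal_low,
                               n_other_low) {
  th <- n_focal_high + n_other_high
  tl <- n_focal_low + n_other_low
  if (any(th == 0) || any(tl == 0)) stopf("zero-depth bulk")
  f <- n_focal_high / th
  g <- n_focal_low / tl
  ed <- sqrt(2) * abs(f - g)
  data.table(ed = ed, ed_squared = ed^2, signed_ed = sign(f - g) * ed)
}

#' G statistic of the 2x2 allele-depth table
#'
#' The log-likelihood-ratio statistic
#' `G = 2 * sum n_ij * ln(n_ij / e_ij)` with expected counts
#' `e_ij = row_i * col_j / N` under independence of allele and bulk.
#' Zero cells contribute 0 (the `x ln x -> 0` limit); no continuity
#' correction is applied.
#'
#' @inheritParams snp_index
#' @return numeric vector of G values (>= 0).
#' @examples
#' g_statistic(90, 10, 10, 90)   # 147.226
#' @export
g_statistic <- function(n_focal_high, n_other_high, n_focal_low,
                        n_other_low) {
  n <- cbind(n_focal_high, n_other_high, n_focal_low, n_other_low)
  tot <- rowSums(n)
  if (any(tot == 0)) stopf("grand total 0 in %d table(s)", sum(tot == 0))
  r1 <- n[, 1L] + n[, 2L]          # high bulk total
  r2 <- n[, 3L] + n[, 4L]
  c1 <- n[, 1L] + n[, 3L]          # focal allele total
  c2 <- n[, 2L] + n[, 4L]
  e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / tot
  term <- n * log(n / e)
  term[n == 0] <- 0
  pmax(2 * rowSums(term), 0)
}

#' Two-sided Fisher's exact test for 2x2 allele-depth tables
#'
#' The two-sided P value follows the probability-mass convention: the
#' sum of all hypergeometric outcomes (at fixed margins) whose
#' probability does not exceed that of the observed table, within
#' relative tolerance 1e-7 (the convention of `stats::fisher.test`).
#' Probabilities are accumulated in log space, so `neg_log10_p` stays
#' finite and accurate even when P underflows double precision.
#'
#' @inheritParams snp_index
#' @return data.table: `fisher_p` (clamped to `[1e-300, 1]`),
#'   `neg_log10_p` (exact, from log-space).
#' @examples
#' fisher_exact(5, 0, 0, 5)    # p = 2/252
#' @export
fisher_exact <- function(n_focal_high, n_other_high, n_focal_low,
                         n_other_low) {
  n <- length(n_focal_high)
  p <- numeric(n)
  nl10 <- numeric(n)
  for (i in seq_len(n)) {
    a <- n_focal_high[i]; b <- n_other_high[i]
    c_ <- n_focal_low[i]; d <- n_other_low[i]
    m <- a + c_          # focal total (white balls)
    nn <- b + d          # other total
    k <- a + b           # high-bulk draws
    lo <- max(0L, k - nn)
    hi <- min(k, m)
    supp <- lo:hi
    lp <- dhyper(supp, m, nn, k, log = TRUE)
    lobs <- lp[supp == a]
    sel <- lp <= lobs + log(1 + 1e-7)
    lse <- logsumexp(lp[sel])
    lse <- min(lse, 0)
    p[i] <- exp(lse)
    nl10[i] <- -lse / log(10)
  }
  data.table(fisher_p = pmin(pmax(p, 1e-300), 1), neg_log10_p = nl10)
}

#' Compute all four association statistics per variant
#'
#' @param counts bulk-count table from [orient_counts()] (columns
#'   `chrom`, `pos`, `n_focal_high`, `n_other_high`, `n_focal_low`,
#'   `n_other_low`).
#' @return data.table keyed by (`chrom`, `pos`) with the depths,
#'   SNP-indices, delta, ED variants, `g_stat`, `fisher_p` and
#'   `neg_log10_p`.
#' @export
variant_stats <- function(counts) {
  ct <- as.data.table(counts)
  need <- c("chrom", "pos", "n_focal_high", "n_other_high",
            "n_focal_low", "n_other_low")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stopf("counts lack column(s): %s",
                          paste(miss, collapse = ", "))
  si <- snp_index(ct$n_focal_high, ct$n_other_high, ct$n_focal_low,
                  ct$n_other_low)
  ed <- euclidean_distance(ct$n_focal_high, ct$n_other_high,
                           ct$n_focal_low, ct$n_other_low)
  g <- g_statistic(ct$n_focal_high, ct$n_other_high, ct$n_focal_low,
                   ct$n_other_low)
  fp <- fisher_exact(ct$n_focal_high, ct$n_other_high, ct$n_focal_low,
                     ct$n_other_low)
  out <- data.table(
    chrom = ct$chrom, pos = ct$pos,
    depth_high = ct$n_focal_high + ct$n_other_high,
    depth_low = ct$n_focal_low + ct$n_other_low,
    si, ed, g_stat = g, fp)
  setorder(out, chrom, pos)
  out[]
}
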