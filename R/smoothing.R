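#' Sliding-window means of per-variant statistics
#'
#' Windows of `window_bp` are laid on a step-aligned grid per
#' chromosome: starts 1, `step_bp + 1`, `2 step_bp + 1`, ... up to the
#' chromosome end; a variant at position p belongs to
#' `[start, start + window_bp - 1]` iff it lies inside. Each window
#' reports the unweighted mean of every value column; windows holding
#' fewer than `min_snps` variants are emitted with `NA` means (masked,
#' not zeroed).
#'
#' @param stats per-variant table with `chrom`, `pos` and numeric
#'   statistic columns, sorted by (`chrom`, `pos`).
#' @param window_bp window size (default 2 Mb).
#' @param step_bp grid step (default 10 kb).
#' @param min_snps minimum variants for a reported window (default 10).
#' @param chrom_lengths optional named vector; defaults to the last
#'   variant position per chromosome.
#' @param value_cols columns to average; default every numeric column
#'   except `pos`.
#' @return data.table: `chrom`, `start`, `end`, `n_snps`, and
#'   `mean_<col>` columns.
#' @export
sliding_windows <- function(stats, window_bp = 2e6, step_bp = 1e4,
                            min_snps = 10L, chrom_lengths = NULL,
                            value_cols = NULL) {
  st <- as.data.table(stats)
  if (!all(c("chrom", "pos") %in% names(st)))
    stopf("stats must have chrom and pos columns")
  if (is.null(value_cols))
    value_cols <- setdiff(names(st)[vapply(st, is.numeric, TRUE)], "pos")
  if (length(value_cols) == 0L) stopf("no value columns to average")
  chroms <- unique(st$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    s <- st[chrom == chroms[ci]]
    pos <- s$pos
    if (is.unsorted(pos))
      stopf("stats not sorted by position on %s", chroms[ci])
    clen <- if (!is.null(chrom_lengths)) {
      if (!chroms[ci] %in% names(chrom_lengths))
        stopf("no length for chromosome %s", chroms[ci])
      chrom_lengths[[chroms[ci]]]
    } else max(pos)
    starts <- seq(1, clen, by = step_bp)
    ends <- starts + window_bp - 1
    lo <- findInterval(starts - 1, pos)     # variants strictly before
    hi <- findInterval(ends, pos)           # variants up to window end
    nsnp <- hi - lo
    w <- data.table(chrom = chroms[ci], start = starts, end = ends,
                    n_snps = nsnp)
    for (v in value_cols) {
      cs <- c(0, cumsum(s[[v]]))
      m <- (cs[hi + 1L] - cs[lo + 1L]) / nsnp
      m[nsnp < min_snps] <- NA_real_
      w[, (paste0("mean_", v)) := m]
    }
    out[[ci]] <- w
  }
  data.table::rbindlist(out)
}

#' Tricube-smoothed G statistic (G')
#'
#' For every variant i, `G'_i` is the kernel-weighted mean of the raw G
#' values of all variants j within `window_bp / 2` physically, with
#' tricube weights
#' `k_ij = (1 - (|pos_j - pos_i| / (W/2))^3)^3`. The variant always
#' includes itself, so an isolated variant keeps `G' = G`.
#'
#' @param g numeric vector of raw G values.
#' @param positions bp positions, sorted increasing (within chromosome).
#' @param window_bp full smoothing window (default 2 Mb).
#' @param chrom optional chromosome id per variant; smoothing never
#'   crosses a chromosome boundary.
#' @return numeric vector of G' values.
#' @export
tricube_g_prime <- function(g, positions, window_bp = 2e6,
                            chrom = NULL) {
  if (length(g) != length(positions)) stopf("length mismatch")
  if (!is.null(chrom)) {
    out <- numeric(length(g))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      out[idx] <- tricube_g_prime(g[idx], positions[idx], window_bp)
    }
    return(out)
  }
  if (is.unsorted(positions)) stopf("positions must be sorted")
  half <- window_bp / 2
  n <- length(g)
  out <- numeric(n)
  lo <- findInterval(positions - half - 0.5, positions) + 1L
  hi <- findInterval(positions + half, positions)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    d <- abs(positions[j] - positions[i]) / half
    k <- (1 - d^3)^3
    out[i] <- sum(k * g[j]) / sum(k)
  }
  out
}

#' Null-simulation confidence thresholds for delta SNP-index
#'
#' Simulates the no-linkage null: each bulk's true focal-allele
#' frequency is the mean of `2 * bulk_size` independent gametes
#' (Binomial(2m, 1/2) / 2m), observed frequencies are binomial draws at
#' the given depth, and delta is their difference. Symmetric
#' `(1 - level)/2` and `(1 + level)/2` quantiles give the two-sided
#' confidence band per depth; the band shrinks as depth grows.
#'
#' @param bulk_size individuals per bulk.
#' @param depths integer vector of per-bulk depths to tabulate
#'   (default `c(20, 40, 60, 85, 120, 200, 400)`).
#' @param n_sims null replicates per depth (>= 1000; default 10000).
#' @param levels confidence levels (default 0.95 and 0.99).
#' @param seed optional seed.
#' @return `threshold_set` data.table: `depth`, `level`, `lower`,
#'   `upper`; attributes `method` ("delta_snp_index"), `derivation`
#'   ("simulation"), `seed`.
#' @export
delta_ci_thresholds <- function(bulk_size,
                                depths = c(20, 40, 60, 85, 120, 200, 400),
                                n_sims = 10000L,
                                levels = c(0.95, 0.99),
                                seed = NULL) {
  if (bulk_size <= 0) stopf("bulk_size must be positive")
  if (n_sims < 1000L) stopf("n_sims must be at least 1000")
  set_op_seed(seed, 505L)
  m2 <- 2L * as.integer(bulk_size)
  rows <- list()
  for (d in depths) {
    f_high <- rbinom(n_sims, m2, 0.5) / m2
    f_low <- rbinom(n_sims, m2, 0.5) / m2
    obs_h <- rbinom(n_sims, round(d), f_high) / round(d)
    obs_l <- rbinom(n_sims, round(d), f_low) / round(d)
    delta <- obs_h - obs_l
    for (lv in levels) {
      qs <- quantile(delta, c((1 - lv) / 2, (1 + lv) / 2), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.table(depth = d, level = lv, lower = qs[1L], upper = qs[2L])
    }
  }
  ts <- data.table::rbindlist(rows)
  data.table::setattr(ts, "method", "delta_snp_index")
  data.table::setattr(ts, "derivation", "simulation")
  data.table::setattr(ts, "seed", seed)
  data.table::setattr(ts, "class",
                      c("threshold_set", class(ts)))
  ts
}

#' Genome-wide empirical quantile thresholds
#'
#' The empirical alternative used for the unsigned tracks (squared ED,
#' G', -log10 P) and optionally for signed ones: thresholds are
#' genome-wide quantiles (linear interpolation, R type 7) of the
#' window statistic. Signed statistics get both tails.
#'
#' @param values window-statistic vector (NAs dropped).
#' @param levels confidence levels (default 0.95, 0.99).
#' @param two_sided also report the lower tail (for signed statistics).
#' @param method statistic name stored as metadata.
#' @return `threshold_set` data.table: `level`, `lower` (NA when
#'   one-sided), `upper`.
#' @export
quantile_thresholds <- function(values, levels = c(0.95, 0.99),
                                two_sided = FALSE,
                                method = "statistic") {
  x <- values[!is.na(values)]
  if (length(x) < 100L)
    stopf("need at least 100 non-null windows, got %d", length(x))
  ts <- data.table(
    level = levels,
    lower = if (two_sided) quantile(x, (1 - levels) / 2, names = FALSE)
            else NA_real_,
    upper = if (two_sided) quantile(x, (1 + levels) / 2, names = FALSE)
            else quantile(x, levels, names = FALSE))
  data.table::setattr(ts, "method", method)
  data.table::setattr(ts, "derivation", "quantile")
  data.table::setattr(ts, "class", c("threshold_set", class(ts)))
  ts
}

#' Evaluate a threshold set at a level (and depth)
#'
#' Depth-dependent sets (from [delta_ci_thresholds()]) are linearly
#' interpolated in depth; quantile sets ignore `depth`.
#'
#' @param thresholds a `threshold_set`.
#' @param level confidence level present in the set.
#' @param depth per-window depth vector (simulation sets only).
#' @return list with numeric `lower` and `upper` (recycled or
#'   per-window).
#' @export
threshold_at <- function(thresholds, level, depth = NULL) {
  ts <- as.data.frame(thresholds)
  sub <- ts[abs(ts$level - level) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("level %s not tabulated", level)
  if ("depth" %in% names(sub) && length(unique(sub$depth)) > 1L) {
    if (is.null(depth))
      stopf("depth-dependent thresholds need a depth")
    list(lower = approx(sub$depth, sub$lower, depth, rule = 2,
                        ties = "ordered")$y,
         upper = approx(sub$depth, sub$upper, depth, rule = 2,
                        ties = "ordered")$y)
  } else {
    list(lower = sub$lower[1L], upper = sub$upper[1L])
  }
}

#' Write a threshold set as JSON with derivation metadata
#'
#' @param thresholds a `threshold_set`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(
    list(method = attr(thresholds, "method"),
         derivation = attr(thresholds, "derivation"),
         seed = attr(thresholds, "seed"),
         table = as.data.frame(thresholds)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
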