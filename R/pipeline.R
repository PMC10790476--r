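#' Full bulked-segregant scan: filter, statistics, windows, thresholds,
#' candidate regions
#'
#' Runs the whole association pipeline on a 4-sample variant table:
#' informative-site filtering, allele orientation to the thick-parent
#' allele, the four per-variant statistics plus tricube G', 2-Mb/10-kb
#' sliding-window means, confidence thresholds (null simulation for
#' delta SNP-index; genome-wide quantiles for squared ED, G' and
#' -log10 P), per-method interval calling at the chosen confidence
#' level, and the four-method intersection.
#'
#' @param variants variant-record table (from [read_variants()] or
#'   [simulate_bulk_depths()]).
#' @param bulk_size individuals per bulk (used by the delta null
#'   simulation; default 60).
#' @param window_bp,step_bp,min_snps sliding-window layout
#'   (defaults 2 Mb, 10 kb, 10).
#' @param level confidence level for region calling (default 0.99).
#' @param chrom_lengths optional named chromosome lengths.
#' @param min_qual,min_depth,max_depth filtering cutoffs
#'   (see [filter_informative()]).
#' @param n_sims null replicates for the delta thresholds.
#' @param k_required methods required to support a candidate
#'   (default all 4).
#' @param seed seed for the threshold simulation.
#' @return list of class `bsa_scan`: `counts`, `stats`, `windows`,
#'   `thresholds` (per method), `method_regions` (per method),
#'   `candidates`.
#' @export
bsa_scan <- function(variants, bulk_size = 60L,
                     window_bp = 2e6, step_bp = 1e4, min_snps = 10L,
                     level = 0.99, chrom_lengths = NULL,
                     min_qual = 30, min_depth = 10, max_depth = NULL,
                     n_sims = 10000L, k_required = 4L, seed = NULL) {
  filtered <- filter_informative(variants, min_qual = min_qual,
                                 min_depth = min_depth,
                                 max_depth = max_depth)
  if (nrow(filtered) == 0L) stopf("no informative sites after filtering")
  counts <- orient_counts(filtered)
  stats <- variant_stats(counts)
  stats$gprime <- tricube_g_prime(stats$g_stat, stats$pos,
                                  window_bp = window_bp,
                                  chrom = stats$chrom)
  windows <- sliding_windows(stats, window_bp = window_bp,
                             step_bp = step_bp, min_snps = min_snps,
                             chrom_lengths = chrom_lengths)

  thresholds <- list(
    delta = delta_ci_thresholds(bulk_size, n_sims = n_sims, seed = seed),
    ed = quantile_thresholds(windows$mean_signed_ed, two_sided = TRUE,
                             method = "ed"),
    g = quantile_thresholds(windows$mean_gprime, method = "g"),
    fisher = quantile_thresholds(windows$mean_neg_log10_p,
                                 method = "fisher"))

  method_regions <- list(
    delta = call_method_regions(windows, "mean_delta_snp_index",
                                thresholds$delta, level = level,
                                method = "delta_snp_index"),
    ed = call_method_regions(windows, "mean_signed_ed", thresholds$ed,
                             level = level, method = "ed"),
    g = call_method_regions(windows, "mean_gprime", thresholds$g,
                            level = level, method = "g"),
    fisher = call_method_regions(windows, "mean_neg_log10_p",
                                 thresholds$fisher, level = level,
                                 method = "fisher"))

  candidates <- intersect_methods(method_regions,
                                  k_required = k_required)
  structure(list(counts = counts, stats = stats, windows = windows,
                 thresholds = thresholds,
                 method_regions = method_regions,
                 candidates = candidates,
                 level = level),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf(
    "bsa_scan: %d informative sites, %d windows; %d candidate region(s) at the %.0f%% level\n",
    nrow(x$stats), nrow(x$windows), nrow(x$candidates),
    100 * x$level))
  if (nrow(x$candidates)) {
    cat("\nCandidate regions (all-method intersection):\n")
    print(x$candidates)
  }
  invisible(x)
}

#' Write the per-variant statistics table as TSV
#'
#' @param stats table from [variant_stats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  data.table::fwrite(as.data.table(stats), path, sep = "\t")
  invisible(path)
}

#' Write the window table as TSV
#'
#' @param windows table from [sliding_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(windows, path) {
  data.table::fwrite(as.data.table(windows), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write candidate regions as a report-style TSV
#'
#' Columns mirror the usual candidate-region table: chromosome, start,
#' end, size (Mb), direction, peak and supporting algorithms.
#'
#' @param candidates table from [intersect_methods()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  data.table::fwrite(as.data.table(candidates), path, sep = "\t")
  invisible(path)
}
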