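#' Interval size in megabases
#'
#' 1-based inclusive coordinates: `(end - start + 1) / 1e6`, rounded
#' half-up to two decimals.
#'
#' @param start,end 1-based inclusive bp coordinates (vectorized).
#' @return numeric size(s) in Mb.
#' @examples
#' region_size_mb(127500001, 129500000)   # 2.00
#' @export
region_size_mb <- function(start, end) {
  if (any(start > end)) stopf("start exceeds end")
  round_half_up((end - start + 1) / 1e6, 2)
}

#' Call significant intervals for one statistic track
#'
#' Windows whose mean exceeds the confidence threshold (upper tail,
#' lower tail, or either — two-sided for signed statistics) are merged
#' whenever they overlap or abut on the step grid. Each merged interval
#' carries the most extreme window mean as its peak, and
#' `direction = "upper"` if the peak is positive, `"lower"` otherwise.
#'
#' @param windows table from [sliding_windows()].
#' @param value_col window column to threshold (e.g. `"mean_delta_snp_index"`).
#' @param thresholds a `threshold_set` for that statistic.
#' @param level confidence level (default 0.99).
#' @param method label recorded on the output (defaults to the
#'   threshold set's method attribute).
#' @param depth_cols window columns averaged into the depth used for
#'   depth-dependent thresholds.
#' @return data.table: `chrom`, `start`, `end`, `direction`,
#'   `peak_value`, `n_windows`, `method`; zero rows when nothing is
#'   significant.
#' @export
call_method_regions <- function(windows, value_col, thresholds,
                                level = 0.99, method = NULL,
                                depth_cols = c("mean_depth_high",
                                               "mean_depth_low")) {
  w <- as.data.table(windows)
  if (!value_col %in% names(w)) stopf("no window column %s", value_col)
  tmeth <- attr(thresholds, "method")
  if (!is.null(method) && !is.null(tmeth) &&
      !tmeth %in% c(method, "statistic"))
    stopf("threshold set is for '%s', not '%s'", tmeth, method)
  method <- method %||% tmeth %||% value_col
  x <- w[[value_col]]
  depth <- if (all(depth_cols %in% names(w)))
    rowMeans(w[, depth_cols, with = FALSE]) else NULL
  th <- threshold_at(thresholds, level, depth)
  sig <- !is.na(x) &
    ((!is.na(th$upper) & x > th$upper) |
       (!is.na(th$lower) & x < th$lower))
  sig[is.na(sig)] <- FALSE
  if (!any(sig))
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      peak_value = numeric(), n_windows = integer(),
                      method = character()))
  ws <- w[sig]
  out <- lapply(split(ws, ws$chrom), function(s) {
    ir <- IRanges::reduce(IRanges::IRanges(start = s$start, end = s$end))
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$start, s$end), ir)
    grp <- S4Vectors::subjectHits(hits)
    vals <- s[[value_col]][S4Vectors::queryHits(hits)]
    peak <- vapply(split(vals, grp),
                   function(v) v[which.max(abs(v))], 0)
    nwin <- as.integer(table(grp))
    data.table(chrom = s$chrom[1L],
               start = IRanges::start(ir), end = IRanges::end(ir),
               direction = ifelse(peak > 0, "upper", "lower"),
               peak_value = unname(peak), n_windows = nwin,
               method = method)
  })
  res <- data.table::rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' Intersect per-method significant intervals into candidate regions
#'
#' A candidate region is a maximal interval covered by at least one
#' significant interval of every required method (default: all of
#' them). Peaks of the contributing methods are carried along; the
#' region's direction follows the delta SNP-index track when present
#' (unsigned tracks cannot orient a region), else the sign of the most
#' extreme contributing peak.
#'
#' @param method_regions named list of per-method tables from
#'   [call_method_regions()].
#' @param k_required minimum number of supporting methods
#'   (default all).
#' @return data.table of candidate regions: `chrom`, `start`, `end`,
#'   `size_mb`, `direction`, `peak_value`, `peak_method`,
#'   `supporting_methods` (comma-joined).
#' @export
intersect_methods <- function(method_regions,
                              k_required = length(method_regions)) {
  if (length(method_regions) < 2L)
    stopf("need at least 2 method interval lists")
  if (is.null(names(method_regions)) || any(names(method_regions) == ""))
    stopf("method_regions must be a named list")
  k_required <- as.integer(k_required)
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), size_mb = numeric(),
                      direction = character(), peak_value = numeric(),
                      peak_method = character(),
                      supporting_methods = character())
  nonempty <- Filter(function(d) nrow(d) > 0L, method_regions)
  if (length(nonempty) < k_required) return(empty)
  chroms <- sort(unique(unlist(lapply(nonempty, function(d) d$chrom))))
  rows <- list()
  for (ch in chroms) {
    irs <- lapply(method_regions, function(d) {
      s <- d[d$chrom == ch, ]
      IRanges::reduce(IRanges::IRanges(s$start, s$end))
    })
    cov <- Reduce(`+`, lapply(irs, function(ir)
      IRanges::coverage(ir, width = max(1, vapply(irs, function(i)
        if (length(i)) max(IRanges::end(i)) else 1, 0)))))
    cand <- IRanges::slice(cov, lower = k_required, rangesOnly = TRUE)
    if (length(cand) == 0L) next
    for (i in seq_along(cand)) {
      cs <- IRanges::start(cand)[i]; ce <- IRanges::end(cand)[i]
      cand_ir <- IRanges::IRanges(cs, ce)
      support <- character(); peaks <- numeric()
      for (mth in names(method_regions)) {
        s <- method_regions[[mth]]
        s <- s[s$chrom == ch, ]
        if (nrow(s) == 0L) next
        ov <- IRanges::overlapsAny(IRanges::IRanges(s$start, s$end),
                                   cand_ir)
        if (any(ov)) {
          support <- c(support, mth)
          pv <- s$peak_value[ov]
          peaks[mth] <- pv[which.max(abs(pv))]
        }
      }
      dir_src <- intersect(c("delta", "delta_snp_index"), names(peaks))
      direction <- if (length(dir_src)) {
        if (peaks[[dir_src[1L]]] > 0) "upper" else "lower"
      } else if (length(peaks)) {
        if (peaks[[which.max(abs(peaks))]] > 0) "upper" else "lower"
      } else NA_character_
      pk_i <- which.max(abs(peaks))
      rows[[length(rows) + 1L]] <- data.table(
        chrom = ch, start = cs, end = ce,
        size_mb = region_size_mb(cs, ce),
        direction = direction,
        peak_value = unname(peaks[pk_i]),
        peak_method = names(peaks)[pk_i],
        supporting_methods = paste(support, collapse = ","))
    }
  }
  if (length(rows) == 0L) return(empty)
  res <- data.table::rbindlist(rows)
  setorder(res, chrom, start)
  res[]
}

#' Genes overlapping candidate regions
#'
#' Reads gene models from GFF3 and reports every gene whose span
#' overlaps a region by at least 1 bp. Malformed feature lines (fewer
#' than 9 tab-separated fields) abort with the offending line number.
#'
#' @param gff path to a GFF3 file, or a `GRanges` of gene features.
#' @param regions data.table/data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param feature_type GFF type to keep (default `"gene"`).
#' @return data.table: `region_chrom`, `region_start`, `region_end`,
#'   `gene_id`, `gene_start`, `gene_end`, `strand`, `annotation`.
#' @export
genes_in_region <- function(gff, regions, feature_type = "gene") {
  regions <- as.data.table(regions)
  if (nrow(regions) == 0L)
    return(data.table(region_chrom = character(),
                      region_start = numeric(), region_end = numeric(),
                      gene_id = character(), gene_start = numeric(),
                      gene_end = numeric(), strand = character(),
                      annotation = character()))
  if (is.character(gff)) {
    validate_gff_lines(gff)
    gr <- rtracklayer::import(gff)
  } else gr <- gff
  if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type %in% feature_type]
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start,
                                                 regions$end))
  hits <- GenomicRanges::findOverlaps(gr, reg, minoverlap = 1L)
  gi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc))
    as.character(mc[[col]][gi]) else rep(NA_character_, length(gi))
  gene_id <- pick("ID")
  gene_id[is.na(gene_id)] <- pick("Name")[is.na(gene_id)]
  ann <- pick("Note")
  out <- data.table(
    region_chrom = regions$chrom[ri],
    region_start = regions$start[ri],
    region_end = regions$end[ri],
    gene_id = gene_id,
    gene_start = GenomicRanges::start(gr)[gi],
    gene_end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    annotation = ann)
  setorder(out, region_chrom, region_start, gene_start)
  out[]
}

validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 9L]
  if (length(bad))
    stopf("malformed GFF line %d in %s (has %d field(s), expected 9)",
          bad[1L], path, nf[which(which(body) == bad[1L])])
  invisible(TRUE)
}

#' Write regions as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param regions table with `chrom`, `start`, `end` (and optionally
#'   `peak_value`).
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  r <- as.data.table(regions)
  name <- if ("supporting_methods" %in% names(r)) r$supporting_methods
          else if ("method" %in% names(r)) r$method else "."
  score <- if ("peak_value" %in% names(r)) r$peak_value else 0
  bed <- data.table(chrom = r$chrom, start = r$start - 1, end = r$end,
                    name = name, score = score)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
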