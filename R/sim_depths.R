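#' Simulate pooled sequencing depths for two bulks and both parents
#'
#' For every marker the true focal-allele ("thick"-parent allele)
#' frequency in a bulk is the mean genotype of the bulk members divided
#' by two (equal DNA contribution per individual). Site depth is
#' Poisson(`bulk_depth`); the focal-allele read count is binomial with
#' probability `f (1 - e) + (1 - f) e`, applying the sequencing error
#' rate symmetrically. Parents are emitted as homozygotes at
#' Poisson(`parent_depth`) coverage with the same error model.
#'
#' Whether the thick-parent allele is the REF or the ALT base is drawn
#' at random per site, so downstream allele orientation is exercised.
#'
#' @param genotypes matrix from [simulate_f2_genotypes()].
#' @param bulks list from [select_bulks()].
#' @param config the same [sim_config()].
#' @return A `data.table` of variant records: `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `gt_parentA`, `gt_parentB`, and
#'   `ad_<sample>_{ref,alt}` depth columns for samples `parentA`
#'   (thick), `parentB` (thin), `high`, `low`.
#' @export
simulate_bulk_depths <- function(genotypes, bulks, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(bulks$high) == 0L || length(bulks$low) == 0L)
    stopf("empty bulk")
  set_op_seed(config$seed, 303L)
  map <- attr(genotypes, "map")
  if (is.null(map)) stopf("genotypes must carry a marker map attribute")
  m <- nrow(genotypes)
  e <- config$seq_error_rate

  f_high <- rowMeans(genotypes[, bulks$high, drop = FALSE]) / 2
  f_low  <- rowMeans(genotypes[, bulks$low,  drop = FALSE]) / 2

  draw_pool <- function(freq, mean_depth) {
    dp <- rpois(m, mean_depth)
    p <- freq * (1 - e) + (1 - freq) * e
    focal <- rbinom(m, dp, p)
    list(dp = dp, focal = focal)
  }
  hi <- draw_pool(f_high, config$bulk_depth)
  lo <- draw_pool(f_low, config$bulk_depth)
  pa <- draw_pool(rep(1, m), config$parent_depth)   # thick parent: all focal
  pb <- draw_pool(rep(0, m), config$parent_depth)

  # random per-site choice: is the focal (thick-parent) allele REF or ALT?
  focal_is_ref <- runif(m) < 0.5
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  ad <- function(pool) {
    refd <- ifelse(focal_is_ref, pool$focal, pool$dp - pool$focal)
    list(ref = as.integer(refd), alt = as.integer(pool$dp - refd))
  }
  ad_pa <- ad(pa); ad_pb <- ad(pb); ad_hi <- ad(hi); ad_lo <- ad(lo)

  data.table(
    chrom = map$chrom, pos = as.integer(map$pos), ref = ref, alt = alt,
    qual = 60,
    gt_parentA = ifelse(focal_is_ref, "0/0", "1/1"),
    gt_parentB = ifelse(focal_is_ref, "1/1", "0/0"),
    ad_parentA_ref = ad_pa$ref, ad_parentA_alt = ad_pa$alt,
    ad_parentB_ref = ad_pb$ref, ad_parentB_alt = ad_pb$alt,
    ad_high_ref = ad_hi$ref, ad_high_alt = ad_hi$alt,
    ad_low_ref = ad_lo$ref, ad_low_alt = ad_lo$alt
  )
}

#' One-call synthetic BSA-seq dataset
#'
#' Convenience wrapper chaining [simulate_f2_genotypes()],
#' [simulate_phenotypes()], [select_bulks()] and
#' [simulate_bulk_depths()].
#'
#' @param config a [sim_config()].
#' @return list with `variants` (variant-record table), `phenotypes`,
#'   `bulks`, `true_qtl` (per-locus truth, `NULL` for null genomes) and
#'   the `config`.
#' @export
sim_bsa_dataset <- function(config) {
  g <- simulate_f2_genotypes(config)
  p <- simulate_phenotypes(g, config)
  b <- select_bulks(p, config$bulk_size)
  v <- simulate_bulk_depths(g, b, config)
  list(variants = v, phenotypes = p, bulks = b,
       true_qtl = attr(p, "true_qtl"), config = config)
}

#' Write a variant-record table as a minimal VCF 4.2
#'
#' Emits four samples named `parentA`, `parentB`, `bulkHigh`, `bulkLow`
#' with `GT:AD:DP` fields, plus `##contig` headers inferred from the
#' table.
#'
#' @param variants table from [simulate_bulk_depths()] (or the same
#'   columns).
#' @param path output file path (plain text `.vcf`).
#' @param contig_lengths optional named vector of chromosome lengths;
#'   defaults to the maximum observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, contig_lengths = NULL) {
  v <- as.data.table(variants)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(split(v$pos, v$chrom), max, 0)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=shellBSA",
    sprintf("##contig=<ID=%s,length=%.0f>", names(contig_lengths),
            contig_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parentA", "parentB", "bulkHigh", "bulkLow",
          sep = "\t")
  )
  fmt <- function(gt, ad_ref, ad_alt)
    sprintf("%s:%d,%d:%d", gt, ad_ref, ad_alt, ad_ref + ad_alt)
  gt_het <- "0/1"
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, v$qual, "PASS", ".", "GT:AD:DP",
    fmt(v$gt_parentA, v$ad_parentA_ref, v$ad_parentA_alt),
    fmt(v$gt_parentB, v$ad_parentB_ref, v$ad_parentB_alt),
    fmt(gt_het, v$ad_high_ref, v$ad_high_alt),
    fmt(gt_het, v$ad_low_ref, v$ad_low_alt),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a variant-record table as TSV
#'
#' The TSV dialect mirrors the VCF content column-for-column and can be
#' read back with [read_variants()].
#'
#' @param variants variant-record table.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  data.table::fwrite(as.data.table(variants), path, sep = "\t")
  invisible(path)
}
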