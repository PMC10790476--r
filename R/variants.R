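#' Read a 4-sample variant table (VCF or TSV)
#'
#' VCF 4.x files are parsed with `VariantAnnotation::readVcf`; the four
#' samples are mapped to roles via `samples`. Multi-allelic records are
#' skipped (a count is reported via attribute and message), as are
#' records with missing allele depths. The TSV dialect written by
#' [write_variant_tsv()] is detected by extension.
#'
#' @param path `.vcf` (uncompressed or bgzipped) or `.tsv`/`.csv` file.
#' @param samples named character vector mapping roles to VCF sample
#'   names: `c(parentA=, parentB=, high=, low=)`. `parentA` is the
#'   "thick"-phenotype parent whose allele becomes the focal allele.
#'   Ignored for TSV input.
#' @return data.table of variant records (columns as in
#'   [simulate_bulk_depths()]) with attributes `n_skipped_multiallelic`
#'   and `n_skipped_missing_ad`.
#' @export
read_variants <- function(path,
                          samples = c(parentA = "parentA",
                                      parentB = "parentB",
                                      high = "bulkHigh",
                                      low = "bulkLow")) {
  if (!file.exists(path)) stopf("cannot read variants: no such file %s",
                                path)
  if (grepl("\\.(tsv|csv|txt)(\\.gz)?$", path, ignore.case = TRUE))
    return(read_variants_tsv(path))
  need <- c("parentA", "parentB", "high", "low")
  if (!all(need %in% names(samples)))
    stopf("samples must name %s", paste(need, collapse = ", "))

  vcf <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(gen))
    stopf("VCF lacks the AD FORMAT field required for bulk counts")
  have <- colnames(vcf)
  missing <- setdiff(unname(samples), have)
  if (length(missing))
    stopf("sample(s) %s not present in VCF (found: %s)",
          paste(missing, collapse = ", "), paste(have, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  biallelic <- n_alt == 1L
  n_multi <- sum(!biallelic)

  ad <- gen$AD
  gt <- gen$GT
  col_of <- function(role) match(samples[[role]], have)
  ad_pair <- function(role) {
    x <- ad[, col_of(role)]
    ok <- vapply(x, function(v) length(v) >= 2L && !anyNA(v[1:2]), TRUE)
    refd <- vapply(x, function(v) if (length(v) >= 1L) v[1L] else NA_integer_,
                   NA_integer_)
    altd <- vapply(x, function(v) if (length(v) >= 2L) v[2L] else NA_integer_,
                   NA_integer_)
    list(ok = ok, ref = refd, alt = altd)
  }
  pa <- ad_pair("parentA"); pb <- ad_pair("parentB")
  hi <- ad_pair("high"); lo <- ad_pair("low")
  have_ad <- pa$ok & pb$ok & hi$ok & lo$ok
  n_missing_ad <- sum(biallelic & !have_ad)
  keep <- biallelic & have_ad

  qualv <- VariantAnnotation::qual(vcf)
  qualv[is.na(qualv)] <- 0

  out <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = vapply(as.list(VariantAnnotation::alt(vcf)[keep]),
                 function(a) as.character(a)[1L], ""),
    qual = qualv[keep],
    gt_parentA = unname(gt[keep, col_of("parentA")]),
    gt_parentB = unname(gt[keep, col_of("parentB")]),
    ad_parentA_ref = pa$ref[keep], ad_parentA_alt = pa$alt[keep],
    ad_parentB_ref = pb$ref[keep], ad_parentB_alt = pb$alt[keep],
    ad_high_ref = hi$ref[keep], ad_high_alt = hi$alt[keep],
    ad_low_ref = lo$ref[keep], ad_low_alt = lo$alt[keep]
  )
  if (n_multi + n_missing_ad > 0L)
    message(sprintf("read_variants: skipped %d multi-allelic and %d missing-AD record(s)",
                    n_multi, n_missing_ad))
  data.table::setattr(out, "n_skipped_multiallelic", n_multi)
  data.table::setattr(out, "n_skipped_missing_ad", n_missing_ad)
  out[]
}

read_variants_tsv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("chrom", "pos", "ref", "alt", "qual", "gt_parentA",
            "gt_parentB", "ad_parentA_ref", "ad_parentA_alt",
            "ad_parentB_ref", "ad_parentB_alt", "ad_high_ref",
            "ad_high_alt", "ad_low_ref", "ad_low_alt")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("TSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  data.table::setattr(dt, "n_skipped_multiallelic", 0L)
  data.table::setattr(dt, "n_skipped_missing_ad", 0L)
  dt[]
}

# TRUE for genotype strings that are homozygous calls (e.g. 0/0, 1|1)
is_hom <- function(gt) gt %in% c("0/0", "1/1", "0|0", "1|1")

# 0 for hom-ref, 1 for hom-alt, NA otherwise
hom_allele <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("1/1", "1|1")] <- 1L
  out
}

#' Filter to informative sites for bulked-segregant analysis
#'
#' A site is kept iff (1) both parents are homozygous, (2) they carry
#' different alleles, (3) `QUAL >= min_qual`, and (4) each bulk's total
#' depth lies in `[min_depth, max_depth]`. This mirrors the standard
#' "remove low-quality sites and sites heterozygous in either parent"
#' rule that leaves only fully informative biparental markers.
#'
#' @param records variant-record table from [read_variants()].
#' @param min_qual minimum QUAL (default 30).
#' @param min_depth minimum per-bulk total depth (default 10).
#' @param max_depth maximum per-bulk total depth; default `NULL` means
#'   3x the mean bulk depth of the input.
#' @return filtered data.table with attribute `n_retained`; a message
#'   reports the retained count.
#' @export
filter_informative <- function(records, min_qual = 30, min_depth = 10,
                               max_depth = NULL) {
  r <- as.data.table(records)
  dp_high <- r$ad_high_ref + r$ad_high_alt
  dp_low <- r$ad_low_ref + r$ad_low_alt
  if (is.null(max_depth))
    max_depth <- 3 * mean(c(dp_high, dp_low))
  if (min_depth > max_depth)
    stopf("min_depth (%s) exceeds max_depth (%s)", min_depth, max_depth)
  keep <- is_hom(r$gt_parentA) & is_hom(r$gt_parentB) &
    hom_allele(r$gt_parentA) != hom_allele(r$gt_parentB) &
    r$qual >= min_qual &
    dp_high >= min_depth & dp_high <= max_depth &
    dp_low >= min_depth & dp_low <= max_depth
  keep[is.na(keep)] <- FALSE
  out <- r[keep]
  message(sprintf("filter_informative: retained %d of %d site(s)",
                  nrow(out), nrow(r)))
  data.table::setattr(out, "n_retained", nrow(out))
  out[]
}

#' Orient allele depths to the thick-parent (focal) allele
#'
#' The focal allele at each site is the allele carried by `parentA`
#' (the thick-phenotype parent), so a positive delta SNP-index always
#' means thick-bulk enrichment for thick-parent alleles regardless of
#' which strand the reference genome happens to carry.
#'
#' @param records filtered variant-record table
#'   (see [filter_informative()]).
#' @return data.table of bulk counts: `chrom`, `pos`,
#'   `n_focal_high`, `n_other_high`, `n_focal_low`, `n_other_low`, and
#'   `focal_is_ref` (orientation metadata).
#' @export
orient_counts <- function(records) {
  r <- as.data.table(records)
  pa <- hom_allele(r$gt_parentA)
  if (anyNA(pa))
    stopf("parentA genotype missing or heterozygous at %d site(s); run filter_informative first",
          sum(is.na(pa)))
  focal_is_ref <- pa == 0L
  data.table(
    chrom = r$chrom, pos = r$pos,
    n_focal_high = ifelse(focal_is_ref, r$ad_high_ref, r$ad_high_alt),
    n_other_high = ifelse(focal_is_ref, r$ad_high_alt, r$ad_high_ref),
    n_focal_low = ifelse(focal_is_ref, r$ad_low_ref, r$ad_low_alt),
    n_other_low = ifelse(focal_is_ref, r$ad_low_alt, r$ad_low_ref),
    focal_is_ref = focal_is_ref
  )
}
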