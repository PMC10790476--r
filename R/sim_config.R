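#' Configuration for the F2 bulked-segregant simulator
#'
#' Bundles every knob of the synthetic-data generator: population and
#' genome layout, causal loci, heritability, bulk construction and
#' sequencing-depth model. Defaults reproduce the design the pipeline is
#' meant to emulate: an F2 of 1,153 individuals, bulks of 60 + 60
#' phenotypic extremes, pooled coverage around 85x and parental coverage
#' around 43x.
#'
#' @param n_individuals F2 population size (default 1153).
#' @param n_chromosomes number of simulated chromosomes.
#' @param chrom_length_bp physical length of each chromosome in bp.
#' @param n_markers_per_chrom informative markers per chromosome,
#'   evenly spaced.
#' @param qtls data.frame with columns `chrom` (index), `pos_bp`,
#'   `additive_effect`, `dominance_effect` (mm). `NULL` means no causal
#'   locus (null genome).
#' @param heritability fraction of phenotypic variance explained by the
#'   simulated loci jointly, in `[0, 1]`. Default 0.3, the scale of a
#'   single major shell-thickness QTL.
#' @param bulk_size individuals per phenotypic-extreme bulk (default 60).
#' @param bulk_depth mean pooled sequencing depth per site (default 85).
#' @param parent_depth mean parental depth per site (default 43).
#' @param seq_error_rate per-read allele miscall probability
#'   (default 0.001), applied symmetrically.
#' @param cm_per_mb constant physical-to-genetic map rate (default 1
#'   cM/Mb); recombination fractions come from the Haldane map function.
#' @param baseline_mm phenotype intercept (mm).
#' @param resid_sd_mm residual phenotype SD used when the genome carries
#'   no genetic variance (null genomes), in mm.
#' @param seed integer seed making every generator call reproducible;
#'   `NULL` leaves the RNG state alone.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_chromosomes = 1,
#'                   n_markers_per_chrom = 100, bulk_size = 20, seed = 1)
#' cfg
#' @export
sim_config <- function(n_individuals = 1153L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1e8,
                       n_markers_per_chrom = 2000L,
                       qtls = default_qtls(),
                       heritability = 0.3,
                       bulk_size = 60L,
                       bulk_depth = 85,
                       parent_depth = 43,
                       seq_error_rate = 0.001,
                       cm_per_mb = 1,
                       baseline_mm = 0.89,
                       resid_sd_mm = 0.31,
                       seed = NULL) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    qtls = qtls,
    heritability = heritability,
    bulk_size = as.integer(bulk_size),
    bulk_depth = bulk_depth,
    parent_depth = parent_depth,
    seq_error_rate = seq_error_rate,
    cm_per_mb = cm_per_mb,
    baseline_mm = baseline_mm,
    resid_sd_mm = resid_sd_mm,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default causal-locus table: one additive-plus-partial-dominance QTL
#'
#' Effects (in mm) are on the scale reported for major pod-shell QTLs
#' (additive ~0.24 mm, dominance ~0.07 mm).
#' @return data.frame with one row per QTL.
#' @export
default_qtls <- function() {
  data.frame(chrom = 1L, pos_bp = 5e7,
             additive_effect = 0.24, dominance_effect = 0.07)
}

#' Read a simulator configuration from a JSON key/value file
#'
#' The file holds a flat object whose keys are [sim_config()] argument
#' names; `qtls` may be an array of objects with the QTL columns.
#' Unknown keys are an error (they are silent typos otherwise).
#'
#' @param path JSON file path.
#' @return a validated `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(vals$qtls)) vals$qtls <- as.data.frame(vals$qtls)
  do.call(sim_config, vals)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 2L) stopf("need at least 2 individuals")
  if (cfg$n_chromosomes < 1L) stopf("need at least 1 chromosome")
  if (cfg$n_markers_per_chrom < 1L) stopf("zero markers per chromosome")
  if (cfg$chrom_length_bp < cfg$n_markers_per_chrom)
    stopf("chromosome shorter than marker count")
  if (!is.numeric(cfg$heritability) || cfg$heritability < 0 ||
      cfg$heritability > 1)
    stopf("heritability must lie in [0, 1], got %s", cfg$heritability)
  if (2L * cfg$bulk_size > cfg$n_individuals)
    stopf("bulk_size * 2 (%d) exceeds n_individuals (%d)",
          2L * cfg$bulk_size, cfg$n_individuals)
  if (cfg$bulk_size <= 0L) stopf("bulk_size must be positive")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate >= 0.5)
    stopf("seq_error_rate must lie in [0, 0.5)")
  if (!is.null(cfg$qtls) && nrow(cfg$qtls) > 0L) {
    q <- cfg$qtls
    need <- c("chrom", "pos_bp", "additive_effect", "dominance_effect")
    if (!all(need %in% names(q)))
      stopf("qtls must have columns %s", paste(need, collapse = ", "))
    if (any(q$chrom < 1L | q$chrom > cfg$n_chromosomes))
      stopf("qtl chromosome index out of range")
    if (any(q$pos_bp < 1 | q$pos_bp > cfg$chrom_length_bp))
      stopf("qtl position outside chromosome")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  nq <- if (is.null(x$qtls)) 0L else nrow(x$qtls)
  cat(sprintf(
    paste0("sim_config: %d F2 individuals, %d chromosome(s) x %d markers ",
           "(%.0f bp)\n  %d QTL(s), h2 = %.2f; bulks 2 x %d at %.0fx, ",
           "parents %.0fx, error %.2g\n"),
    x$n_individuals, x$n_chromosomes, x$n_markers_per_chrom,
    x$chrom_length_bp, nq, x$heritability, x$bulk_size, x$bulk_depth,
    x$parent_depth, x$seq_error_rate))
  invisible(x)
}

# evenly spaced marker map shared by all simulator stages
marker_map <- function(cfg) {
  pos <- round(seq(1, cfg$chrom_length_bp,
                   length.out = cfg$n_markers_per_chrom))
  data.table(
    chrom = rep(sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
                each = cfg$n_markers_per_chrom),
    chrom_idx = rep(seq_len(cfg$n_chromosomes),
                    each = cfg$n_markers_per_chrom),
    pos = rep(pos, cfg$n_chromosomes)
  )
}
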