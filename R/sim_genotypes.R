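#' Simulate F2 genotypes with recombination
#'
#' Each individual receives two independent gametes per chromosome. A
#' gamete starts from a random parental phase at the first marker and
#' switches phase between adjacent markers with the Haldane
#' recombination fraction `r = (1 - exp(-2 d_cM / 100)) / 2`, where the
#' genetic distance `d_cM` comes from the physical gap at a constant
#' `cm_per_mb` rate. Crossovers are independent (no interference).
#'
#' Genotypes are coded as copies of the "thick"-parent allele: 0, 1 or 2,
#' so marker frequencies converge to the Mendelian 1:2:1.
#'
#' @param config a [sim_config()].
#' @return integer matrix, markers x individuals, with attribute `"map"`
#'   (a data.table with columns `chrom`, `chrom_idx`, `pos`).
#' @examples
#' g <- simulate_f2_genotypes(sim_config(n_individuals = 50,
#'   n_chromosomes = 1, n_markers_per_chrom = 20, bulk_size = 10, seed = 1))
#' dim(g)
#' @export
simulate_f2_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_op_seed(config$seed, 101L)
  map <- marker_map(config)
  n <- config$n_individuals
  m <- config$n_markers_per_chrom
  gen <- matrix(0L, nrow = nrow(map), ncol = n)
  for (ci in seq_len(config$n_chromosomes)) {
    pos <- map$pos[map$chrom_idx == ci]
    d_cm <- diff(pos) / 1e6 * config$cm_per_mb
    r <- 0.5 * (1 - exp(-2 * d_cm / 100))      # Haldane
    g1 <- simulate_gametes(m, n, r)
    g2 <- simulate_gametes(m, n, r)
    gen[map$chrom_idx == ci, ] <- g1 + g2
  }
  storage.mode(gen) <- "integer"
  attr(gen, "map") <- map
  gen
}

# one gamete per column: phase 0/1 at marker 1, phase switches are
# cumulative crossovers mod 2
simulate_gametes <- function(m, n, r) {
  start <- matrix(rbinom(n, 1L, 0.5), nrow = 1L)
  if (m == 1L) return(start)
  xo <- matrix(rbinom((m - 1L) * n, 1L, rep(r, n)), nrow = m - 1L)
  phase <- rbind(start, (start[rep(1L, m - 1L), , drop = FALSE] +
                           apply(xo, 2L, cumsum)) %% 2L)
  phase
}

#' Simulate phenotypes from genotypes and causal loci
#'
#' The genetic value of individual `i` is
#' `sum_q a_q (g_qi - 1) + d_q 1[g_qi == 1]` over the configured QTLs,
#' using the marker nearest each QTL position. Gaussian noise is scaled
#' so that `var(genetic) / var(total)` equals the configured
#' heritability. With `heritability = 0` (or a genome with no genetic
#' variance) the phenotype is pure noise with SD `resid_sd_mm`.
#'
#' @param genotypes matrix from [simulate_f2_genotypes()].
#' @param config the same [sim_config()].
#' @return numeric phenotype vector (mm) with attribute `"true_qtl"`, a
#'   data.frame (`chrom`, `pos_bp`, `marker_row`, `pve`) recording each
#'   causal locus and its realized variance share — used only by tests.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set_op_seed(config$seed, 202L)
  map <- attr(genotypes, "map")
  if (is.null(map)) stopf("genotypes must carry a marker map attribute")
  n <- ncol(genotypes)
  h2 <- config$heritability

  gval <- numeric(n)
  truth <- NULL
  percomp <- list()
  if (!is.null(config$qtls) && nrow(config$qtls) > 0L && h2 > 0) {
    q <- config$qtls
    rows <- integer(nrow(q))
    for (k in seq_len(nrow(q))) {
      on_chr <- which(map$chrom_idx == q$chrom[k])
      rows[k] <- on_chr[which.min(abs(map$pos[on_chr] - q$pos_bp[k]))]
      gq <- genotypes[rows[k], ]
      comp <- q$additive_effect[k] * (gq - 1L) +
        q$dominance_effect[k] * (gq == 1L)
      percomp[[k]] <- comp
      gval <- gval + comp
    }
    truth <- data.frame(chrom = map$chrom[rows], pos_bp = map$pos[rows],
                        marker_row = rows, pve = NA_real_)
  }

  vg <- var(gval)
  if (vg == 0 || h2 == 0) {
    if (h2 == 1) stopf("heritability 1 with zero genetic variance")
    pheno <- config$baseline_mm + rnorm(n, 0, config$resid_sd_mm)
  } else {
    ve <- vg * (1 - h2) / h2
    pheno <- config$baseline_mm + gval + rnorm(n, 0, sqrt(ve))
  }
  if (!is.null(truth)) {
    vp <- var(pheno)
    truth$pve <- vapply(percomp, function(cmp) var(cmp) / vp, 0)
  }
  attr(pheno, "true_qtl") <- truth
  pheno
}

#' Select extreme-phenotype bulks
#'
#' Returns the indices of the `bulk_size` largest (high bulk) and
#' `bulk_size` smallest (low bulk) phenotypes. The high bulk is chosen
#' first, ties broken by lowest index; the low bulk is then chosen from
#' the remaining individuals, again lowest index first, so the two sets
#' are always disjoint.
#'
#' @param phenotypes numeric vector, no missing values.
#' @param bulk_size individuals per bulk; `2 * bulk_size <= n`.
#' @return list with integer components `high` and `low` (sorted,
#'   1-based indices).
#' @examples
#' select_bulks(c(1, 5, 3, 2, 4), bulk_size = 2)
#' @export
select_bulks <- function(phenotypes, bulk_size) {
  if (anyNA(phenotypes) || !all(is.finite(phenotypes)))
    stopf("phenotypes contain missing or non-finite values")
  n <- length(phenotypes)
  bulk_size <- as.integer(bulk_size)
  if (bulk_size < 1L || 2L * bulk_size > n)
    stopf("bulk_size must satisfy 1 <= bulk_size <= n/2")
  high <- order(-phenotypes, seq_len(n))[seq_len(bulk_size)]
  rest <- setdiff(seq_len(n), high)
  low <- rest[order(phenotypes[rest], rest)][seq_len(bulk_size)]
  list(high = sort(high), low = sort(low))
}
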