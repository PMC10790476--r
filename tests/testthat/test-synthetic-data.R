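test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_markers_per_chrom = 0), "markers")
  expect_error(sim_config(n_individuals = 100, bulk_size = 60),
               "bulk_size")
  expect_error(sim_config(heritability = 1.2), "heritability")
  expect_error(sim_config(qtls = data.frame(chrom = 5, pos_bp = 1,
                                            additive_effect = 1,
                                            dominance_effect = 0)),
               "chromosome index")
})

test_that("a JSON config file round-trips into an identical sim_config", {
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(n_individuals = 200, n_chromosomes = 1,
         n_markers_per_chrom = 50, bulk_size = 20, heritability = 0.4,
         qtls = data.frame(chrom = 1, pos_bp = 5e7,
                           additive_effect = 0.2,
                           dominance_effect = 0.05),
         seed = 9),
    js, auto_unbox = TRUE, digits = NA)
  cfg <- sim_config_from_file(js)
  expect_identical(cfg$n_individuals, 200L)
  expect_identical(cfg$bulk_size, 20L)
  expect_equal(cfg$qtls$additive_effect, 0.2)
  expect_identical(simulate_f2_genotypes(cfg),
                   simulate_f2_genotypes(sim_config(
                     n_individuals = 200, n_chromosomes = 1,
                     n_markers_per_chrom = 50, bulk_size = 20,
                     heritability = 0.4, qtls = cfg$qtls, seed = 9)))
  writeLines("{\"bogus_key\": 1}", js)
  expect_error(sim_config_from_file(js), "unknown config key")
  unlink(js)
})

test_that("zero recombination makes chromosomes fully correlated", {
  cfg <- sim_config(n_individuals = 200, n_chromosomes = 1,
                    n_markers_per_chrom = 30, bulk_size = 10,
                    cm_per_mb = 0, qtls = NULL, seed = 11)
  g <- simulate_f2_genotypes(cfg)
  # every individual's genotype is constant along the chromosome
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1L)))
  # and the constant takes only the three F2 values
  expect_true(all(g[1, ] %in% 0:2))
})

test_that("marker genotype frequencies are Mendelian 1:2:1", {
  cfg <- sim_config(n_individuals = 10000, n_chromosomes = 1,
                    n_markers_per_chrom = 40, bulk_size = 100,
                    qtls = NULL, seed = 21)
  g <- simulate_f2_genotypes(cfg)
  n <- ncol(g)
  for (row in c(1L, 20L, 40L)) {
    freq <- tabulate(g[row, ] + 1L, 3L) / n
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / n)
    expect_true(all(abs(freq - c(.25, .5, .25)) <= 3 * se))
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 120, n_chromosomes = 2,
                    n_markers_per_chrom = 25, bulk_size = 20, seed = 33)
  g1 <- simulate_f2_genotypes(cfg)
  g2 <- simulate_f2_genotypes(cfg)
  expect_identical(g1, g2)
  d1 <- sim_bsa_dataset(cfg)
  d2 <- sim_bsa_dataset(cfg)
  expect_identical(d1$variants, d2$variants)
  expect_identical(d1$bulks, d2$bulks)
})

test_that("phenotype heritability controls genotype-phenotype coupling", {
  one_qtl <- data.frame(chrom = 1, pos_bp = 5e7,
                        additive_effect = 0.24, dominance_effect = 0)
  # h2 = 0: no association
  cfg0 <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                     n_markers_per_chrom = 11, bulk_size = 100,
                     qtls = one_qtl, heritability = 0, seed = 41)
  g0 <- simulate_f2_genotypes(cfg0)
  p0 <- simulate_phenotypes(g0, cfg0)
  expect_lt(abs(cor(g0[6, ], p0)), 3 / sqrt(2000))

  # single additive QTL at h2 = 0.32: r^2 with the causal marker
  cfg1 <- sim_config(n_individuals = 5000, n_chromosomes = 1,
                     n_markers_per_chrom = 11, bulk_size = 100,
                     qtls = one_qtl, heritability = 0.32, seed = 42)
  g1 <- simulate_f2_genotypes(cfg1)
  p1 <- simulate_phenotypes(g1, cfg1)
  qrow <- attr(p1, "true_qtl")$marker_row[1]
  expect_equal(cor(g1[qrow, ], p1)^2, 0.32, tolerance = 0.03 / 0.32)

  # zero noise (h2 = 1), one additive QTL: exactly three phenotype values
  cfg2 <- sim_config(n_individuals = 500, n_chromosomes = 1,
                     n_markers_per_chrom = 11, bulk_size = 50,
                     qtls = one_qtl, heritability = 1, seed = 43)
  g2 <- simulate_f2_genotypes(cfg2)
  p2 <- simulate_phenotypes(g2, cfg2)
  expect_length(unique(p2), 3L)

  # h2 = 1 with no genetic variance is an error
  cfg3 <- sim_config(n_individuals = 100, n_chromosomes = 1,
                     n_markers_per_chrom = 5, bulk_size = 10,
                     qtls = NULL, heritability = 1, seed = 44)
  g3 <- simulate_f2_genotypes(cfg3)
  expect_error(simulate_phenotypes(g3, cfg3), "zero genetic variance")
})

test_that("select_bulks picks extremes with the documented tie rule", {
  b <- select_bulks(c(1, 5, 3, 2, 4), bulk_size = 2)
  expect_identical(b$high, c(2L, 5L))
  expect_identical(b$low, c(1L, 4L))

  # bulk_size = n/2 partitions all individuals
  b2 <- select_bulks(c(3, 1, 4, 2), bulk_size = 2)
  expect_setequal(c(b2$high, b2$low), 1:4)

  # all equal: ties broken by lowest index, sets disjoint
  b3 <- select_bulks(rep(1, 4), bulk_size = 2)
  expect_identical(b3$high, c(1L, 2L))
  expect_identical(b3$low, c(3L, 4L))

  expect_error(select_bulks(c(1, NaN, 3, 4), 1), "missing")
})

test_that("bulk depth simulation respects frequencies and the error model", {
  cfg <- sim_config(n_individuals = 40, n_chromosomes = 1,
                    n_markers_per_chrom = 50, bulk_size = 10,
                    qtls = NULL, seq_error_rate = 0, seed = 51)
  g <- simulate_f2_genotypes(cfg)
  # force the high bulk to be fixed for the focal allele
  g[, 1:10] <- 2L
  attr(g, "map") <- attr(simulate_f2_genotypes(cfg), "map")
  v <- simulate_bulk_depths(g, list(high = 1:10, low = 11:20), cfg)
  focal_high <- ifelse(v$gt_parentA == "0/0", v$ad_high_ref,
                       v$ad_high_alt)
  # bulk fixed for the focal allele + zero error: every read is focal
  expect_true(all(focal_high == v$ad_high_ref + v$ad_high_alt))

  expect_error(simulate_bulk_depths(g, list(high = integer(0),
                                            low = 1:10), cfg),
               "empty bulk")

  # frequency 0.5 at very high depth: observed frequency within 3 SE
  cfg2 <- sim_config(n_individuals = 4, n_chromosomes = 1,
                     n_markers_per_chrom = 1, bulk_size = 2,
                     qtls = NULL, seq_error_rate = 0,
                     bulk_depth = 10000, seed = 52)
  g2 <- matrix(c(2L, 0L, 2L, 0L), nrow = 1)
  attr(g2, "map") <- attr(simulate_f2_genotypes(cfg2), "map")
  v2 <- simulate_bulk_depths(g2, list(high = 1:2, low = 3:4), cfg2)
  fh <- ifelse(v2$gt_parentA == "0/0", v2$ad_high_ref, v2$ad_high_alt)
  dp <- v2$ad_high_ref + v2$ad_high_alt
  expect_lt(abs(fh / dp - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("bulk divergence at the causal locus grows with heritability", {
  div <- sapply(c(0.1, 0.3, 0.6), function(h2) {
    mean(sapply(1:20, function(rep) {
      cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                        n_markers_per_chrom = 5, bulk_size = 100,
                        qtls = data.frame(chrom = 1, pos_bp = 5e7,
                                          additive_effect = 0.24,
                                          dominance_effect = 0),
                        heritability = h2, seed = 1000 * h2 + rep)
      g <- simulate_f2_genotypes(cfg)
      p <- simulate_phenotypes(g, cfg)
      b <- select_bulks(p, cfg$bulk_size)
      qrow <- attr(p, "true_qtl")$marker_row[1]
      mean(g[qrow, b$high]) / 2 - mean(g[qrow, b$low]) / 2
    }))
  })
  expect_true(all(div > 0))
  expect_true(all(diff(div) > 0))
})

test_that("null genomes show no bulk divergence beyond Monte Carlo error", {
  diffs <- unlist(lapply(1:10, function(rep) {
    cfg <- sim_config(n_individuals = 500, n_chromosomes = 1,
                      n_markers_per_chrom = 10, bulk_size = 50,
                      qtls = NULL, seed = 600 + rep)
    g <- simulate_f2_genotypes(cfg)
    p <- simulate_phenotypes(g, cfg)
    b <- select_bulks(p, cfg$bulk_size)
    rowMeans(g[, b$high]) / 2 - rowMeans(g[, b$low]) / 2
  }))
  # each diff has SD ~ sqrt(2 * 0.125/ bulk) ~ 0.05; mean of 100 draws
  expect_lt(abs(mean(diffs)), 3 * 0.05 / sqrt(length(diffs)) + 0.01)
})

test_that("VCF and TSV round-trips preserve the variant table", {
  cfg <- sim_config(n_individuals = 60, n_chromosomes = 2,
                    n_markers_per_chrom = 15, bulk_size = 10, seed = 71)
  d <- sim_bsa_dataset(cfg)
  vcf <- tempfile(fileext = ".vcf")
  tsv <- tempfile(fileext = ".tsv")
  write_variant_vcf(d$variants, vcf)
  write_variant_tsv(d$variants, tsv)
  rv <- suppressMessages(read_variants(vcf))
  rt <- read_variants(tsv)
  cols <- names(d$variants)
  orig <- data.table::as.data.table(d$variants)
  data.table::setorder(orig, chrom, pos)
  for (dt in list(rv, rt)) {
    data.table::setorder(dt, chrom, pos)
    expect_equal(as.data.frame(dt[, cols, with = FALSE]),
                 as.data.frame(orig), ignore_attr = TRUE)
  }
  unlink(c(vcf, tsv))
})

test_that("shell image generator produces valid rings with exact truth", {
  s <- generate_shell_image(100, 20, 0.1)
  expect_equal(s$truth_mm, 2.0)                      # (R - r) * scale
  expect_true(all(s$mask %in% 0:1))
  # connected ring with exactly one hole (checked by the contour module)
  expect_silent(extract_contours(s$mask))

  # hole absent: thickness equal to the outer radius
  expect_error(generate_shell_image(100, 100, 0.1), "no hole")
  expect_error(generate_shell_image(100, 20, 0), "scale")

  # reproducible jitter
  a <- generate_shell_image(90, 15, 0.1, boundary_noise_px = 1, seed = 5)
  b <- generate_shell_image(90, 15, 0.1, boundary_noise_px = 1, seed = 5)
  expect_identical(a$mask, b$mask)
})

test_that("elliptical ring truth matches an independent geometric oracle", {
  s <- generate_shell_image(100, 20, 0.1, eccentricity = 0.3)
  oracle <- oracle_ellipse_ring_thickness(100, 70, 80, 50) * 0.1
  expect_equal(s$truth_mm, oracle, tolerance = 1e-3)
})

test_that("mask image files round-trip (PNG and PGM) with truth sidecar", {
  s <- generate_shell_image(60, 10, 0.1, canvas_px = 160)
  png <- tempfile(fileext = ".png")
  pgm <- tempfile(fileext = ".pgm")
  js <- tempfile(fileext = ".json")
  write_mask_png(s$mask, png)
  write_pgm(s$mask, pgm)
  write_shell_truth(s, js)
  expect_identical(read_mask(png), s$mask)
  expect_identical(read_mask(pgm), s$mask)
  truth <- jsonlite::read_json(js)
  expect_equal(truth$truth_mm, s$truth_mm, tolerance = 1e-12)
  unlink(c(png, pgm, js))
})
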