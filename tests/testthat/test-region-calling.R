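fake_windows <- function(starts, values, window_bp = 2e6,
                         chrom = "chr01") {
  data.table::data.table(chrom = chrom, start = starts,
                         end = starts + window_bp - 1, n_snps = 50L,
                         mean_x = values)
}

test_that("region size arithmetic reproduces printed interval sizes", {
  # BSA candidate intervals
  expect_equal(region_size_mb(127500001, 129500000), 2.00)
  expect_equal(region_size_mb(22920001, 41090000), 18.17)
  expect_equal(region_size_mb(125790001, 132490000), 6.70)
  expect_equal(region_size_mb(3490001, 16360000), 12.87)
  # fine-mapped physical intervals
  expect_equal(region_size_mb(31024672, 31713024), 0.69)
  expect_equal(region_size_mb(126828166, 127788471), 0.96)
  expect_equal(region_size_mb(7198124, 7347232), 0.15)
  expect_equal(region_size_mb(1, 1000000), 1.00)
  expect_error(region_size_mb(10, 5), "start exceeds end")
})

test_that("significant windows merge into grid-spanning intervals", {
  w <- fake_windows(c(10001, 20001, 5e6 + 1), c(0.9, 0.8, 0.1))
  r <- call_method_regions(w, "mean_x", make_threshold(upper = 0.5))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 10001)
  expect_equal(r$end, 2020000)
  expect_equal(r$peak_value, 0.9)
  expect_equal(r$direction, "upper")

  # nothing significant
  r0 <- call_method_regions(w, "mean_x", make_threshold(upper = 2))
  expect_equal(nrow(r0), 0L)

  # single significant window spans exactly itself
  w1 <- fake_windows(30001, 0.9)
  r1 <- call_method_regions(w1, "mean_x", make_threshold(upper = 0.5))
  expect_equal(c(r1$start, r1$end), c(30001, 2030000))

  # lower-tail calls carry direction "lower"
  w2 <- fake_windows(c(1, 10001), c(-0.9, -0.85))
  r2 <- call_method_regions(w2, "mean_x",
                            make_threshold(upper = 0.5, lower = -0.5))
  expect_equal(r2$direction, "lower")
  expect_equal(r2$peak_value, -0.9)

  # mismatched method labels are refused
  expect_error(call_method_regions(w, "mean_x",
                                   make_threshold(0.5, method = "g"),
                                   method = "ed"),
               "threshold set is for")
})

test_that("raising the threshold never enlarges intervals", {
  set.seed(47)
  starts <- seq(1, 3e6, by = 1e4)
  w <- fake_windows(starts, rnorm(length(starts), 0, 1))
  r_lo <- call_method_regions(w, "mean_x", make_threshold(upper = 1))
  r_hi <- call_method_regions(w, "mean_x", make_threshold(upper = 1.5))
  cover <- function(r) {
    if (nrow(r) == 0) return(integer(0))
    unlist(mapply(seq, r$start, r$end, SIMPLIFY = FALSE))
  }
  expect_true(all(cover(r_hi) %in% cover(r_lo)))
})

test_that("four-method intersection is exact interval arithmetic", {
  mk <- function(start, end, method)
    data.table::data.table(chrom = "chr01", start = start, end = end,
                           direction = "upper", peak_value = 1,
                           n_windows = 1L, method = method)
  regions <- list(delta = mk(1, 10, "delta"), ed = mk(5, 20, "ed"),
                  g = mk(5, 12, "g"), fisher = mk(3, 11, "fisher"))
  cand <- intersect_methods(regions)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(5, 10))
  expect_equal(cand$supporting_methods, "delta,ed,g,fisher")

  # disjoint intervals: empty result
  regions2 <- list(delta = mk(1, 10, "delta"), ed = mk(50, 60, "ed"),
                   g = mk(5, 12, "g"), fisher = mk(3, 11, "fisher"))
  expect_equal(nrow(intersect_methods(regions2)), 0L)
  expect_error(intersect_methods(regions[1]), "at least 2")
})

test_that("intersection equals per-bp brute force on a toy genome", {
  set.seed(53)
  toy_len <- 10000L
  mk_random <- function(method) {
    n <- sample(2:5, 1)
    s <- sort(sample.int(toy_len - 500, n))
    e <- pmin(s + sample(100:1500, n, replace = TRUE), toy_len)
    data.table::data.table(chrom = "chr01", start = s, end = e,
                           direction = "upper", peak_value = runif(n),
                           n_windows = 1L, method = method)
  }
  for (rep in 1:5) {
    regions <- list(delta = mk_random("delta"), ed = mk_random("ed"),
                    g = mk_random("g"), fisher = mk_random("fisher"))
    memb <- sapply(regions, function(r) {
      v <- logical(toy_len)
      for (i in seq_len(nrow(r))) v[r$start[i]:r$end[i]] <- TRUE
      v
    })
    for (k in c(4L, 2L)) {
      cand <- intersect_methods(regions, k_required = k)
      got <- logical(toy_len)
      if (nrow(cand))
        for (i in seq_len(nrow(cand)))
          got[cand$start[i]:cand$end[i]] <- TRUE
      expect_identical(got, rowSums(memb) >= k)
    }
    # containment: every candidate bp lies in every method's union
    cand4 <- intersect_methods(regions, k_required = 4L)
    if (nrow(cand4)) {
      got4 <- logical(toy_len)
      for (i in seq_len(nrow(cand4)))
        got4[cand4$start[i]:cand4$end[i]] <- TRUE
      for (m in colnames(memb))
        expect_true(all(memb[got4, m]))
    }
  }
})

test_that("gene overlap honours the 1-bp rule and validates GFF", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr01\ttest\tgene\t100\t500\t.\t+\t.\tID=gene1;Note=kinase",
    "chr01\ttest\tgene\t900\t1200\t.\t-\t.\tID=gene2",
    "chr01\ttest\tgene\t2000\t2100\t.\t+\t.\tID=gene3",
    "chr02\ttest\tgene\t100\t200\t.\t+\t.\tID=gene4"), gff)
  region <- data.frame(chrom = "chr01", start = 450, end = 1000)
  hits <- genes_in_region(gff, region)
  expect_identical(sort(hits$gene_id), c("gene1", "gene2"))
  expect_equal(hits$annotation[hits$gene_id == "gene1"], "kinase")

  # 1-bp touch is an overlap
  touch <- genes_in_region(gff, data.frame(chrom = "chr01",
                                           start = 500, end = 600))
  expect_identical(touch$gene_id, "gene1")

  # empty region list gives an empty table
  expect_equal(nrow(genes_in_region(gff, region[0, ])), 0L)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr01\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr01\tbroken line"), bad)
  expect_error(genes_in_region(bad, region), "line 3")
  unlink(c(gff, bad))
})

test_that("BED export converts to 0-based half-open coordinates", {
  r <- data.table::data.table(chrom = "chr01", start = 101L, end = 200L,
                              peak_value = 0.5, method = "ed")
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(r, bed)
  got <- data.table::fread(bed, header = FALSE)
  expect_equal(got$V2, 100L)
  expect_equal(got$V3, 200L)
  expect_equal(got$V3 - got$V2, r$end - r$start + 1L)
  unlink(bed)
})
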