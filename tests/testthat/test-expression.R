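test_that("representative regions subtract other genes strand-agnostically", {
  exon <- data.frame(chrom = "chr1", start = 100, end = 200)
  other <- data.frame(chrom = "chr1", start = 150, end = 400)
  rr <- select_representative_regions(exon, other)
  expect_equal(rr$intervals$start, 100)
  expect_equal(rr$intervals$end, 150)
  expect_equal(rr$total_length, 50)

  # no overlap: identity
  rr2 <- select_representative_regions(exon,
                                       data.frame(chrom = "chr1",
                                                  start = 300, end = 400))
  expect_equal(rr2$total_length, 100)

  # fully inside an anti-sense gene: empty and flagged
  rr3 <- select_representative_regions(exon,
                                       data.frame(chrom = "chr1",
                                                  start = 0, end = 500))
  expect_false(rr3$quantifiable)
  expect_equal(rr3$total_length, 0)

  expect_error(select_representative_regions(
    data.frame(chrom = "chr1", start = 10, end = 5)), "malformed")
})

test_that("region subtraction is idempotent and order-independent", {
  set.seed(3)
  exons <- data.frame(chrom = "chr1",
                      start = c(0, 500, 1200), end = c(300, 900, 1500))
  others <- data.frame(chrom = "chr1",
                       start = sample(0:1400, 8), end = NA)
  others$end <- others$start + sample(50:300, 8)
  r1 <- select_representative_regions(exons, others)
  r2 <- select_representative_regions(r1$intervals, others)
  expect_equal(r1$intervals, r2$intervals)
  shuffled <- others[sample(nrow(others)), ]
  r3 <- select_representative_regions(exons, shuffled)
  expect_equal(r1$intervals, r3$intervals)
})

test_that("synteny filtering drops unmappable sub-intervals", {
  exon <- data.frame(chrom = "chr1", start = 100, end = 200)
  rr <- select_representative_regions(exon, synteny_map =
                                        data.frame(chrom = "chr1",
                                                   start = 120, end = 160))
  expect_equal(rr$intervals$start, 120)
  expect_equal(rr$intervals$end, 160)
})

test_that("bed12 rows expand to exon intervals", {
  row <- data.frame(chrom = "chr2", start = 1000, end = 2000, name = "g",
                    score = 0, strand = "+", thickStart = 1000,
                    thickEnd = 2000, itemRgb = "0", blockCount = 2,
                    blockSizes = "100,200", blockStarts = "0,800")
  ex <- bed12_exons(row)
  expect_equal(ex$start, c(1000, 1800))
  expect_equal(ex$end, c(1100, 2000))
})

test_that("RPKM follows the formula and its invariances", {
  expect_equal(compute_rpkm(100, 1000, 1e7), 10)
  expect_equal(compute_rpkm(0, 1000, 1e7), 0)
  expect_equal(compute_rpkm(5, 500, 1e6), 10)
  # doubling counts and library size leaves RPKM unchanged
  expect_equal(compute_rpkm(2 * 37, 812, 2 * 3.3e6),
               compute_rpkm(37, 812, 3.3e6))
  expect_error(compute_rpkm(1, 0, 1e6), "region_length")
  expect_error(compute_rpkm(1, 100, 0), "library_size")
})

test_that("intergenic background tail probabilities behave", {
  regions <- data.frame(chrom = "chrU", start = 0:199 * 2000,
                        end = 0:199 * 2000 + 1000)
  # degenerate: all background zero
  bg0 <- intergenic_background(regions, rep(0, 200), 1e6, n = 1000, seed = 1)
  expect_equal(background_p(bg0, 0.2), 1 / 1001)
  # query below the background minimum
  bg1 <- intergenic_background(regions, rep(5, 200), 1e6, n = 1000, seed = 1)
  expect_equal(background_p(bg1, 0.0), 1.0)
  # exponential background with mean 0.02: true tail at 0.2 is exp(-10)
  set.seed(8)
  expc <- rexp(200, rate = 50)           # RPKM == count for 1 kb / 1 M reads
  bg2 <- intergenic_background(regions, expc, 1e6, n = 5000, seed = 2)
  expect_lt(background_p(bg2, 0.2), 0.05)
  expect_error(intergenic_background(regions[1:50, ], rep(0, 50), 1e6),
               "at least 100")
})

test_that("background p-values are calibrated under an exchangeable null", {
  regions <- data.frame(chrom = "chrU", start = 0:499 * 2000,
                        end = 0:499 * 2000 + 1000)
  set.seed(21)
  bg <- intergenic_background(regions, rpois(500, 20), 1e6, n = 2000,
                              seed = 3)
  queries <- compute_rpkm(rpois(400, 20), 1000, 1e6)
  p <- background_p(bg, queries)
  expect_gt(min(p), 0)
  expect_lte(max(p), 1)
  expect_lt(abs(mean(p) - 0.5), 0.08)
  expect_lt(abs(mean(p < 0.25) - 0.25), 0.08)
})

test_that("transcription calls require both the cutoff and significance", {
  regions <- data.frame(chrom = "chrU", start = 0:199 * 2000,
                        end = 0:199 * 2000 + 1000)
  bg <- intergenic_background(regions, rep(0, 200), 1e6, n = 1000, seed = 1)
  expect_true(call_transcription(0.25, bg))
  expect_false(call_transcription(0.1, bg))     # below cutoff regardless
  # significant cutoff but weak background separation
  bg_hot <- intergenic_background(regions, rep(1000, 200), 1e6, n = 1000,
                                  seed = 1)
  expect_false(call_transcription(0.5, bg_hot)) # fails significance
})

test_that("tissue proportions normalize and flag all-zero genes", {
  expect_equal(tissue_proportions(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(tissue_proportions(c(0, 0, 5)), c(0, 0, 1))
  expect_true(all(is.na(tissue_proportions(c(0, 0, 0)))))
  expect_error(tissue_proportions(c(-1, 2, 3)), "negative")
  m <- rbind(a = c(1, 3), b = c(0, 0))
  pm <- tissue_proportions(m)
  expect_equal(pm["a", ], c(0.25, 0.75))
  expect_true(all(is.na(pm["b", ])))
})

test_that("density profiles normalize to 1 with the stated binning", {
  # uniform coverage: flat at 1/200
  prof <- density_profile(rep(2, 400), flank_length = 100, bins = 100)
  expect_equal(sum(prof), 1)
  expect_true(all(abs(prof - 1 / 200) < 1e-12))
  # coverage only on the transcript: flank bins all zero
  cov2 <- c(rep(0, 100), rep(5, 200), rep(0, 100))
  prof2 <- density_profile(cov2, 100)
  expect_true(all(prof2[grepl("up|down", names(prof2))] == 0))
  expect_equal(sum(prof2), 1)
  # 20x transcript vs 0.1x flanks: mean bin ratio ~ 200
  cov3 <- c(rep(0.1, 100), rep(20, 200), rep(0.1, 100))
  prof3 <- density_profile(cov3, 100)
  ratio <- mean(prof3[grepl("tx", names(prof3))]) /
    mean(prof3[grepl("up|down", names(prof3))])
  expect_equal(ratio, 200, tolerance = 1e-6)
  expect_warning(expect_null(density_profile(rep(0, 400), 100)), "zero")
})

test_that("genomic context classification is multi-label", {
  focal <- data.frame(chrom = "chr1", start = 1000, end = 2000, strand = "+")
  same <- data.frame(chrom = "chr1", start = 1500, end = 3000, strand = "+")
  expect_equal(classify_context(focal, same), "same_strand_overlap")

  anti <- data.frame(chrom = "chr1", start = 1500, end = 3000, strand = "-")
  expect_equal(classify_context(focal, anti), "antisense_overlap")

  bi_focal <- data.frame(chrom = "chr1", start = 5000, end = 6000,
                         strand = "+")
  bi_other <- data.frame(chrom = "chr1", start = 3000, end = 4500,
                         strand = "-")
  expect_equal(classify_context(bi_focal, bi_other), "bi")

  lone <- data.frame(chrom = "chr9", start = 0, end = 10, strand = "-")
  expect_equal(classify_context(focal, lone), "none")

  both <- rbind(same, anti)
  expect_setequal(classify_context(focal, both),
                  c("same_strand_overlap", "antisense_overlap"))
})

test_that("qc_summary computes ratios, flags and error rates", {
  sc <- data.frame(tissue = c("liver", "testis"),
                   correct = c(1000, 500), mislabeled = c(5, 10))
  dens <- data.frame(tissue = c("liver", "testis"), exon = c(50, 50),
                     intron = c(0.1, 0.1), intergenic = c(0.05, 0))
  q <- qc_summary(sc, dens, per_position_mismatches = rep(1.51 / 90, 90))
  expect_equal(unname(q$strand_ratio), c(200, 50))
  expect_true("strand_ratio" %in% q$flags)     # testis ratio 50 <= 100
  expect_equal(unname(q$exon_intergenic_ratio[2]), Inf)
  expect_equal(q$mean_errors_per_read, 1.51)
  q2 <- qc_summary(sc[1, ], dens[1, ])
  expect_false("strand_ratio" %in% q2$flags)
})
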