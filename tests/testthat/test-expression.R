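test_that("count prefilter uses a strict less-than-one-mean rule", {
  counts <- rbind(a = c(1, 1, 1, 0.6), b = rep(1, 4), c = rep(0, 4))
  counts["a", ] <- c(1, 1, 1, 0)        # mean 0.75 -> removed
  out <- prefilter_counts(counts, 1)
  expect_equal(rownames(out), "b")
  expect_equal(nrow(prefilter_counts(matrix(0, 5, 3))), 0)
})

test_that("TPM normalisation is length-corrected and scale-invariant", {
  counts <- matrix(c(5, 15), 2, 1, dimnames = list(c("t1", "t2"), "i1"))
  x <- tpm(counts, c(1000, 1000))
  expect_equal(unname(x[, 1]), c(250000, 750000))

  counts2 <- matrix(3, 4, 2)
  expect_true(all(tpm(counts2, rep(500, 4)) == 250000))

  # doubling one individual's counts leaves its TPM unchanged
  c3 <- matrix(withr::with_seed(81, rpois(20, 40)), 10, 2)
  l3 <- withr::with_seed(82, sample(200:3000, 10))
  t3a <- tpm(c3, l3)
  c3[, 2] <- c3[, 2] * 2
  expect_equal(tpm(c3, l3)[, 2], t3a[, 2])

  # every column sums to one million
  expect_equal(unname(colSums(t3a)), rep(1e6, 2), tolerance = 1e-6)
  expect_error(tpm(matrix(0, 2, 1), c(100, 100)), "zero total")
})

test_that("logFC with prior count follows the published convention", {
  expect_equal(logfc(8, 2), log2(8.125 / 2.125), tolerance = 1e-12)
  expect_equal(round(logfc(8, 2), 3), 1.935)
  expect_equal(logfc(5, 5), 0)
  expect_equal(logfc(0, 0), 0)
  expect_gt(logfc(10, 1), 0)  # positive = male-biased
  expect_lt(logfc(1, 10), 0)
})

test_that("bias classes obey the FDR, logFC and specificity rules", {
  meta <- data.frame(transcript_id = paste0("t", 1:4), gene_id = "g",
                     chrom = "chr7", start = 1:4 * 1e6, end = 1:4 * 1e6 + 500,
                     length_bp = 500)
  counts <- rbind(c(10, 12, 0, 0, 0),   # male-specific candidate
                  c(30, 28, 9, 9, 9),
                  c(50, 55, 2, 2, 2),
                  c(9, 9, 40, 45, 44))  # female-biased candidate
  colnames(counts) <- paste0("i", 1:5)
  rownames(counts) <- meta$transcript_id
  sexes <- rep(c("male", "female"), c(2, 3))
  de <- data.frame(transcript_id = paste0("t", 1:4),
                   logFC = c(2.5, 1.5, 5, -4),
                   FDR = c(0.04, 0.04, 0.06, 0.01))
  rec <- call_bias(counts, meta, sexes, de_table = de)
  expect_equal(rec$bias_class,
               c("male_specific",  # q < .05, |logFC| > 2, all female zero
                 "unbiased",       # |logFC| <= 2
                 "unbiased",       # FDR fail
                 "female_biased")) # males express it, so biased not specific
  # a transcript absent from the DE table is unbiased and flagged
  expect_warning(rec2 <- call_bias(counts, meta, sexes, de_table = de[-1, ]),
                 "missing")
  expect_equal(rec2$bias_class[1], "unbiased")
  expect_true(rec2$missing_from_de[1])
})

test_that("the internal Welch test matches t.test on log2(TPM + prior)", {
  withr::with_seed(83, {
    counts <- matrix(rpois(60, 50), 6, 10)
    counts[1, 1:5] <- counts[1, 1:5] * 20
  })
  meta <- data.frame(transcript_id = paste0("t", 1:6), gene_id = "g",
                     chrom = "chr1", start = 1:6, end = 1:6 + 1,
                     length_bp = rep(1000, 6))
  rownames(counts) <- meta$transcript_id
  sexes <- rep(c("male", "female"), each = 5)
  rec <- call_bias(counts, meta, sexes)
  x <- log2(tpm(counts, meta$length_bp) + 0.125)
  pref <- vapply(1:6, function(i) {
    stats::t.test(x[i, 1:5], x[i, 6:10])$p.value
  }, numeric(1))
  qref <- stats::p.adjust(pref, "BH")
  expect_equal(rec$q, qref, tolerance = 1e-10)
})

test_that("region densities reproduce the worked per-Mb numbers", {
  mk <- function(n, chrom, lo, hi, class) {
    data.frame(transcript_id = sprintf("%s_%d", chrom, seq_len(n)),
               gene_id = "g", chrom = chrom,
               start = round(seq(lo, hi, length.out = n)),
               end = round(seq(lo, hi, length.out = n)) + 100,
               length_bp = 100, bias_class = class,
               stringsAsFactors = FALSE)
  }
  rec <- rbind(mk(45, "chr7", 1e5, 10.2e6, "male_biased"),
               mk(21, "chr3", 114.1e6, 127.9e6, "female_biased"),
               mk(10, "chr1", 1e6, 9e7, "unbiased"))
  d7 <- region_density(rec, list(chrom = "chr7", start = 0, end = 10.3e6))
  expect_equal(round(d7, 1), 4.4)
  d3 <- region_density(rec, list(chrom = "chr3", start = 114e6, end = 128e6),
                       bias_classes = c("female_specific", "female_biased"))
  expect_equal(round(d3, 1), 1.5)
  expect_equal(region_density(rec, list(chrom = "chr1", start = 0, end = 1e5)),
               0)
  expect_error(region_density(rec, list(chrom = "chr7", start = 5, end = 5)),
               "end > start")
})

test_that("binomial enrichment matches brute-force tail summation", {
  # region with 45 of 46 male-biased vs 63:44 in the rest of the genome
  p <- binomial_enrichment(45, 46, 63, 44)
  expect_lt(p, 1e-5)
  expect_equal(p, binom_tail_oracle(45, 46, 63 / 107), tolerance = 1e-12)
  expect_equal(binomial_enrichment(1, 2, 5, 5), 0.75)
  expect_equal(binomial_enrichment(0, 10, 1, 1), 1)
  withr::with_seed(84, {
    for (r in 1:100) {
      n <- sample(1:60, 1); x <- sample(0:n, 1)
      m <- sample(1:50, 1); f <- sample(0:50, 1)
      expect_equal(binomial_enrichment(x, n, m, f),
                   binom_tail_oracle(x, n, m / (m + f)), tolerance = 1e-10)
    }
  })
  expect_error(binomial_enrichment(1, 2, 0, 0), "no sex-biased")
})

test_that("null data keep the empirical FDR near nominal", {
  cfg <- sim_config(sl_male_bias_fraction = 0, background_bias_fraction = 0,
                    n_transcripts_SL = 150, n_transcripts_background = 350)
  inds <- data.frame(id = sprintf("i%02d", 1:14),
                     sex = rep(c("female", "male"), c(9, 5)),
                     sl_genotype = rep(c("WZ", "WW", "WY", "ZY"), c(5, 4, 3, 2)))
  ## under the global null every rejection is false, so the per-seed false
  ## discovery proportion is 1 when anything is called and 0 otherwise
  fdp <- vapply(1:40, function(s) {
    ex <- simulate_expression(cfg, inds, seed = 8000 + s)
    counts <- prefilter_counts(ex$counts)
    meta <- ex$transcripts[match(rownames(counts),
                                 ex$transcripts$transcript_id), ]
    rec <- call_bias(counts, meta, inds$sex)
    as.numeric(any(rec$bias_class != "unbiased"))
  }, numeric(1))
  expect_lte(mean(fdp), 1.5 * 0.05)
})

test_that("the default scenario enriches the sex-linked region as configured", {
  cfg <- sim_config()
  inds <- data.frame(id = sprintf("i%02d", 1:14),
                     sex = rep(c("female", "male"), c(9, 5)),
                     sl_genotype = rep(c("WZ", "WW", "WY", "ZY"), c(5, 4, 3, 2)))
  ex <- simulate_expression(cfg, inds, seed = 85)
  counts <- prefilter_counts(ex$counts)
  meta <- ex$transcripts[match(rownames(counts), ex$transcripts$transcript_id), ]
  rec <- call_bias(counts, meta, inds$sex)
  region <- list(chrom = cfg$sex_chrom, start = cfg$sl_start, end = cfg$sl_end)
  enr <- region_enrichment(rec, region, "male")
  bg_len_mb <- cfg$chromosomes[["chr1"]] / 1e6
  bg_density <- sum(!grepl("^chr7", rec$chrom) &
                      rec$bias_class %in% c("male_specific", "male_biased")) /
    bg_len_mb
  expect_gt(enr$density_per_mb, 5 * max(bg_density, 1 / bg_len_mb))
  expect_lt(enr$p_binomial, 0.01)
  # genotype-class subset contrasts run through the identical code path
  sub <- inds$sl_genotype %in% c("WW", "WY")
  rec_sub <- call_bias(counts[, sub], meta, inds$sex[sub])
  expect_s3_class(rec_sub, "expression_records")
  expect_gt(region_density(rec_sub, region), 0)
})
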