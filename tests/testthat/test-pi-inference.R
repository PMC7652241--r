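test_that("per-individual pi applies the genotype filters and pools sites", {
  mk <- function(tx, n, het_idx = integer(0), dp = 30L, gq = 80L, mq = 50L) {
    data.frame(individual = "i1", transcript_id = tx, chrom = "chr7",
               pos = seq_len(n), het = seq_len(n) %in% het_idx,
               dp = dp, gq = gq, mq = mq, stringsAsFactors = FALSE)
  }
  txmeta <- data.frame(transcript_id = c("a", "b", "c"),
                       is_sl = c(TRUE, TRUE, FALSE))
  # transcript a: 3 het of 50; transcript b: 0 of 30 -> pooled 3/80 = 0.0375
  calls <- rbind(mk("a", 50, 1:3), mk("b", 30), mk("c", 40, 1:4))
  prof <- per_individual_pi(calls, txmeta)
  s <- prof$summary
  expect_equal(s$pi_sl, 3 / 80)
  expect_equal(s$pi_bg, 0.1)
  pt <- prof$per_transcript
  expect_equal(pt$pi[pt$transcript_id == "a"], 0.06)
  expect_equal(pt$pi[pt$transcript_id == "b"], 0)

  # all homozygous -> pi = 0
  prof0 <- per_individual_pi(rbind(mk("a", 50), mk("c", 10)), txmeta)
  expect_equal(prof0$summary$pi_sl, 0)

  # failing DP/GQ/MQ sites are excluded from callable and het counts
  bad <- rbind(mk("a", 10, 1:2),
               mk("a", 5, 1:5, dp = 3L),    # DP < 4
               mk("a", 5, 1:5, gq = 19L),   # GQ < 20
               mk("a", 5, 1:5, mq = 19L))   # MQ < 20
  bad$pos <- seq_len(nrow(bad))
  profb <- per_individual_pi(bad, txmeta)
  expect_equal(profb$per_transcript$callable[1], 10)
  expect_equal(profb$per_transcript$het[1], 2)

  # region-based SL assignment from transcript coordinates
  txc <- data.frame(transcript_id = c("a", "b", "c"), chrom = "chr7",
                    start = c(1e6, 5e6, 9e7))
  profr <- per_individual_pi(calls, txc,
                             region = list(chrom = "chr7", start = 0,
                                           end = 10.3e6))
  expect_equal(profr$summary$pi_sl, 3 / 80)

  # zero callable SL sites: flagged, summary undefined
  expect_warning(profu <- per_individual_pi(mk("c", 10, 1), txmeta),
                 "zero callable")
  expect_true(is.na(profu$summary$pi_sl))
})

test_that("simulated site-level calls reproduce the configured divergence", {
  cfg <- sim_config(n_transcripts_SL = 60, n_transcripts_background = 40,
                    transcript_callable_bp = 60)
  inds <- data.frame(id = c("a", "b"), sex = c("female", "male"),
                     sl_genotype = c("WZ", "ZY"))
  sc <- expression_site_calls(cfg, inds, seed = 91)
  prof <- per_individual_pi(sc$calls, sc$transcripts)
  s <- prof$summary
  expect_lt(abs(s$pi_sl[s$individual == "a"] - cfg$d_WZ), 0.006)
  expect_lt(abs(s$pi_sl[s$individual == "b"] - cfg$d_ZY), 0.004)
  # filters actually removed sites
  expect_lt(sum(prof$per_transcript$callable),
            nrow(sc$calls))
})

test_that("two-level splitting uses the largest gap against background spread", {
  v <- c(a = 0.001, b = 0.0012, c = 0.010, d = 0.011)
  sp <- split_two_levels(v, background_spread = 0.0005)
  expect_equal(sp$k, 2)
  expect_equal(unname(sp$level[c("a", "b", "c", "d")]),
               c("low", "low", "high", "high"))

  flat <- c(a = 0.0010, b = 0.0011, c = 0.0009, d = 0.0012)
  expect_equal(split_two_levels(flat, 0.0005)$k, 1)
  expect_equal(split_two_levels(c(x = 0.5), 0.1)$k, 1)
})

test_that("two-level recovery holds across seeded WZ x WY replicates", {
  cfg <- sim_config(n_transcripts_SL = 400, n_transcripts_background = 600)
  ok <- vapply(1:60, function(s) {
    inds <- data.frame(id = sprintf("i%02d", 1:14),
                       sex = rep(c("female", "male"), c(9, 5)),
                       sl_genotype = rep(c("WZ", "WW", "WY", "ZY"),
                                         c(5, 4, 3, 2)))
    ex <- simulate_expression(cfg, inds, seed = 9100 + s)
    prof <- pi_profile_from_summary(ex$het_summary)
    s2 <- prof$summary
    bg <- diff(range(s2$pi_bg))
    spl_f <- split_two_levels(
      stats::setNames(s2$pi_sl, s2$individual)[inds$sex == "female"], bg)
    spl_m <- split_two_levels(
      stats::setNames(s2$pi_sl, s2$individual)[inds$sex == "male"], bg)
    spl_f$k == 2 && spl_m$k == 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("genotype assignment resolves the cross and labels the levels", {
  summ <- data.frame(individual = sprintf("i%02d", 1:14),
                     pi_sl = c(0.010, 0.0005, 0.011, 0.0004, 0.0102,
                               0.0098, 0.0005, 0.0101, 0.0099,
                               0.0097, 0.002, 0.0105, 0.0021, 0.0102),
                     pi_bg = rep(c(0.0005, 0.0006), 7))
  sexes <- stats::setNames(rep(c("female", "male"), c(9, 5)), summ$individual)
  calls <- assign_genotypes(summ, sexes)
  expect_equal(attr(calls, "cross"), list(mother = "WZ", father = "WY"))
  expect_equal(calls$genotype[calls$sex == "female"],
               ifelse(summ$pi_sl[1:9] > 0.005, "WZ", "WW"))
  expect_equal(calls$genotype[calls$sex == "male"],
               ifelse(summ$pi_sl[10:14] > 0.005, "WY", "ZY"))
  # inferred genotypes never conflict with phenotypic sex
  expect_true(all(sex_of(calls$genotype) == calls$sex))

  # single level in sons is anchored by the two female levels
  summ2 <- summ
  summ2$pi_sl[10:14] <- c(0.0101, 0.099e-1, 0.0098, 0.0102, 0.0100)[1:5]
  calls2 <- assign_genotypes(summ2, sexes)
  expect_true(all(calls2$genotype[calls2$sex == "male"] == "WY"))
  summ3 <- summ
  summ3$pi_sl[10:14] <- 0.002
  calls3 <- assign_genotypes(summ3, sexes)
  expect_true(all(calls3$genotype[calls3$sex == "male"] == "ZY"))

  # both sexes single-level: conservative abstention
  summ4 <- summ
  summ4$pi_sl <- rep(c(0.0101, 0.0099), 7)
  calls4 <- assign_genotypes(summ4, sexes)
  expect_true(all(is.na(calls4$genotype)))

  # a cross whose sex ratio is implausible for the sample is excluded:
  # 9 daughters + 5 sons with one level each cannot resolve WZ x ZY alone
  expect_true(is.null(attr(calls4, "cross")))
})

test_that("Y-origin inference follows the class ordering with bootstrap support", {
  mk_pt <- function(pi_by_class, n_tx = 300, callable = 50) {
    inds <- names(pi_by_class)
    do.call(rbind, lapply(inds, function(i) {
      withr::with_seed(match(i, inds) * 7 + 1, {
        data.frame(individual = i, transcript_id = sprintf("tx%03d", 1:n_tx),
                   is_sl = TRUE, callable = callable,
                   het = rbinom(n_tx, callable, pi_by_class[[i]]),
                   stringsAsFactors = FALSE)
      })
    }))
  }
  calls <- data.frame(individual = c("wz", "wy", "zy"),
                      genotype = c("WZ", "WY", "ZY"))
  pt <- mk_pt(c(wz = 0.010, wy = 0.011, zy = 0.002))
  yo <- infer_y_origin(pt, calls, B = 500, seed = 92)
  expect_equal(yo$call, "from_Z")
  expect_gte(yo$support[["from_Z"]], 0.95)

  # symmetric rule: a W-derived Y
  ptw <- mk_pt(c(wz = 0.010, wy = 0.002, zy = 0.011))
  expect_equal(infer_y_origin(ptw, calls, B = 500, seed = 93)$call, "from_W")

  # indistinguishable classes stay undetermined
  pteq <- mk_pt(c(wz = 0.005, wy = 0.005, zy = 0.005))
  expect_equal(infer_y_origin(pteq, calls, B = 300, seed = 94)$call,
               "undetermined")

  # a missing class is undetermined, not an error
  yo2 <- infer_y_origin(pt[pt$individual != "zy", ], calls, B = 100, seed = 95)
  expect_equal(yo2$call, "undetermined")
})
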