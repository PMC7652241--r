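test_that("informative-site extraction recodes inherited alleles", {
  # sites: father het x mother hom(ref); father het x mother het; father hom
  g <- rbind(c(0L, 1L, 0L, 1L, 1L, 0L),   # mom 0/0, dad 0/1
             c(1L, 1L, 0L, 1L, 2L, 1L),   # both het -> excluded
             c(0L, 0L, 0L, 0L, 0L, 0L),   # dad hom -> excluded
             c(2L, 1L, 2L, 1L, 1L, 2L))   # mom 1/1, dad 0/1
  fd <- make_tiny_family(g)
  iss <- extract_informative_sites(fd, "father")
  expect_equal(nrow(iss$states), 2)
  # mother 0/0: offspring dosage = inherited paternal allele
  expect_equal(unname(iss$states[1, ]), c(0L, 1L, 1L, 0L))
  # mother 1/1: inherited paternal allele = dosage - 1
  expect_equal(unname(iss$states[2, ]), c(1L, 0L, 0L, 1L))

  # an impossible offspring genotype becomes missing, not an error
  g2 <- rbind(c(0L, 1L, 2L, 0L, 1L, 0L))  # offspring dosage 2 impossible
  fd2 <- make_tiny_family(g2)
  iss2 <- extract_informative_sites(fd2, "father")
  expect_true(is.na(iss2$states[1, 1]))

  # maternal scan mirrors the paternal one (no maternal het site here)
  expect_warning(issm <- extract_informative_sites(fd, "mother"),
                 "no informative")
  expect_equal(nrow(issm$states), 0)
  expect_warning(extract_informative_sites(fd2, "mother"), "no informative")
})

test_that("phasing minimises implied recombinants with a deterministic tie-break", {
  # 20 offspring, marker 2 stored in opposite coding: phase should flip it
  s1 <- rep(c(0L, 1L), 10)
  st <- rbind(s1, 1L - s1)
  iss <- make_states(st, pos = c(1e6, 2e6), sexes = rep("female", 20))
  ph <- phase_states(iss)
  expect_equal(unname(ph$states[2, ]), unname(ph$states[1, ]))

  # 19/20 concordant after the best phase: one recombinant, not 19
  s2 <- s1; s2[5] <- 1L - s2[5]
  iss2 <- make_states(rbind(s1, 1L - s2), c(1e6, 2e6), rep("female", 20))
  ph2 <- phase_states(iss2)
  expect_equal(sum(ph2$states[1, ] != ph2$states[2, ]), 1)

  # exact tie (10/20 mismatches): current coding kept
  s3 <- c(rep(0L, 10), rep(1L, 10))
  s4 <- c(rep(1L, 5), rep(0L, 10), rep(1L, 5))
  iss3 <- make_states(rbind(s3, s4), c(1e6, 2e6), rep("female", 20))
  ph3 <- phase_states(iss3)
  expect_equal(unname(ph3$states[2, ]), s4)
})

test_that("double-recombinant masking follows the flank-to-flank window rule", {
  pos <- c(1, 2, 3, 4, 5) * 1e6
  # A A B A A: the middle B is masked (span 2 Mb <= 10 Mb)
  st <- matrix(c(0L, 0L, 1L, 0L, 0L), 5, 1)
  iss <- make_states(st, pos, sexes = "male", phased = TRUE)
  out <- mask_double_recombinants(iss, 1e7)
  expect_true(is.na(out$states[3, 1]))
  expect_equal(sum(is.na(out$states)), 1)

  # single crossover: nothing masked
  st2 <- matrix(c(0L, 0L, 1L, 1L, 1L), 5, 1)
  out2 <- mask_double_recombinants(make_states(st2, pos, "male", phased = TRUE))
  expect_equal(sum(is.na(out2$states)), 0)

  # A B B A with a 15 Mb flank-to-flank span: exceeds the 10 Mb window
  st3 <- matrix(c(0L, 1L, 1L, 0L), 4, 1)
  out3 <- mask_double_recombinants(
    make_states(st3, c(1e6, 6e6, 11e6, 16e6), "male", phased = TRUE), 1e7)
  expect_equal(sum(is.na(out3$states)), 0)

  # runs at chromosome ends are never masked, even single markers
  st4 <- matrix(c(1L, 0L, 0L, 0L, 0L), 5, 1)
  out4 <- mask_double_recombinants(make_states(st4, pos, "male", phased = TRUE))
  expect_equal(sum(is.na(out4$states)), 0)
  # an interior multi-marker run within the window is a double recombinant
  st4b <- matrix(c(1L, 0L, 0L, 0L, 1L), 5, 1)
  out4b <- mask_double_recombinants(make_states(st4b, pos, "male",
                                                phased = TRUE))
  expect_equal(sum(is.na(out4b$states)), 3)

  # iteration to a fixed point: alternating states collapse
  st5 <- matrix(c(0L, 1L, 0L, 1L, 0L), 5, 1)
  out5 <- mask_double_recombinants(make_states(st5, pos, "male", phased = TRUE))
  final <- out5$states[!is.na(out5$states[, 1]), 1]
  expect_true(length(rle(final)$lengths) <= 2)

  expect_error(mask_double_recombinants(make_states(st, pos, "male")), "phased")
})

test_that("exact sex-association p-values match hypergeometric enumeration", {
  # 5 sons all state 1, 7 daughters all state 0
  st <- matrix(c(rep(1L, 5), rep(0L, 7)), 1)
  iss <- make_states(st, 1e6, sexes = rep(c("male", "female"), c(5, 7)),
                     phased = TRUE)
  res <- test_sex_association(iss)
  expect_equal(res$p, 2 / choose(12, 5), tolerance = 1e-12)

  # states balanced within each sex are not associated with sex
  st2 <- matrix(rep(c(1L, 0L), 6), 1)
  iss2 <- make_states(st2, 1e6, sexes = rep(c("male", "female"), each = 6),
                      phased = TRUE)
  expect_equal(test_sex_association(iss2)$p, 1)

  # family-1 scale: 21 sons vs 22 daughters, perfect linkage
  st3 <- matrix(c(rep(1L, 21), rep(0L, 22)), 1)
  iss3 <- make_states(st3, 1e6, sexes = rep(c("male", "female"), c(21, 22)),
                      phased = TRUE)
  expect_lt(test_sex_association(iss3)$p, 2e-11)

  # vectorised implementation vs the enumeration oracle on random tables
  withr::with_seed(61, {
    for (r in 1:300) {
      n <- sample(6:60, 1)
      g1 <- sample(2:(n - 2), 1)
      k <- sample(0:n, 1)
      x <- sample(max(0, k + g1 - n):min(k, g1), 1)
      expect_equal(exact_2x2_p(x, k, n, g1),
                   exact_2x2_enumeration_oracle(x, k, n, g1),
                   tolerance = 1e-12)
    }
  })

  # all-missing site: p = 1 with a flag
  st4 <- matrix(NA_integer_, 1, 12)
  iss4 <- make_states(st4, 1e6, sexes = rep(c("male", "female"), 6),
                      phased = TRUE)
  res4 <- test_sex_association(iss4)
  expect_equal(res4$p, 1)
  expect_true(res4$all_missing)
  expect_true(all(res4$q >= res4$p))
})

test_that("type-I error is calibrated under sex-label permutation", {
  fd <- simulate_family(sim_config(n_offspring = 40), seed = 62)
  iss <- mask_double_recombinants(phase_states(
    extract_informative_sites(fd, "father")))
  n_perm <- 200
  rates <- withr::with_seed(63, vapply(seq_len(n_perm), function(i) {
    iss$sexes <- sample(iss$sexes)
    res <- test_sex_association(iss, apply_fdr = FALSE)
    ## autosomal sites only: physically linked states are not independent
    ## across sites, so calibrate on the per-site marginal rate
    mean(res$p[res$chrom == "chr1"] < 0.05)
  }, numeric(1)))
  ## discrete exact tests are conservative: marginal rejection at or below 5%
  ## plus binomial slack
  expect_lt(mean(rates), 0.05 + 2 * stats::sd(rates) / sqrt(n_perm) + 0.01)
})

test_that("the scan pinpoints the sex-linked region in a WW x WY family", {
  fd <- simulate_family(sim_config(mother = "WW", father = "WY"), seed = 64)
  scan <- sex_linkage_scan(fd, "father")
  sup <- sexlink_support_set(scan)
  expect_true(all(sup$chrom == "chr7"))
  expect_true(any(sup$pos <= 10.3e6))
  # maternal heterozygous sites are not sex-linked in this cross
  expect_warning(scanm <- sex_linkage_scan(fd, "mother"), regexp = NA)
  expect_gt(min(scanm$q), 0.05)
})
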