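test_that("mapping functions match their closed forms", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambi_cm(0.1), 3), 10.137)
  expect_equal(round(kosambi_cm(0.25), 3), 27.465)
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.25), -50 * log(0.5))
  # Kosambi compresses relative to Haldane at large r
  expect_lt(kosambi_cm(0.4), haldane_cm(0.4))
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(haldane_cm(-0.01), "0.5")
})

test_that("interval recombination fractions count state flips", {
  st <- rbind(rep(0L, 40),
              c(rep(1L, 4), rep(0L, 36)),  # 4/40 recombinants vs row 1? see below
              rep(0L, 40))
  # phase_states will flip row 2 only if that reduces recombinants (4 < 36: no)
  iss <- make_states(st, pos = c(1, 2, 3) * 1e6, sexes = rep("male", 40),
                     phased = TRUE)
  ivl <- interval_recombination_fractions(iss, min_informative = 5)
  expect_equal(ivl$r, c(4 / 40, 4 / 40))
  expect_equal(ivl$n_informative, c(40, 40))

  # no recombinants
  st0 <- rbind(rep(0L, 40), rep(0L, 40))
  ivl0 <- interval_recombination_fractions(
    make_states(st0, c(1e6, 2e6), rep("male", 40), phased = TRUE))
  expect_equal(ivl0$r, 0)

  # a complete state flip is a phase artifact, absorbed by phasing
  stf <- rbind(rep(0L, 40), rep(1L, 40))
  issf <- phase_states(make_states(stf, c(1e6, 2e6), rep("male", 40)))
  expect_equal(interval_recombination_fractions(issf)$r, 0)

  # underpowered intervals merge into the next one
  stm <- rbind(rep(0L, 10), c(rep(NA_integer_, 8), 0L, 0L), rep(1L, 10))
  ivlm <- interval_recombination_fractions(
    make_states(stm, c(1e6, 2e6, 3e6), rep("male", 10), phased = TRUE),
    min_informative = 5)
  expect_equal(nrow(ivlm), 1)
  expect_equal(ivlm$start_pos, 1e6)
  expect_equal(ivlm$end_pos, 3e6)
  expect_equal(ivlm$r, 1)  # all ten flip between the outer markers
})

test_that("crossover localisation recovers simulated events when error-free", {
  cfg <- sim_config(n_offspring = 25, het_to_hom_error_rate = 0,
                    missing_rate = 0)
  fd <- simulate_family(cfg, seed = 101)
  iss <- phase_states(extract_informative_sites(fd, "mother"))
  ev <- locate_crossovers(iss)
  expect_gt(nrow(ev), 0)
  # every located event interval contains at least one true maternal crossover
  off <- fd$pedigree$id[fd$pedigree$role == "offspring"]
  contained <- vapply(seq_len(nrow(ev)), function(i) {
    tx <- fd$truth$crossovers[[ev$offspring[i]]][[ev$chrom[i]]]$maternal
    any(tx >= ev$left_pos[i] & tx <= ev$right_pos[i])
  }, logical(1))
  expect_true(all(contained))
  expect_true(all(ev$midpoint == (ev$left_pos + ev$right_pos) / 2))

  # simple flip example: midpoint of the flanking markers
  st <- matrix(c(0L, 1L), 2, 1)
  ev2 <- locate_crossovers(make_states(st, c(10e6, 12e6), "male", phased = TRUE))
  expect_equal(ev2$midpoint, 11e6)
  st3 <- matrix(c(0L, 0L), 2, 1)
  expect_equal(nrow(locate_crossovers(
    make_states(st3, c(10e6, 12e6), "male", phased = TRUE))), 0)
})

test_that("quartile densities and tip bias summarise crossover locations", {
  lens <- c(chrA = 100e6)
  ev1 <- data.frame(chrom = "chrA", midpoint = c(1e6, 5e6, 20e6))
  qd1 <- quartile_density(ev1, lens)
  expect_equal(unname(qd1$counts), c(3, 0, 0, 0))
  expect_equal(qd1$tip_bias, 1)

  unif <- data.frame(chrom = "chrA",
                     midpoint = withr::with_seed(102, runif(4000, 0, 100e6)))
  qdu <- quartile_density(unif, lens)
  expect_lt(abs(qdu$tip_bias - 0.5), 0.03)
  expect_error(quartile_density(ev1[0, ], lens), "no crossover")
})

test_that("map totals are invariant to reversing marker order", {
  cfg <- sim_config(n_offspring = 30)
  fd <- simulate_family(cfg, seed = 103)
  fwd <- build_linkage_map(fd, "mother")
  # reflect all coordinates: physical order reverses within each chromosome
  fd_rev <- fd
  len <- cfg$chromosomes[fd_rev$sites$chrom]
  fd_rev$sites$pos <- unname(len - fd_rev$sites$pos + 1)
  fd_rev <- family_dataset(fd_rev$pedigree, fd_rev$geno, fd_rev$dp, fd_rev$gq,
                           fd_rev$sites, fd_rev$truth)
  rev <- build_linkage_map(fd_rev, "mother")
  expect_equal(sort(fwd$per_chromosome$total_cM),
               sort(rev$per_chromosome$total_cM), tolerance = 1e-9)
  expect_equal(fwd$per_chromosome$bp_covered, rev$per_chromosome$bp_covered)
})

test_that("female maps are longer than male maps at the configured ratio", {
  cfg <- sim_config(n_offspring = 40)
  ratios <- vapply(1:12, function(s) {
    fd <- simulate_family(cfg, seed = 1030 + s)
    qc <- apply_qc(fd)$dataset
    f <- sum(build_linkage_map(qc, "mother")$per_chromosome$total_cM)
    m <- sum(build_linkage_map(qc, "father")$per_chromosome$total_cM)
    f / m
  }, numeric(1))
  # configured female:male = 2.5; recovered ratio within +-35% on average
  # (error-driven inflation affects both maps; masking removes most of it)
  expect_gt(mean(ratios), 2.5 * 0.65)
  expect_lt(mean(ratios), 2.5 * 1.35)
  # masking shortens maps by removing double-recombinant artifacts
  fd <- simulate_family(cfg, seed = 104)
  qc <- apply_qc(fd)$dataset
  masked <- sum(build_linkage_map(qc, "mother")$per_chromosome$total_cM)
  unmasked <- sum(build_linkage_map(qc, "mother",
                                    window_bp = NULL)$per_chromosome$total_cM)
  expect_lt(masked, unmasked)
})

test_that("the map-length model recovers exact per-cell slopes", {
  cells <- expand.grid(sex = c("female", "male"), family = c("f1", "f2"),
                       stringsAsFactors = FALSE)
  slopes <- c(30, 8, 30, 8)
  intercepts <- c(20, 10, 25, 12)
  dat <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    bp <- seq(0.5, 2.2, length.out = 10)
    data.frame(sex = cells$sex[i], family = cells$family[i], bpcovered = bp,
               maplength = intercepts[i] + slopes[i] * bp)
  }))
  fit <- suppressWarnings(maplength_model(dat)) # exact fit: summary warns
  expect_equal(nrow(fit$slopes), 4)
  got <- fit$slopes$estimate[order(fit$slopes$sex, fit$slopes$family)]
  expect_equal(got, c(30, 30, 8, 8), tolerance = 1e-9)
  expect_true(all(fit$slopes$hi - fit$slopes$lo < 1e-6))

  # a zero true slope yields a CI containing zero
  datz <- dat
  withr::with_seed(105, {
    datz$maplength <- 50 + rnorm(nrow(datz), 0, 5)
  })
  fitz <- maplength_model(datz)
  expect_true(all(fitz$slopes$lo < 0 & fitz$slopes$hi > 0))

  # rank-deficient design is rejected with a message
  expect_error(maplength_model(dat[dat$bpcovered == 0.5, ]), "rank-deficient")
})
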