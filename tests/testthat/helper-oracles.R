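# Independent oracles used by the tests. Each deliberately takes a different
# computational route from the package implementation it checks.

# Weir-Cockerham theta via the nested random-effects ANOVA mean squares on
# allele indicators (alleles within individuals within groups), rather than
# the allele-frequency/heterozygosity formulas used by fst_per_site().
wc_anova_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  pops <- list(g1, g2)
  r <- 2
  n <- vapply(pops, length, integer(1))
  N <- sum(n)
  # allele indicator pairs per individual: dosage g -> alleles (1,1)/(1,0)/(0,0)
  alleles <- lapply(pops, function(g) {
    lapply(g, function(d) if (d == 1) c(1, 0) else rep(d / 2, 2))
  })
  y_all <- unlist(alleles)
  ybar <- mean(y_all)
  ybar_p <- vapply(alleles, function(a) mean(unlist(a)), numeric(1))
  ssp <- sum(2 * n * (ybar_p - ybar)^2)
  ssi <- 0; ssg <- 0
  for (p in 1:2) {
    for (ind in alleles[[p]]) {
      m <- mean(ind)
      ssi <- ssi + 2 * (m - ybar_p[p])^2
      ssg <- ssg + sum((ind - m)^2)
    }
  }
  msp <- ssp / (r - 1)
  msi <- ssi / (N - r)
  msg <- ssg / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  cc <- msg
  a / (a + b + cc)
}

# Exact HWE p by direct log-factorial enumeration over all heterozygote counts
# compatible with the allele counts (no recurrence).
hwe_lchoose_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  hets <- seq((min(na, nb)) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) return(1)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# Doubled-tail conditional exact 2x2 p by explicit dhyper summation.
exact_2x2_enumeration_oracle <- function(x, k, n, g1) {
  xs <- max(0, k + g1 - n):min(k, g1)
  probs <- stats::dhyper(xs, k, n - k, g1)
  lower <- sum(probs[xs <= x])
  upper <- sum(probs[xs >= x])
  min(1, 2 * min(lower, upper))
}

# Exact upper-tail binomial by brute-force summation of the pmf.
binom_tail_oracle <- function(x, n, p0) {
  if (x <= 0) return(1)
  sum(vapply(x:n, function(k) {
    choose(n, k) * p0^k * (1 - p0)^(n - k)
  }, numeric(1)))
}

# Localization support set of a sex-linkage scan: the significant markers with
# zero sex-discordant inheritance states. Fully co-segregating markers carry
# identical localization evidence (their p-values differ only through
# uninformative missingness), so - as in linkage mapping, where tied maximal
# markers form the support interval - the scan's location estimate is this
# set; when no marker is fully linked, the minimum-p markers are used.
sexlink_support_set <- function(scan, alpha = 0.05) {
  discord <- pmin(scan$het_male + scan$hom_female,
                  scan$hom_male + scan$het_female)
  q <- if (!is.null(scan$q)) scan$q else scan$p
  sup <- scan[discord == 0 & q < alpha & scan$n_scored > 0, , drop = FALSE]
  if (nrow(sup) == 0) sup <- scan[scan$p <= min(scan$p) * (1 + 1e-12), ,
                                  drop = FALSE]
  sup
}

# Small hand-built family for QC unit tests: two parents + offspring with
# fully controlled genotype/DP/GQ values.
make_tiny_family <- function(geno, dp = NULL, gq = NULL,
                             sites = NULL, n_off = ncol(geno) - 2,
                             off_sex = NULL) {
  ids <- c("mom", "dad", sprintf("kid%02d", seq_len(n_off)))
  colnames(geno) <- ids
  if (is.null(dp)) {
    dp <- matrix(50L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  }
  if (is.null(gq)) {
    gq <- matrix(99L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  }
  if (is.null(sites)) {
    sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(geno)) * 1000,
                        radtag = paste0("tag", seq_len(nrow(geno))),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  if (is.null(off_sex)) off_sex <- rep(c("female", "male"), length.out = n_off)
  ped <- data.frame(id = ids, family = "f1",
                    role = c("mother", "father", rep("offspring", n_off)),
                    sex = c("female", "male", off_sex),
                    stringsAsFactors = FALSE)
  family_dataset(ped, geno, dp, gq, sites)
}

# Small informative_sites object built directly from a state matrix
# (sites x offspring), for phasing/masking/mapping unit tests.
make_states <- function(states, pos, sexes, chrom = "chr7",
                        parent = "father", phased = FALSE) {
  structure(list(parent = parent,
                 sites = data.frame(chrom = chrom, pos = pos,
                                    stringsAsFactors = FALSE),
                 states = states,
                 offspring = paste0("kid", seq_len(ncol(states))),
                 sexes = sexes, phased = phased),
            class = "informative_sites")
}
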