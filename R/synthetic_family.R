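#' Simulate one meiosis of a single chromosome
#'
#' Draws a Poisson number of crossovers (mean = map length in Morgans), places
#' them uniformly (female meiosis) or with a symmetric tip-biased Beta(alpha,
#' alpha) distribution mapped onto the chromosome (male meiosis), optionally
#' removes crossovers falling in a recombination-suppressed region, and
#' returns the recombinant gamete. Crossover interference is not modelled.
#'
#' @param haplotypes 2 x n_sites matrix of parental haplotype alleles (0/1).
#' @param positions Site positions in bp, increasing.
#' @param chrom_length Chromosome length in bp (> 0).
#' @param map_cM Map length of this chromosome in this parent, centimorgans.
#' @param parent_sex `"female"` or `"male"`.
#' @param tip_bias_alpha Beta shape for male crossover positions.
#' @param suppress_region Optional `c(start, end)` in bp within which
#'   crossovers are removed (recombination suppression).
#' @return List with `alleles` (gamete allele vector), `crossovers` (sorted bp
#'   positions), `start_hap` (1 or 2, the haplotype transmitted at position 0)
#'   and `hap_index` (per-site transmitted haplotype).
#' @export
simulate_meiosis <- function(haplotypes, positions, chrom_length, map_cM,
                             parent_sex = c("female", "male"),
                             tip_bias_alpha = 0.4, suppress_region = NULL) {
  parent_sex <- match.arg(parent_sex)
  if (chrom_length <= 0) stop("chromosome length must be positive")
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2,
            ncol(haplotypes) == length(positions))
  n_xo <- stats::rpois(1, map_cM / 100)
  xo <- if (parent_sex == "female") {
    stats::runif(n_xo, 0, chrom_length)
  } else {
    stats::rbeta(n_xo, tip_bias_alpha, tip_bias_alpha) * chrom_length
  }
  if (!is.null(suppress_region) && length(xo)) {
    xo <- xo[xo < suppress_region[1] | xo > suppress_region[2]]
  }
  xo <- sort(xo)
  start_hap <- sample.int(2L, 1L)
  hap_index <- ((start_hap - 1L + findInterval(positions, xo)) %% 2L) + 1L
  alleles <- haplotypes[cbind(hap_index, seq_along(positions))]
  list(alleles = alleles, crossovers = xo, start_hap = start_hap,
       hap_index = hap_index)
}

## Haplotype index transmitted at an arbitrary position, given a meiosis.
hap_at_position <- function(meiosis, pos) {
  ((meiosis$start_hap - 1L + sum(meiosis$crossovers <= pos)) %% 2L) + 1L
}

## Generate RAD site positions and per-site allele models for all chromosomes.
## Each SL-region SNP is, with probability sl_diagnostic_frac, a fixed
## difference diagnostic for one chromosome type (W, Z or Y, drawn in
## proportion to the pattern probabilities implied by the configured
## divergences); all other SNPs are ordinary biallelic polymorphisms with a
## shared population frequency.
sim_rad_sites <- function(cfg) {
  pieces <- lapply(names(cfg$chromosomes), function(chrom) {
    len <- cfg$chromosomes[[chrom]]
    n_tags <- stats::rpois(1, cfg$rad_density * len / 1e6)
    if (n_tags == 0) return(NULL)
    tag_pos <- sort(round(stats::runif(n_tags, 1, len - 300)))
    n_snps <- sample(0:2, n_tags, replace = TRUE,
                     prob = cfg$snps_per_radtag_probs)
    keep <- n_snps > 0
    if (!any(keep)) return(NULL)
    tag_idx <- rep(which(keep), n_snps[keep])
    offset <- unlist(lapply(n_snps[keep], function(k) sample(0:290, k)))
    data.frame(chrom = chrom, pos = tag_pos[tag_idx] + offset,
               radtag = paste0(chrom, "_tag", tag_idx),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, pieces)
  sites <- sites[order(match(sites$chrom, names(cfg$chromosomes)), sites$pos), ]
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), ]
  rownames(sites) <- NULL

  n <- nrow(sites)
  in_sl <- sites$chrom == cfg$sex_chrom &
    sites$pos >= cfg$sl_start & sites$pos <= cfg$sl_end
  pp <- sl_pattern_probs(cfg)
  diag_type <- rep(NA_character_, n)
  cand <- which(in_sl & stats::runif(n) < cfg$sl_diagnostic_frac)
  if (length(cand) && sum(pp) > 0) {
    diag_type[cand] <- sample(names(pp), length(cand), replace = TRUE,
                              prob = pp / sum(pp))
  }
  sites$in_sl <- in_sl
  sites$diag_type <- diag_type
  sites$freq <- stats::runif(n, 0.2, 0.8)
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1), "")
  sites
}

## Founder haplotypes for one individual: a list (per chromosome) of 2 x
## n_sites allele matrices, plus the chromosome-type pair on the sex
## chromosome. Diagnostic sites carry allele 1 on haplotypes of the focal
## type; background sites are Bernoulli draws at the site frequency.
sim_founder <- function(cfg, sites, sl_types) {
  lapply(names(cfg$chromosomes), function(chrom) {
    idx <- sites$chrom == chrom
    s <- sites[idx, , drop = FALSE]
    haps <- matrix(0L, 2, nrow(s))
    for (h in 1:2) {
      bg <- stats::rbinom(nrow(s), 1, s$freq)
      al <- bg
      if (chrom == cfg$sex_chrom) {
        d <- !is.na(s$diag_type)
        al[d] <- as.integer(s$diag_type[d] == sl_types[h])
      }
      haps[h, ] <- al
    }
    haps
  }) |> stats::setNames(names(cfg$chromosomes))
}

#' Simulate an F1 family with RAD-style genotypes
#'
#' Builds founder haplotypes for the configured cross, performs seeded
#' meioses with sex-specific map lengths and crossover-position distributions
#' (and recombination suppression in the sex-linked region of W-carrying
#' parents), derives each offspring's phenotypic sex from its inherited
#' chromosome types at the sex locus, and then overlays an observation layer:
#' negative-binomial depth (parents at higher coverage), depth-driven genotype
#' quality, heterozygous-to-homozygous genotyping errors and missingness.
#' Truth (true genotypes, sexes, chromosome types, crossovers, error and
#' missingness masks) is retained for testing.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param family_id Family label used in sample ids.
#' @return A [family_dataset()] with a `truth` block.
#' @export
simulate_family <- function(config, seed = NULL, family_id = "fam1") {
  run <- function() simulate_family_impl(config, family_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_family_impl <- function(cfg, family_id) {
  if (cfg$n_offspring < 1) stop("n_offspring must be at least 1")
  sites <- sim_rad_sites(cfg)
  chroms <- names(cfg$chromosomes)

  mother <- sim_founder(cfg, sites, genotype_alleles(cfg$mother))
  father <- sim_founder(cfg, sites, genotype_alleles(cfg$father))
  m_types <- genotype_alleles(cfg$mother)
  f_types <- genotype_alleles(cfg$father)

  n_off <- cfg$n_offspring
  ids <- c(paste0(family_id, "_mother"), paste0(family_id, "_father"),
           sprintf("%s_off%02d", family_id, seq_len(n_off)))

  geno_true <- matrix(NA_integer_, nrow(sites), length(ids),
                      dimnames = list(NULL, ids))
  for (chrom in chroms) {
    idx <- which(sites$chrom == chrom)
    geno_true[idx, 1] <- mother[[chrom]][1, ] + mother[[chrom]][2, ]
    geno_true[idx, 2] <- father[[chrom]][1, ] + father[[chrom]][2, ]
  }

  off_sex <- character(n_off)
  off_genotype <- character(n_off)
  crossovers <- list()
  for (i in seq_len(n_off)) {
    id <- ids[2 + i]
    xo_i <- list()
    types <- c(NA_character_, NA_character_)
    for (chrom in chroms) {
      idx <- which(sites$chrom == chrom)
      pos <- sites$pos[idx]
      len <- cfg$chromosomes[[chrom]]
      is_sex <- chrom == cfg$sex_chrom
      sup_m <- if (is_sex && cfg$suppress_W_recombination && "W" %in% m_types) {
        c(cfg$sl_start, cfg$sl_end)
      }
      sup_f <- if (is_sex && cfg$suppress_W_recombination && "W" %in% f_types) {
        c(cfg$sl_start, cfg$sl_end)
      }
      gm <- simulate_meiosis(mother[[chrom]], pos, len, cfg$female_map_cM,
                             "female", cfg$male_tip_bias, sup_m)
      gf <- simulate_meiosis(father[[chrom]], pos, len, cfg$male_map_cM,
                             "male", cfg$male_tip_bias, sup_f)
      geno_true[idx, 2 + i] <- gm$alleles + gf$alleles
      xo_i[[chrom]] <- list(maternal = gm$crossovers, paternal = gf$crossovers)
      if (is_sex) {
        types <- c(m_types[hap_at_position(gm, cfg$sex_locus_pos)],
                   f_types[hap_at_position(gf, cfg$sex_locus_pos)])
      }
    }
    crossovers[[id]] <- xo_i
    off_genotype[i] <- canonical_genotype(types)
    off_sex[i] <- sex_of(off_genotype[i])
  }

  ## observation layer
  n_sites <- nrow(sites)
  depth_mu <- c(rep(cfg$depth_mean_parents, 2),
                rep(cfg$depth_mean_offspring, n_off))
  dp <- vapply(depth_mu, function(mu) {
    as.integer(stats::rnbinom(n_sites, mu = mu, size = cfg$depth_dispersion))
  }, integer(n_sites))
  colnames(dp) <- ids
  gq <- pmin(99L, pmax(0L, round(4 * dp + stats::rnorm(length(dp), 0, 6))))
  dim(gq) <- dim(dp); dimnames(gq) <- dimnames(dp)
  storage.mode(gq) <- "integer"

  geno <- geno_true
  err_mask <- geno_true == 1L &
    matrix(stats::runif(length(geno_true)) < cfg$het_to_hom_error_rate,
           n_sites, length(ids))
  geno[err_mask] <- sample(c(0L, 2L), sum(err_mask), replace = TRUE)
  miss_mask <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                      n_sites, length(ids)) | dp == 0L
  geno[miss_mask] <- NA_integer_

  pedigree <- data.frame(
    id = ids, family = family_id,
    role = c("mother", "father", rep("offspring", n_off)),
    sex = c("female", "male", off_sex),
    stringsAsFactors = FALSE)

  truth <- list(
    config = cfg,
    geno_true = geno_true,
    offspring_genotype = stats::setNames(off_genotype, ids[-(1:2)]),
    offspring_sex = stats::setNames(off_sex, ids[-(1:2)]),
    crossovers = crossovers,
    error_mask = err_mask,
    missing_mask = miss_mask,
    sl_region = c(chrom = cfg$sex_chrom, start = cfg$sl_start,
                  end = cfg$sl_end))

  family_dataset(pedigree, geno, dp, gq,
                 sites[, c("chrom", "pos", "radtag", "ref", "alt",
                           "in_sl", "diag_type")],
                 truth = truth)
}

#' Simulate a population sample of unrelated individuals
#'
#' Draws unrelated females and males whose sex-chromosome genotypes follow the
#' given frequencies, using the same site and founder-haplotype machinery as
#' [simulate_family()]. Useful for between-sex differentiation scans: in the
#' sex-linked region, type-diagnostic alleles differ in frequency between the
#' sexes, while the rest of the genome is undifferentiated.
#'
#' @param config A [sim_config()]; `rad_density` is replaced by `snp_density`.
#' @param n_female,n_male Sample sizes.
#' @param female_geno_freq,male_geno_freq Named genotype frequency vectors.
#' @param snp_density Expected SNPs per Mb for the population panel.
#' @param seed Optional seed.
#' @return List with `geno`, `dp`, `gq`, `sites`, `samples` (id, sex) and
#'   `truth` (true sex-chromosome genotype per individual), of class
#'   `population_dataset`.
#' @export
simulate_population <- function(config, n_female = 12, n_male = 26,
                                female_geno_freq = c(WW = 0.2, WZ = 0.8),
                                male_geno_freq = c(WY = 0.35, ZY = 0.35, ZZ = 0.3),
                                snp_density = 8, seed = NULL) {
  run <- function() {
    cfg <- config
    cfg$rad_density <- snp_density
    cfg$snps_per_radtag_probs <- c(0, 1, 0) # one SNP per locus in the panel
    sites <- sim_rad_sites(cfg)
    ids <- c(sprintf("F%02d", seq_len(n_female)),
             sprintf("M%02d", seq_len(n_male)))
    sexes <- c(rep("female", n_female), rep("male", n_male))
    gt <- character(length(ids))
    gt[sexes == "female"] <- sample(names(female_geno_freq), n_female,
                                    replace = TRUE, prob = female_geno_freq)
    gt[sexes == "male"] <- sample(names(male_geno_freq), n_male,
                                  replace = TRUE, prob = male_geno_freq)
    geno <- matrix(NA_integer_, nrow(sites), length(ids),
                   dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      haps <- sim_founder(cfg, sites, genotype_alleles(gt[j]))
      for (chrom in names(cfg$chromosomes)) {
        idx <- sites$chrom == chrom
        geno[idx, j] <- haps[[chrom]][1, ] + haps[[chrom]][2, ]
      }
    }
    n_sites <- nrow(sites)
    dp <- matrix(stats::rnbinom(n_sites * length(ids),
                                mu = cfg$depth_mean_offspring,
                                size = cfg$depth_dispersion),
                 n_sites, length(ids), dimnames = list(NULL, ids))
    gq <- pmin(99L, pmax(0L, round(4 * dp + stats::rnorm(length(dp), 0, 6))))
    dim(gq) <- dim(dp); dimnames(gq) <- dimnames(dp)
    miss <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   n_sites, length(ids))
    geno[miss | dp == 0L] <- NA_integer_
    structure(list(geno = geno, dp = dp, gq = gq,
                   sites = sites[, c("chrom", "pos", "radtag", "ref", "alt",
                                     "in_sl", "diag_type")],
                   samples = data.frame(id = ids, sex = sexes,
                                        stringsAsFactors = FALSE),
                   truth = list(genotype = stats::setNames(gt, ids))),
              class = "population_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
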