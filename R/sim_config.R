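#' Simulation configuration for WZY family and expression data
#'
#' Collects every knob of the synthetic-data generators in one validated list.
#' Defaults describe a realistic reduced-representation study of a frog-sized
#' genome with a ~10.3 Mb non-recombining sex-linked (SL) region at the start
#' of the sex chromosome: gametolog divergence is higher between W and Z or W
#' and Y than between Z and Y (the Y being recently derived from a Z), female
#' linkage maps are about 2.5x longer than male maps, male crossovers are
#' biased towards chromosome tips, parents are sequenced at about four times
#' offspring coverage, and heterozygous genotypes are occasionally miscalled
#' as homozygous.
#'
#' @param mother,father Parental sex-chromosome genotypes (default WZ x WY).
#' @param n_offspring Number of offspring per simulated family.
#' @param chromosomes Named numeric vector of chromosome lengths in bp. The
#'   first entry is the sex chromosome.
#' @param sex_chrom Name of the sex chromosome in `chromosomes`.
#' @param sl_start,sl_end Bounds (bp) of the sex-linked region on `sex_chrom`.
#' @param sex_locus_pos Position (bp) of the sex-determining locus; must lie
#'   inside the SL region.
#' @param female_map_cM,male_map_cM Per-chromosome map lengths in centimorgans
#'   for oogenesis and spermatogenesis.
#' @param male_tip_bias Shape parameter alpha of the symmetric Beta(alpha,
#'   alpha) crossover-position distribution used for male meiosis; alpha < 1
#'   pushes crossovers towards chromosome tips. Female positions are uniform.
#' @param suppress_W_recombination When `TRUE`, a parent carrying a W receives
#'   no crossovers inside the SL region (Z-Y recombination remains possible).
#' @param rad_density Expected RADtags per Mb.
#' @param snps_per_radtag_probs Probabilities of a RADtag carrying 0, 1 or 2
#'   SNPs.
#' @param depth_mean_offspring,depth_mean_parents Negative-binomial mean read
#'   depths (parents default to four times offspring).
#' @param depth_dispersion Negative-binomial size parameter for depth.
#' @param het_to_hom_error_rate Probability that a true heterozygous genotype
#'   is miscalled as one of the homozygotes (allelic dropout style).
#' @param missing_rate Probability a genotype is missing outright.
#' @param d_WZ,d_WY,d_ZY Per-bp divergence (expected heterozygosity) between
#'   haplotypes of the named chromosome types inside the SL region.
#' @param within_type_theta Per-bp polymorphism between two haplotypes of the
#'   same chromosome type (and of non-sex-linked sequence).
#' @param sl_diagnostic_frac Fraction of SL-region RAD SNPs that are fixed
#'   differences diagnostic for one chromosome type (the remainder behave as
#'   ordinary background SNPs).
#' @param n_transcripts_SL,n_transcripts_background Transcript counts for the
#'   expression generator.
#' @param transcript_callable_bp Mean callable bp per transcript per
#'   individual after RNA-seq genotype filters.
#' @param sl_male_bias_fraction Fraction of SL-region genes with male-biased
#'   expression.
#' @param sl_male_specific_fraction Of those, the fraction expressed only in
#'   males.
#' @param background_bias_fraction Per-gene probability of sex bias outside
#'   the SL region (direction random).
#' @param logfc_effect_range Range of |log2 fold change| for biased genes.
#' @param nb_dispersion Negative-binomial size for expression counts.
#' @param expr_depth_mean Mean depth used when site-level RNA-seq genotype
#'   calls are simulated.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(mother = "WZ", father = "WY",
                       n_offspring = 40,
                       chromosomes = c(chr7 = 133e6, chr1 = 217e6),
                       sex_chrom = names(chromosomes)[1],
                       sl_start = 0, sl_end = 10.3e6,
                       sex_locus_pos = 9.94e6,
                       female_map_cM = 90, male_map_cM = 36,
                       male_tip_bias = 0.4,
                       suppress_W_recombination = TRUE,
                       rad_density = 1.5,
                       snps_per_radtag_probs = c(0.3, 0.5, 0.2),
                       depth_mean_offspring = 30,
                       depth_mean_parents = 4 * depth_mean_offspring,
                       depth_dispersion = 8,
                       het_to_hom_error_rate = 0.02,
                       missing_rate = 0.03,
                       d_WZ = 0.010, d_WY = 0.010, d_ZY = 0.002,
                       within_type_theta = 5e-4,
                       sl_diagnostic_frac = 0.7,
                       n_transcripts_SL = 780,
                       n_transcripts_background = 2000,
                       transcript_callable_bp = 50,
                       sl_male_bias_fraction = 0.06,
                       sl_male_specific_fraction = 0.6,
                       background_bias_fraction = 0.01,
                       logfc_effect_range = c(2.5, 8),
                       nb_dispersion = 5,
                       expr_depth_mean = 20) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$chromosomes), length(cfg$chromosomes) >= 1,
            !is.null(names(cfg$chromosomes)), all(cfg$chromosomes > 0))
  if (!cfg$sex_chrom %in% names(cfg$chromosomes)) {
    stop("sex_chrom must name one of the chromosomes")
  }
  sex_len <- cfg$chromosomes[[cfg$sex_chrom]]
  if (cfg$sl_start < 0 || cfg$sl_end <= cfg$sl_start || cfg$sl_end > sex_len) {
    stop("sex-linked region must lie within the sex chromosome")
  }
  if (cfg$sex_locus_pos < cfg$sl_start || cfg$sex_locus_pos > cfg$sl_end) {
    stop("sex_locus_pos must lie inside the sex-linked region")
  }
  rates <- c(cfg$het_to_hom_error_rate, cfg$missing_rate, cfg$d_WZ, cfg$d_WY,
             cfg$d_ZY, cfg$within_type_theta, cfg$sl_diagnostic_frac,
             cfg$sl_male_bias_fraction, cfg$sl_male_specific_fraction,
             cfg$background_bias_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  pp <- sl_pattern_probs(cfg)
  if (any(pp < 0)) {
    stop("divergences d_WZ, d_WY, d_ZY violate the triangle conditions ",
         "(each pairwise divergence must not exceed the sum of the other two)")
  }
  if (sum(pp) > 1) stop("pattern probabilities exceed 1; reduce divergences")
  if (length(cfg$snps_per_radtag_probs) != 3 ||
      abs(sum(cfg$snps_per_radtag_probs) - 1) > 1e-8) {
    stop("snps_per_radtag_probs must be three probabilities summing to 1")
  }
  sex_of(cfg$mother); sex_of(cfg$father) # validates genotypes
  ce <- cross_expectation(cfg$mother, cfg$father)
  invisible(cfg)
}

## Per-site probabilities that exactly one chromosome type carries the derived
## allele: solving d_WZ = pW + pZ, d_WY = pW + pY, d_ZY = pZ + pY.
sl_pattern_probs <- function(cfg) {
  c(W = (cfg$d_WZ + cfg$d_WY - cfg$d_ZY) / 2,
    Z = (cfg$d_WZ + cfg$d_ZY - cfg$d_WY) / 2,
    Y = (cfg$d_WY + cfg$d_ZY - cfg$d_WZ) / 2)
}

## Divergence (expected per-bp heterozygosity) between the two haplotypes of a
## sex-chromosome genotype in the SL region.
sl_pair_divergence <- function(cfg, genotype) {
  switch(canonical_genotype(genotype),
         WZ = cfg$d_WZ, WY = cfg$d_WY, ZY = cfg$d_ZY,
         WW = cfg$within_type_theta, ZZ = cfg$within_type_theta,
         YY = cfg$within_type_theta)
}
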