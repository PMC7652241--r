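#' Quality-control configuration for family genotype data
#'
#' Thresholds for the family genotype filtering cascade. Boundary semantics:
#' a genotype is kept at DP exactly `min_dp` ("minimum depth") and at GQ
#' exactly `min_gq` (masked only when *below*); the missingness and
#' Mendelian-violation fractions are strict (`>`) cutoffs.
#'
#' @param min_dp Minimum per-genotype depth (inclusive).
#' @param min_gq Minimum genotype quality (genotypes below are masked).
#' @param max_offspring_missing_frac Drop a site when more than this fraction
#'   of offspring genotypes is missing.
#' @param hwe_alpha Exact Hardy-Weinberg test level applied to offspring
#'   genotype counts.
#' @param max_mendel_violation_frac Drop a site when more than this fraction
#'   of non-missing offspring genotypes is impossible given the parents.
#' @param max_individual_missing_frac Drop offspring with more than this
#'   fraction of missing genotypes; `NULL` disables the filter (as for a small
#'   family where it would be too aggressive).
#' @param thin_seed Seed for the one-SNP-per-RADtag random draw.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(min_dp = 15, min_gq = 20,
                      max_offspring_missing_frac = 0.20,
                      hwe_alpha = 0.01,
                      max_mendel_violation_frac = 0.10,
                      max_individual_missing_frac = 0.20,
                      thin_seed = 1L) {
  fr <- c(max_offspring_missing_frac, max_mendel_violation_frac)
  if (!is.null(max_individual_missing_frac)) {
    fr <- c(fr, max_individual_missing_frac)
  }
  stopifnot(all(fr >= 0 & fr <= 1), hwe_alpha > 0, hwe_alpha < 1,
            min_dp >= 0, min_gq >= 0)
  structure(as.list(environment())[c("min_dp", "min_gq",
                                     "max_offspring_missing_frac", "hwe_alpha",
                                     "max_mendel_violation_frac",
                                     "max_individual_missing_frac",
                                     "thin_seed")],
            class = "qc_config")
}

#' Mask low-quality genotypes
#'
#' Sets to missing any genotype whose depth is below `min_dp` or whose
#' genotype quality is below `min_gq`. Nothing else is altered.
#'
#' @param fd A [family_dataset()] with DP and GQ matrices.
#' @param min_dp,min_gq Thresholds (DP inclusive, GQ exclusive below).
#' @return The dataset with failing genotypes set to `NA`.
#' @export
mask_low_quality <- function(fd, min_dp = 15, min_gq = 20) {
  if (is.null(fd$dp) || is.null(fd$gq)) stop("dataset lacks DP/GQ matrices")
  bad <- fd$dp < min_dp | fd$gq < min_gq
  fd$geno[bad] <- NA_integer_
  attr(fd, "n_masked_low_quality") <- sum(bad & !is.na(bad))
  fd
}

#' Drop sites with too many missing offspring genotypes
#'
#' @param fd A [family_dataset()].
#' @param max_frac Strict threshold on the fraction of offspring with missing
#'   genotypes at a site.
#' @return The dataset restricted to passing sites.
#' @export
filter_offspring_missing_sites <- function(fd, max_frac = 0.20) {
  off <- offspring_ids(fd)
  miss_frac <- rowMeans(is.na(fd$geno[, off, drop = FALSE]))
  keep_sites(fd, miss_frac <= max_frac)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions given the
#' observed allele counts, computed by enumerating the probabilities of all
#' heterozygote counts compatible with the allele counts (via a numerically
#' stable recurrence) and summing those no more probable than the observation.
#' Monomorphic samples return p = 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return Two-sided exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab # minor-izing below
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1)
  ## heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  probs <- numeric(length(hets))
  ## start from the largest het count and recurse downwards:
  ## P(h-2)/P(h) = h*(h-1) / (4 * n_aa(h-2+..)*n_bb(...)) rearranged
  i0 <- length(hets)
  probs[i0] <- 1
  for (i in rev(seq_len(i0 - 1))) {
    h <- hets[i + 1]
    haa <- (n_a - h) / 2
    hbb <- (2 * n - n_a - h) / 2
    probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

#' Drop sites out of Hardy-Weinberg equilibrium among offspring
#'
#' @param fd A [family_dataset()].
#' @param alpha Exact-test level; sites with p < alpha among offspring are
#'   dropped. Sites with fewer than `min_n` non-missing offspring, or
#'   monomorphic sites, are retained untested.
#' @param min_n Minimum non-missing offspring genotypes for the test.
#' @return The dataset restricted to passing sites.
#' @export
hwe_filter <- function(fd, alpha = 0.01, min_n = 5) {
  off <- offspring_ids(fd)
  g <- fd$geno[, off, drop = FALSE]
  p <- vapply(seq_len(nrow(g)), function(i) {
    x <- g[i, ]
    x <- x[!is.na(x)]
    if (length(x) < min_n) return(1)
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  keep_sites(fd, p >= alpha)
}

## Offspring genotypes possible under Mendelian transmission for parental
## alt-dosages gm, gf (0/1/2): the set of sums of one allele from each parent.
mendelian_possible <- function(gm, gf) {
  am <- if (gm == 1) 0:1 else gm / 2
  af <- if (gf == 1) 0:1 else gf / 2
  unique(as.vector(outer(am, af, "+")))
}

#' Drop sites with an excess of Mendelian-impossible offspring genotypes
#'
#' A site is dropped when, among non-missing offspring genotypes, the fraction
#' that is impossible given the two parental genotypes exceeds `max_frac`
#' (such sites are typically heterozygous positions miscalled as homozygous).
#' Sites where either parental genotype is missing are passed through
#' untested.
#'
#' @param fd A [family_dataset()].
#' @param max_frac Strict threshold on the impossible-genotype fraction.
#' @return The dataset restricted to passing sites.
#' @export
mendelian_filter <- function(fd, max_frac = 0.10) {
  mo <- parent_id(fd, "mother"); fa <- parent_id(fd, "father")
  off <- offspring_ids(fd)
  viol <- vapply(seq_len(nrow(fd$geno)), function(i) {
    gm <- fd$geno[i, mo]; gf <- fd$geno[i, fa]
    if (is.na(gm) || is.na(gf)) return(0)
    x <- fd$geno[i, off]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(0)
    ok <- mendelian_possible(gm, gf)
    mean(!(x %in% ok))
  }, numeric(1))
  keep_sites(fd, viol <= max_frac)
}

#' Thin to one randomly selected SNP per RADtag
#'
#' @param fd A [family_dataset()] whose sites carry a `radtag` column.
#' @param seed Seed for the reproducible uniform draw.
#' @return The dataset with exactly one site per RADtag.
#' @export
thin_one_snp_per_radtag <- function(fd, seed = 1L) {
  if (is.null(fd$sites$radtag)) stop("sites lack RADtag ids")
  pick <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(fd$sites)), fd$sites$radtag), function(ix) {
      if (length(ix) == 1) ix else sample(ix, 1)
    }), use.names = FALSE)
  })
  keep <- logical(nrow(fd$sites))
  keep[pick] <- TRUE
  keep_sites(fd, keep)
}

#' Drop offspring with excessive missing data
#'
#' Removes offspring whose missing-genotype fraction strictly exceeds
#' `max_frac`; parents are never removed. Pass `max_frac = NULL` to disable
#' (the small-family mode).
#'
#' @param fd A [family_dataset()].
#' @param max_frac Strict threshold, or `NULL` to disable.
#' @return The dataset restricted to retained individuals.
#' @export
drop_high_missing_individuals <- function(fd, max_frac = 0.20) {
  if (is.null(max_frac)) return(fd)
  off <- offspring_ids(fd)
  miss <- colMeans(is.na(fd$geno[, off, drop = FALSE]))
  drop <- off[miss > max_frac]
  if (length(drop) == 0) return(fd)
  keep <- !fd$pedigree$id %in% drop
  fd$pedigree <- fd$pedigree[keep, , drop = FALSE]
  rownames(fd$pedigree) <- NULL
  fd$geno <- fd$geno[, fd$pedigree$id, drop = FALSE]
  if (!is.null(fd$dp)) fd$dp <- fd$dp[, fd$pedigree$id, drop = FALSE]
  if (!is.null(fd$gq)) fd$gq <- fd$gq[, fd$pedigree$id, drop = FALSE]
  fd
}

keep_sites <- function(fd, keep) {
  keep[is.na(keep)] <- FALSE
  fd$geno <- fd$geno[keep, , drop = FALSE]
  if (!is.null(fd$dp)) fd$dp <- fd$dp[keep, , drop = FALSE]
  if (!is.null(fd$gq)) fd$gq <- fd$gq[keep, , drop = FALSE]
  fd$sites <- fd$sites[keep, , drop = FALSE]
  rownames(fd$sites) <- NULL
  fd
}

#' Apply the full genotype quality-control cascade
#'
#' Runs, in order: low-quality genotype masking, offspring-missingness site
#' filter, Hardy-Weinberg site filter, Mendelian-consistency site filter,
#' one-SNP-per-RADtag thinning, and the high-missingness individual filter.
#' The cascade is idempotent.
#'
#' @param fd A [family_dataset()].
#' @param config A [qc_config()].
#' @return List with `dataset` (the filtered [family_dataset()]) and `report`
#'   (class `qc_report`): an ordered ledger of what each filter removed.
#' @export
apply_qc <- function(fd, config = qc_config()) {
  steps <- list()
  note <- function(name, before_sites, after_sites, before_ind, after_ind,
                   masked = 0L) {
    steps[[length(steps) + 1L]] <<- data.frame(
      filter = name, genotypes_masked = masked,
      sites_dropped = before_sites - after_sites,
      individuals_dropped = before_ind - after_ind,
      sites_remaining = after_sites, stringsAsFactors = FALSE)
  }

  s0 <- nrow(fd$geno); i0 <- ncol(fd$geno)
  fd <- mask_low_quality(fd, config$min_dp, config$min_gq)
  note("mask_low_quality", s0, nrow(fd$geno), i0, ncol(fd$geno),
       attr(fd, "n_masked_low_quality"))

  s0 <- nrow(fd$geno)
  fd <- filter_offspring_missing_sites(fd, config$max_offspring_missing_frac)
  note("offspring_missing_sites", s0, nrow(fd$geno), i0, ncol(fd$geno))

  s0 <- nrow(fd$geno)
  fd <- hwe_filter(fd, config$hwe_alpha)
  note("hwe", s0, nrow(fd$geno), i0, ncol(fd$geno))

  s0 <- nrow(fd$geno)
  fd <- mendelian_filter(fd, config$max_mendel_violation_frac)
  note("mendelian", s0, nrow(fd$geno), i0, ncol(fd$geno))

  s0 <- nrow(fd$geno)
  fd <- thin_one_snp_per_radtag(fd, config$thin_seed)
  note("thin_one_snp_per_radtag", s0, nrow(fd$geno), i0, ncol(fd$geno))

  s0 <- nrow(fd$geno)
  fd <- drop_high_missing_individuals(fd, config$max_individual_missing_frac)
  note("individual_missingness", s0, nrow(fd$geno), i0, ncol(fd$geno))

  report <- structure(list(steps = do.call(rbind, steps), config = config),
                      class = "qc_report")
  list(dataset = fd, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade report:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
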