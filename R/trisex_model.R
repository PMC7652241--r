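#' @keywords internal
"_PACKAGE"

## Canonical ordering of the three sex chromosome types. W < Z < Y is fixed so
## that genotype strings are reproducible keys ("WZ", never "ZW").
CHROM_TYPES <- c("W", "Z", "Y")

#' Canonical two-letter sex-chromosome genotype
#'
#' Sorts an unordered pair of chromosome types into the fixed W < Z < Y order,
#' so that e.g. `c("Z", "W")` and `"ZW"` both canonicalise to `"WZ"`.
#'
#' @param alleles Either a single two-letter string (e.g. `"ZW"`) or a
#'   character vector of exactly two chromosome types from `W`, `Z`, `Y`.
#' @return A single canonical genotype string.
#' @examples
#' canonical_genotype(c("Z", "W")) # "WZ"
#' canonical_genotype("YZ")        # "ZY"
#' @export
canonical_genotype <- function(alleles) {
  a <- genotype_alleles(alleles)
  paste(a[order(match(a, CHROM_TYPES))], collapse = "")
}

## Split "WZ" or c("W","Z") into a validated length-2 type vector.
genotype_alleles <- function(alleles) {
  if (is.character(alleles) && length(alleles) == 1L && nchar(alleles) == 2L) {
    alleles <- strsplit(alleles, "")[[1L]]
  }
  if (length(alleles) != 2L || !all(alleles %in% CHROM_TYPES)) {
    stop("a sex-chromosome genotype is an unordered pair from {W, Z, Y}; got: ",
         paste(alleles, collapse = ","))
  }
  alleles
}

#' Phenotypic sex of a sex-chromosome genotype
#'
#' Applies the dominance rule of the W/Z/Y system: any Y makes a male;
#' otherwise any W makes a female; otherwise (ZZ) male. So WW and WZ are
#' female while WY, ZY and ZZ are male. YY does not arise from natural
#' crosses (it would require a sex-reversed parent) but is classified male by
#' the same Y-dominance rule.
#'
#' @param genotype A genotype as accepted by [canonical_genotype()], or a
#'   character vector of two-letter genotype strings.
#' @return `"female"` or `"male"` (vectorised over genotype strings).
#' @examples
#' sex_of("WZ") # "female"
#' sex_of("ZY") # "male"
#' @export
sex_of <- function(genotype) {
  if (is.character(genotype) && length(genotype) > 1L && all(nchar(genotype) == 2L)) {
    return(vapply(genotype, sex_of, character(1), USE.NAMES = FALSE))
  }
  a <- genotype_alleles(genotype)
  if ("Y" %in% a) "male" else if ("W" %in% a) "female" else "male"
}

FEMALE_GENOTYPES <- c("WW", "WZ")
MALE_GENOTYPES <- c("WY", "ZY", "ZZ")

#' Enumerate all parental genotype combinations
#'
#' There are two possible sex-chromosome genotypes in females (WW, WZ) and
#' three in males (WY, ZY, ZZ), giving six possible parental combinations.
#'
#' @return A data frame with columns `mother` and `father` (canonical genotype
#'   strings), six rows, in canonical order.
#' @export
enumerate_crosses <- function() {
  out <- expand.grid(father = MALE_GENOTYPES, mother = FEMALE_GENOTYPES,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("mother", "father")]
  out <- out[order(match(out$mother, FEMALE_GENOTYPES),
                   match(out$father, MALE_GENOTYPES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Offspring expectations for a cross between two sex-chromosome genotypes
#'
#' Forms the four equiprobable gamete unions of a mother x father cross,
#' assigns sex to each offspring genotype by the dominance rule, and derives
#' the offspring genotype distribution, expected female fraction and the two
#' complete-linkage flags:
#'
#' * `complete_paternal_Y_linkage`: the father carries exactly one Y, every
#'   male offspring outcome received the paternal Y and no female outcome did,
#'   so paternal variation distinguishing his two haplotypes is passed to all
#'   sons and no daughters.
#' * `complete_maternal_W_linkage`: analogous for a maternal W inherited by
#'   all daughters and no sons.
#'
#' @param mother,father Genotype strings; the mother must be phenotypically
#'   female and the father male.
#' @return An object of class `cross_expectation`: a list with `mother`,
#'   `father`, `offspring` (named probability vector over canonical offspring
#'   genotypes), `outcomes` (data frame of maternal/paternal gamete, genotype,
#'   sex, probability), `female_fraction`, `male_per_female` (NA when no
#'   females are produced), and the two linkage flags.
#' @examples
#' cross_expectation("WZ", "ZY")$female_fraction # 0.25
#' @export
cross_expectation <- function(mother, father) {
  mother <- canonical_genotype(mother)
  father <- canonical_genotype(father)
  if (sex_of(mother) != "female") stop("mother genotype ", mother, " is not female")
  if (sex_of(father) != "male") stop("father genotype ", father, " is not male")

  mg <- genotype_alleles(mother)
  fg <- genotype_alleles(father)
  outcomes <- expand.grid(maternal = mg, paternal = fg,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  outcomes$genotype <- vapply(seq_len(nrow(outcomes)), function(i) {
    canonical_genotype(c(outcomes$maternal[i], outcomes$paternal[i]))
  }, character(1))
  outcomes$sex <- sex_of(outcomes$genotype)
  outcomes$prob <- 1 / 4

  offspring <- tapply(outcomes$prob, outcomes$genotype, sum)
  offspring <- offspring[order(names(offspring))]
  storage.mode(offspring) <- "double"

  female_fraction <- sum(outcomes$prob[outcomes$sex == "female"])

  pat_y <- sum(fg == "Y") == 1L &&
    all((outcomes$paternal == "Y") == (outcomes$sex == "male"))
  mat_w <- any(mg == "W") &&
    all((outcomes$maternal == "W") == (outcomes$sex == "female"))

  structure(list(
    mother = mother, father = father,
    offspring = c(offspring),
    outcomes = outcomes,
    female_fraction = female_fraction,
    male_per_female = if (female_fraction > 0) (1 - female_fraction) / female_fraction else NA_real_,
    complete_paternal_Y_linkage = pat_y,
    complete_maternal_W_linkage = mat_w
  ), class = "cross_expectation")
}

#' @export
print.cross_expectation <- function(x, ...) {
  cat(sprintf("Cross %s x %s\n", x$mother, x$father))
  for (g in names(x$offspring)) {
    cat(sprintf("  %s (%s): %s\n", g, sex_of(g), format(x$offspring[[g]])))
  }
  cat(sprintf("  female fraction: %s\n", format(x$female_fraction)))
  cat(sprintf("  complete paternal Y linkage: %s\n", x$complete_paternal_Y_linkage))
  cat(sprintf("  complete maternal W linkage: %s\n", x$complete_maternal_W_linkage))
  invisible(x)
}

#' Crosses with completely male-linked paternal variation
#'
#' @return The subset of [enumerate_crosses()] for which
#'   `complete_paternal_Y_linkage` is `TRUE` (three crosses: WZ x WY,
#'   WW x ZY, WW x WY).
#' @export
crosses_with_complete_paternal_linkage <- function() {
  crosses <- enumerate_crosses()
  keep <- vapply(seq_len(nrow(crosses)), function(i) {
    cross_expectation(crosses$mother[i], crosses$father[i])$complete_paternal_Y_linkage
  }, logical(1))
  crosses[keep, , drop = FALSE]
}

#' Crosses with completely female-linked maternal variation
#'
#' @return The subset of [enumerate_crosses()] for which
#'   `complete_maternal_W_linkage` is `TRUE` (WW x ZZ and WZ x ZZ).
#' @export
crosses_with_complete_maternal_linkage <- function() {
  crosses <- enumerate_crosses()
  keep <- vapply(seq_len(nrow(crosses)), function(i) {
    cross_expectation(crosses$mother[i], crosses$father[i])$complete_maternal_W_linkage
  }, logical(1))
  crosses[keep, , drop = FALSE]
}

#' Null probability of observing full sex-linkage by chance
#'
#' Probability, under a null in which every individual is independently
#' heterozygous with probability 1/2 regardless of sex, of observing a
#' heterozygous genotype in all individuals of one sex and in none of the
#' other: (1/2)^(n_het_sex + n_hom_sex). For 15 heterozygous males and 14
#' homozygous females this is below 2e-9.
#'
#' @param n_het_sex,n_hom_sex Non-negative counts of individuals observed
#'   heterozygous (one sex) and homozygous (the other sex).
#' @return A probability.
#' @export
null_full_linkage_probability <- function(n_het_sex, n_hom_sex) {
  if (n_het_sex < 0 || n_hom_sex < 0) stop("counts must be non-negative")
  0.5^(n_het_sex + n_hom_sex)
}

#' Sample offspring sex-chromosome genotypes from a cross
#'
#' Draws offspring by independent equal-probability gamete union, optionally
#' conditioning on a fixed number of each phenotypic sex (as when a study
#' deliberately samples a sex-balanced subset of a clutch).
#'
#' @param mother,father Parental genotype strings.
#' @param n Number of offspring (ignored when `n_female`/`n_male` given).
#' @param n_female,n_male Optional fixed counts per sex; genotypes are then
#'   drawn from the within-sex conditional distribution of the cross.
#' @param seed Optional integer seed (local to this call).
#' @return Data frame with columns `genotype` and `sex`.
#' @export
sample_offspring_genotypes <- function(mother, father, n = NULL,
                                       n_female = NULL, n_male = NULL,
                                       seed = NULL) {
  ce <- cross_expectation(mother, father)
  draw <- function() {
    if (!is.null(n_female) || !is.null(n_male)) {
      gt <- character(0)
      for (sx in c("female", "male")) {
        k <- if (sx == "female") n_female else n_male
        if (is.null(k) || k == 0) next
        p <- ce$offspring[sex_of(names(ce$offspring)) == sx]
        if (length(p) == 0) stop("cross ", ce$mother, " x ", ce$father,
                                 " produces no ", sx, " offspring")
        gt <- c(gt, sample(names(p), k, replace = TRUE, prob = p))
      }
    } else {
      if (is.null(n) || n < 1) stop("n must be a positive count")
      gt <- sample(names(ce$offspring), n, replace = TRUE, prob = ce$offspring)
    }
    data.frame(genotype = gt, sex = sex_of(gt), stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
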