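#' Construct a family genotype dataset
#'
#' Container for one family's pedigree and its site-by-individual genotype
#' matrix with per-genotype depth (DP) and genotype quality (GQ). Genotypes
#' are coded as alternate-allele counts (0, 1, 2) with `NA` for missing.
#'
#' @param pedigree Data frame with columns `id`, `family`, `role`
#'   (`mother`/`father`/`offspring`) and `sex` (`female`/`male`).
#' @param geno Integer matrix, sites x individuals, column names matching
#'   `pedigree$id`.
#' @param dp,gq Matrices of the same shape as `geno` (may be `NULL`).
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `radtag`,
#'   and optionally `ref`, `alt`.
#' @param truth Optional simulation truth block (true genotypes, sexes,
#'   crossovers, error and missingness masks).
#' @return An object of class `family_dataset`.
#' @export
family_dataset <- function(pedigree, geno, dp = NULL, gq = NULL, sites,
                           truth = NULL) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "family", "role", "sex") %in% names(pedigree)),
            all(pedigree$role %in% c("mother", "father", "offspring")),
            all(pedigree$sex %in% c("female", "male")),
            is.matrix(geno), is.data.frame(sites),
            all(c("chrom", "pos") %in% names(sites)),
            nrow(geno) == nrow(sites),
            identical(colnames(geno), pedigree$id))
  if (anyDuplicated(pedigree$id)) stop("duplicate individual ids")
  for (fam in unique(pedigree$family)) {
    roles <- pedigree$role[pedigree$family == fam]
    if (sum(roles == "mother") > 1 || sum(roles == "father") > 1) {
      stop("family ", fam, " has more than one mother or father")
    }
  }
  if (any(pedigree$role == "mother" & pedigree$sex != "female")) {
    stop("a mother must be phenotypically female")
  }
  if (any(pedigree$role == "father" & pedigree$sex != "male")) {
    stop("a father must be phenotypically male")
  }
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  structure(list(pedigree = pedigree, geno = geno, dp = dp, gq = gq,
                 sites = sites, truth = truth),
            class = "family_dataset")
}

#' @export
print.family_dataset <- function(x, ...) {
  cat(sprintf("family_dataset: %d sites x %d individuals (%d offspring)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$pedigree$role == "offspring")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing genotype fraction: %.3f\n", mean(is.na(x$geno))))
  if (!is.null(x$truth)) cat("  simulation truth attached\n")
  invisible(x)
}

offspring_ids <- function(fd) fd$pedigree$id[fd$pedigree$role == "offspring"]
parent_id <- function(fd, role) {
  id <- fd$pedigree$id[fd$pedigree$role == role]
  if (length(id) != 1) stop("expected exactly one ", role)
  id
}
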