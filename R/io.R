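#' Read biallelic SNPs from a VCF into genotype matrices
#'
#' Loads a VCF 4.x file (GT required; DP and GQ used when present), keeping
#' biallelic SNPs only. Multiallelic records are skipped and counted.
#' Positions are 1-based as in the VCF.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return List with `geno` (sites x individuals dosage matrix), `dp`, `gq`
#'   (or `NULL` when absent), `sites` (chrom, pos, radtag from the ID column,
#'   ref, alt) and `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  gt <- vcfR::extract.gt(v, "GT", IDtoRowNames = FALSE)
  conv <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- apply(gt, 2, conv)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  dp <- if ("DP" %in% fmt) {
    suppressWarnings(apply(vcfR::extract.gt(v, "DP", IDtoRowNames = FALSE),
                           2, as.integer))
  }
  gq <- if ("GQ" %in% fmt) {
    suppressWarnings(apply(vcfR::extract.gt(v, "GQ", IDtoRowNames = FALSE),
                           2, as.integer))
  }
  fixdim <- function(m) {
    if (!is.null(m) && is.null(dim(m))) {
      matrix(m, nrow = nrow(gt), dimnames = dimnames(gt))
    } else m
  }
  dp <- fixdim(dp); gq <- fixdim(gq)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      radtag = fix[, "ID"],
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  keep <- !multi
  list(geno = geno[keep, , drop = FALSE],
       dp = if (!is.null(dp)) dp[keep, , drop = FALSE],
       gq = if (!is.null(gq)) gq[keep, , drop = FALSE],
       sites = sites[keep, , drop = FALSE],
       n_multiallelic_skipped = sum(multi))
}

#' Write a family dataset as VCF 4.2
#'
#' Emits a plain-text VCF with GT:DP:GQ genotypes; RADtag ids go in the ID
#' column. Deterministic output: the same dataset always produces the same
#' bytes.
#'
#' @param fd A [family_dataset()] (or any list with `geno`, `dp`, `gq`,
#'   `sites` and ids as `geno` column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(fd, path) {
  ids <- colnames(fd$geno)
  gt_str <- matrix(".", nrow(fd$geno), ncol(fd$geno))
  gt_str[which(fd$geno == 0L)] <- "0/0"
  gt_str[which(fd$geno == 1L)] <- "0/1"
  gt_str[which(fd$geno == 2L)] <- "1/1"
  gt_str[gt_str == "."] <- "./."
  dp <- if (!is.null(fd$dp)) fd$dp else matrix(".", nrow(fd$geno), ncol(fd$geno))
  gq <- if (!is.null(fd$gq)) fd$gq else matrix(".", nrow(fd$geno), ncol(fd$geno))
  cells <- matrix(paste(gt_str, dp, gq, sep = ":"),
                  nrow(fd$geno), ncol(fd$geno))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trisexscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  ref <- if (!is.null(fd$sites$ref)) fd$sites$ref else "A"
  alt <- if (!is.null(fd$sites$alt)) fd$sites$alt else "T"
  body <- paste(fd$sites$chrom, format(fd$sites$pos, scientific = FALSE,
                                       trim = TRUE),
                if (!is.null(fd$sites$radtag)) fd$sites$radtag else ".",
                ref, alt, ".", "PASS", ".", "GT:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated pedigree/phenotype table with columns `id`, `family`, `role`
#' (`mother`, `father`, `offspring`, or `wild`) and `sex`. Validates that ids
#' are unique, sexes are `female`/`male`, each family has at most one mother
#' and one father, and parental roles match sex.
#'
#' @param path Path to a TSV file.
#' @return The validated data frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "family", "role", "sex")
  if (!all(need %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ss$id)) stop("duplicate sample ids in sample sheet")
  bad_sex <- setdiff(unique(ss$sex), c("female", "male"))
  if (length(bad_sex)) {
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         "; allowed: female, male")
  }
  bad_role <- setdiff(unique(ss$role), c("mother", "father", "offspring", "wild"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         "; allowed: mother, father, offspring, wild")
  }
  for (fam in unique(ss$family)) {
    r <- ss$role[ss$family == fam]
    if (sum(r == "mother") > 1) stop("family ", fam, " has two mothers")
    if (sum(r == "father") > 1) stop("family ", fam, " has two fathers")
  }
  if (any(ss$role == "mother" & ss$sex != "female")) {
    stop("a mother must have sex = female")
  }
  if (any(ss$role == "father" & ss$sex != "male")) {
    stop("a father must have sex = male")
  }
  ss
}

#' Assemble a family dataset from VCF and sample sheet
#'
#' @param vcf_path Path to the genotype VCF.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param family Family id to extract (default: the only family present).
#' @return A [family_dataset()].
#' @export
read_family_dataset <- function(vcf_path, sample_sheet_path, family = NULL) {
  vc <- read_vcf(vcf_path)
  ss <- read_sample_sheet(sample_sheet_path)
  if (is.null(family)) {
    fams <- unique(ss$family[ss$role != "wild"])
    if (length(fams) != 1) stop("specify one of the families: ",
                                paste(fams, collapse = ", "))
    family <- fams
  }
  ped <- ss[ss$family == family & ss$role != "wild", , drop = FALSE]
  missing_ids <- setdiff(ped$id, colnames(vc$geno))
  if (length(missing_ids)) {
    stop("sample sheet ids absent from VCF: ", paste(missing_ids, collapse = ", "))
  }
  rownames(ped) <- NULL
  family_dataset(ped, vc$geno[, ped$id, drop = FALSE],
                 if (!is.null(vc$dp)) vc$dp[, ped$id, drop = FALSE],
                 if (!is.null(vc$gq)) vc$gq[, ped$id, drop = FALSE],
                 vc$sites)
}

#' Write a sample sheet for a dataset
#'
#' @param fd A [family_dataset()] or `population_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(fd, path) {
  ss <- if (!is.null(fd$pedigree)) fd$pedigree else {
    data.frame(id = fd$samples$id, family = "wild", role = "wild",
               sex = fd$samples$sex, stringsAsFactors = FALSE)
  }
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript coordinates from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive `start`/`end` convention.
#'
#' @param path Path to a BED file (chrom, start, end, name, and optionally a
#'   fifth column with the gene id).
#' @return Data frame: transcript_id, gene_id, chrom, start, end, length_bp.
#' @export
read_transcript_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("transcript BED needs at least 4 columns")
  data.frame(transcript_id = bed[[4]],
             gene_id = if (ncol(bed) >= 5) bed[[5]] else bed[[4]],
             chrom = bed[[1]],
             start = bed[[2]] + 1L, end = bed[[3]],
             length_bp = bed[[3]] - bed[[2]],
             stringsAsFactors = FALSE)
}

#' Write transcript coordinates as BED (0-based half-open)
#'
#' @param transcripts Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `transcript_id`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_bed <- function(transcripts, path) {
  bed <- data.frame(transcripts$chrom,
                    format(transcripts$start - 1L, scientific = FALSE, trim = TRUE),
                    format(transcripts$end, scientific = FALSE, trim = TRUE),
                    transcripts$transcript_id, transcripts$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a region string
#'
#' @param x A string like `"chr7:0-10300000"`.
#' @return List with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9eE.+]+)-([0-9eE.+]+)$", x))[[1]]
  if (length(m) != 4) stop("malformed region: ", x, " (expected chrom:start-end)")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}
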