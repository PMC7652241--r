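#' Remove weakly expressed transcripts
#'
#' Discards transcripts whose mean raw count across individuals is strictly
#' below `min_mean` (default: less than one raw read per sample).
#'
#' @param counts Transcripts x individuals raw count matrix.
#' @param min_mean Minimum mean raw count (kept when mean >= `min_mean`).
#' @return The filtered count matrix.
#' @export
prefilter_counts <- function(counts, min_mean = 1) {
  counts[rowMeans(counts) >= min_mean, , drop = FALSE]
}

#' Transcripts-per-million normalisation
#'
#' Length-corrected within-sample normalisation: each count is divided by the
#' transcript length in kb, and rates are rescaled so that each individual's
#' column sums to one million.
#'
#' @param counts Transcripts x individuals raw count matrix.
#' @param lengths_bp Transcript lengths in bp (> 0), aligned with rows.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths_bp) {
  stopifnot(length(lengths_bp) == nrow(counts), all(lengths_bp > 0))
  rate <- counts / (lengths_bp / 1e3)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("individual(s) with zero total expression: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Log2 male/female expression ratio with a prior count
#'
#' `log2((m + prior) / (f + prior))`; positive values reflect male-biased
#' expression. The prior avoids zero or undefined ratios.
#'
#' @param mean_norm_male,mean_norm_female Non-negative normalised means.
#' @param prior Prior count added to both means (default 0.125).
#' @return log2 fold changes (vectorised).
#' @export
logfc <- function(mean_norm_male, mean_norm_female, prior = 0.125) {
  stopifnot(all(mean_norm_male >= 0), all(mean_norm_female >= 0), prior >= 0)
  log2((mean_norm_male + prior) / (mean_norm_female + prior))
}

#' Call sex-biased expression classes
#'
#' Classifies each transcript as `male_specific`, `male_biased`,
#' `female_specific`, `female_biased` or `unbiased`. A transcript is
#' significant when its FDR q-value is below `fdr_alpha` *and* |logFC| exceeds
#' `logfc_min`; a significant transcript is `*_specific` when every individual
#' of the minor sex has a raw count of zero, otherwise `*_biased`.
#'
#' The differential-expression evidence comes either from an external table
#' (`de_table` with columns `transcript_id`, `logFC`, `FDR`, e.g. an edgeR
#' exact-test output) — the canonical path — or, as an internal approximation,
#' from a two-sided Welch t-test on log2(TPM + prior) with BH FDR. Transcripts
#' absent from an external table are called `unbiased` and flagged.
#'
#' @param counts Prefiltered raw count matrix (transcripts x individuals).
#' @param meta Transcript metadata with `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `length_bp` (rows aligned with `counts`).
#' @param sexes Per-individual sex labels (`female`/`male`).
#' @param de_table Optional external DE table; when `NULL` the internal Welch
#'   test is used.
#' @param fdr_alpha FDR cutoff (default 0.05).
#' @param logfc_min Minimum |logFC| (strict; default 2).
#' @param prior Prior count for the internal logFC (default 0.125).
#' @return Data frame of class `expression_records`: metadata plus
#'   `mean_count`, `log_fc`, `q`, `bias_class`, `missing_from_de`.
#' @export
call_bias <- function(counts, meta, sexes, de_table = NULL,
                      fdr_alpha = 0.05, logfc_min = 2, prior = 0.125) {
  stopifnot(nrow(counts) == nrow(meta),
            all(sexes %in% c("female", "male")),
            length(sexes) == ncol(counts))
  male <- sexes == "male"
  if (sum(male) < 2 || sum(!male) < 2) {
    stop("at least two individuals of each sex are required")
  }

  missing_from_de <- rep(FALSE, nrow(meta))
  if (!is.null(de_table)) {
    stopifnot(all(c("transcript_id", "logFC", "FDR") %in% names(de_table)))
    m <- match(meta$transcript_id, de_table$transcript_id)
    lfc <- de_table$logFC[m]
    q <- de_table$FDR[m]
    missing_from_de <- is.na(m)
    if (any(missing_from_de)) {
      warning(sum(missing_from_de),
              " transcript(s) missing from the DE table; called unbiased")
    }
  } else {
    x <- log2(tpm(counts, meta$length_bp) + prior)
    xm <- x[, male, drop = FALSE]; xf <- x[, !male, drop = FALSE]
    mm <- rowMeans(xm); mf <- rowMeans(xf)
    vm <- apply(xm, 1, stats::var); vf <- apply(xf, 1, stats::var)
    nm <- ncol(xm); nf <- ncol(xf)
    se2 <- vm / nm + vf / nf
    tstat <- (mm - mf) / sqrt(se2)
    df <- se2^2 / ((vm / nm)^2 / (nm - 1) + (vf / nf)^2 / (nf - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(p)] <- 1
    q <- stats::p.adjust(p, method = "BH")
    lfc <- logfc(rowMeans(tpm(counts, meta$length_bp)[, male, drop = FALSE]),
                 rowMeans(tpm(counts, meta$length_bp)[, !male, drop = FALSE]),
                 prior)
  }

  sig <- !missing_from_de & !is.na(q) & !is.na(lfc) &
    q < fdr_alpha & abs(lfc) > logfc_min
  zero_f <- rowSums(counts[, !male, drop = FALSE]) == 0
  zero_m <- rowSums(counts[, male, drop = FALSE]) == 0
  bias <- rep("unbiased", nrow(meta))
  bias[sig & lfc > 0] <- ifelse(zero_f[sig & lfc > 0], "male_specific",
                                "male_biased")
  bias[sig & lfc < 0] <- ifelse(zero_m[sig & lfc < 0], "female_specific",
                                "female_biased")

  out <- cbind(meta,
               data.frame(mean_count = rowMeans(counts),
                          log_fc = lfc, q = q, bias_class = bias,
                          missing_from_de = missing_from_de,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("expression_records", "data.frame")
  out
}

#' Density of sex-biased transcripts in a genomic region
#'
#' Counts significant transcripts of the requested bias classes whose start
#' coordinate lies in the region, per Mb of region length. Transcript-to-region
#' assignment is by start coordinate.
#'
#' @param records Output of [call_bias()].
#' @param region List or vector with `chrom`, `start`, `end` (bp, 1-based
#'   inclusive bounds; `end > start`).
#' @param bias_classes Classes to count (default: both male classes).
#' @return Transcripts per Mb (full precision; round only for reporting).
#' @export
region_density <- function(records, region,
                           bias_classes = c("male_specific", "male_biased")) {
  region <- as.list(region)
  start <- as.numeric(region$start); end <- as.numeric(region$end)
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("region must have end > start")
  }
  inside <- records$chrom == region$chrom &
    records$start >= start & records$start <= end
  n <- sum(inside & records$bias_class %in% bias_classes)
  n / ((end - start) / 1e6)
}

#' Exact binomial enrichment test for a region's bias composition
#'
#' Upper-tail exact binomial probability that at least `x_region` of the
#' `n_region` significant transcripts in a region share one direction of bias,
#' when the expected proportion is taken from the rest of the genome:
#' `p0 = male_rest / (male_rest + female_rest)`.
#'
#' @param x_region Transcripts with the focal bias direction in the region.
#' @param n_region All sex-biased transcripts in the region (>= `x_region`).
#' @param male_rest,female_rest Counts of each direction outside the region.
#' @return Exact upper-tail p-value `P(X >= x_region)`.
#' @export
binomial_enrichment <- function(x_region, n_region, male_rest, female_rest) {
  stopifnot(x_region >= 0, n_region >= x_region)
  if (male_rest + female_rest == 0) {
    stop("no sex-biased transcripts outside the region to estimate p0")
  }
  p0 <- male_rest / (male_rest + female_rest)
  stats::pbinom(x_region - 1, n_region, p0, lower.tail = FALSE)
}

#' Region enrichment summary
#'
#' Tabulates bias classes inside and outside a region, the region density of
#' the focal classes, and the exact binomial enrichment p-value of the focal
#' direction against the rest-of-genome proportion.
#'
#' @param records Output of [call_bias()].
#' @param region As in [region_density()].
#' @param direction `"male"` or `"female"`: which bias direction to test.
#' @return List of class `region_enrichment`: `region`, `counts_inside`,
#'   `counts_outside`, `density_per_mb`, `p_binomial`, `enrichment_ratio`
#'   (region density of the focal classes over rest-of-genome density).
#' @export
region_enrichment <- function(records, region, direction = c("male", "female")) {
  direction <- match.arg(direction)
  region <- as.list(region)
  classes <- paste0(direction, c("_specific", "_biased"))
  other <- paste0(setdiff(c("male", "female"), direction), c("_specific", "_biased"))
  inside <- records$chrom == region$chrom &
    records$start >= as.numeric(region$start) &
    records$start <= as.numeric(region$end)
  sig <- records$bias_class != "unbiased"
  ci <- table(factor(records$bias_class[inside & sig],
                     levels = c(classes, other)))
  co <- table(factor(records$bias_class[!inside & sig],
                     levels = c(classes, other)))
  x <- sum(ci[classes]); n <- sum(ci)
  mrest <- sum(co[classes]); frest <- sum(co[other])
  dens <- region_density(records, region, classes)
  region_mb <- (as.numeric(region$end) - as.numeric(region$start)) / 1e6
  rest_mb <- attr(records, "genome_mb")
  ratio <- if (!is.null(rest_mb) && mrest > 0) {
    dens / (mrest / (rest_mb - region_mb))
  } else NA_real_
  structure(list(region = region,
                 counts_inside = c(ci), counts_outside = c(co),
                 density_per_mb = dens,
                 p_binomial = if (n > 0 && mrest + frest > 0) {
                   binomial_enrichment(x, n, mrest, frest)
                 } else NA_real_,
                 enrichment_ratio = ratio),
            class = "region_enrichment")
}

#' @export
print.region_enrichment <- function(x, ...) {
  cat(sprintf("region %s:%s-%s\n", x$region$chrom,
              format(x$region$start, big.mark = ","),
              format(x$region$end, big.mark = ",")))
  cat("  inside: ", paste(names(x$counts_inside), x$counts_inside,
                          sep = "=", collapse = ", "), "\n")
  cat(sprintf("  density: %.1f transcripts/Mb; binomial p = %.3g\n",
              x$density_per_mb, x$p_binomial))
  invisible(x)
}
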