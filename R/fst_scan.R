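#' Per-site Weir-Cockerham FST between two groups
#'
#' Single-locus Weir and Cockerham (1984) theta for two groups of diploids,
#' computed from genotype dosages (0/1/2, NA missing). The estimator uses the
#' among-population (a), among-individual (b) and within-individual (c)
#' variance components and may be slightly negative. Sites that are
#' monomorphic across both groups, or with fewer than `min_per_group`
#' non-missing genotypes in either group, return `NA`. A Hudson-style
#' estimator (1 - Hw/Hb on allele frequencies) is available as an alternative.
#'
#' @param geno Sites x individuals dosage matrix (a vector is treated as one
#'   site).
#' @param groups Character/factor vector of length `ncol(geno)` with exactly
#'   two levels (e.g. phenotypic sex).
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @param min_per_group Minimum non-missing genotypes per group.
#' @return Numeric vector of per-site FST.
#' @export
fst_per_site <- function(geno, groups, estimator = c("wc", "hudson"),
                         min_per_group = 2) {
  estimator <- match.arg(estimator)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  groups <- as.character(groups)
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2) stop("exactly two groups are required")
  g1 <- geno[, groups == lev[1], drop = FALSE]
  g2 <- geno[, groups == lev[2], drop = FALSE]

  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  pbar_all <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
  bad <- n1 < min_per_group | n2 < min_per_group |
    is.na(pbar_all) | pbar_all <= 0 | pbar_all >= 1

  if (estimator == "hudson") {
    hw <- (2 * p1 * (1 - p1) * 2 * n1 / (2 * n1 - 1) +
             2 * p2 * (1 - p2) * 2 * n2 / (2 * n2 - 1)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- 1 - hw / hb
  } else {
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    fst <- a / (a + b + cc)
  }
  fst[bad] <- NA_real_
  fst
}

#' Moving-average windows over per-site FST
#'
#' Means of runs of exactly `window_size` consecutive SNPs (after removing
#' sites with undefined FST), stepping by `step` SNPs; windows never span
#' chromosomes and trailing partial windows are excluded. The window
#' coordinate is the median SNP position.
#'
#' @param sites Data frame with `chrom` and `pos`, ordered within chromosome.
#' @param fst Per-site FST values aligned with `sites` (NAs dropped).
#' @param window_size Number of SNPs per window (default 50).
#' @param step Step between window starts in SNPs (default 1).
#' @return Data frame: chrom, center, start, end (bp), fst (window mean),
#'   n_snps.
#' @export
moving_window_fst <- function(sites, fst, window_size = 50, step = 1) {
  stopifnot(nrow(sites) == length(fst), window_size >= 1, step >= 1)
  ok <- !is.na(fst)
  sites <- sites[ok, , drop = FALSE]
  fst <- fst[ok]
  out <- lapply(unique(sites$chrom), function(chrom) {
    idx <- which(sites$chrom == chrom)
    m <- length(idx)
    if (m < window_size) {
      warning("chromosome ", chrom, " has fewer than ", window_size,
              " usable SNPs; no windows")
      return(NULL)
    }
    pos <- sites$pos[idx]
    v <- fst[idx]
    starts <- seq(1L, m - window_size + 1L, by = step)
    cs <- cumsum(c(0, v))
    means <- (cs[starts + window_size] - cs[starts]) / window_size
    centers <- vapply(starts, function(s) {
      stats::median(pos[s:(s + window_size - 1L)])
    }, numeric(1))
    data.frame(chrom = chrom, center = centers,
               start = pos[starts], end = pos[starts + window_size - 1L],
               fst = means, n_snps = window_size, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Autosomal null band for windowed FST
#'
#' Reference band from autosomal window values, either as a bootstrap
#' confidence interval for the mean (B resamples, 2.5/97.5 percentiles of the
#' resampled means) or as the 2.5/97.5 percentile envelope of the window
#' values themselves.
#'
#' @param windows Output of [moving_window_fst()].
#' @param sex_chrom Chromosome(s) to exclude as sex-linked.
#' @param mode `"bootstrap-mean"` or `"envelope"`.
#' @param B Bootstrap resamples (>= 100) for the bootstrap-mean mode.
#' @param seed Optional seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
autosomal_band <- function(windows, sex_chrom, mode = c("bootstrap-mean", "envelope"),
                           B = 1000, seed = NULL) {
  mode <- match.arg(mode)
  vals <- windows$fst[!windows$chrom %in% sex_chrom]
  if (length(vals) == 0) stop("no autosomal windows")
  if (mode == "envelope") {
    q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  } else {
    if (B < 100) stop("B must be at least 100")
    boot <- function() {
      means <- vapply(seq_len(B), function(i) {
        mean(sample(vals, length(vals), replace = TRUE))
      }, numeric(1))
      stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
    }
    q <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  }
  c(lo = q[1], hi = q[2])
}

#' Peak window of an FST track
#'
#' @param windows Output of [moving_window_fst()].
#' @return One-row data frame with the maximal window; ties broken by the
#'   smallest (chrom, pos).
#' @export
find_peak <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0) stop("no windows")
  ord <- order(-windows$fst, match(windows$chrom, unique(windows$chrom)),
               windows$center)
  out <- windows[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-sex FST genome scan
#'
#' Per-site Weir-Cockerham FST between phenotypic females and males, a moving
#' average over `window_size` SNPs, the autosomal null band, and the genome
#' peak.
#'
#' @param geno Sites x individuals dosage matrix.
#' @param sites Matching site data frame (`chrom`, `pos`).
#' @param sexes Per-individual sex labels.
#' @param sex_chrom Sex chromosome name(s), excluded from the band.
#' @param window_size,step Moving-window parameters.
#' @param band_mode `"bootstrap-mean"` or `"envelope"`.
#' @param B,seed Bootstrap controls.
#' @param estimator Per-site estimator, `"wc"` or `"hudson"`.
#' @return List of class `fst_track`: `per_site` (sites + fst), `windows`,
#'   `band`, `peak`, `estimator`.
#' @export
fst_scan <- function(geno, sites, sexes, sex_chrom, window_size = 50, step = 1,
                     band_mode = "bootstrap-mean", B = 1000, seed = NULL,
                     estimator = "wc") {
  fst <- fst_per_site(geno, sexes, estimator = estimator)
  windows <- moving_window_fst(sites, fst, window_size, step)
  band <- autosomal_band(windows, sex_chrom, band_mode, B = B, seed = seed)
  structure(list(per_site = cbind(sites[, c("chrom", "pos")], fst = fst),
                 windows = windows, band = band,
                 peak = find_peak(windows), estimator = estimator),
            class = "fst_track")
}

#' @export
print.fst_track <- function(x, ...) {
  cat(sprintf("fst_track (%s): %d windows, band [%.4f, %.4f]\n",
              x$estimator, nrow(x$windows), x$band[1], x$band[2]))
  cat(sprintf("  peak: %s:%d fst = %.4f\n",
              x$peak$chrom, round(x$peak$center), x$peak$fst))
  invisible(x)
}
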