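#' Extract parent-informative sites and offspring inheritance states
#'
#' For a parent-of-origin scan, a site is informative when the focal parent is
#' heterozygous and the other parent homozygous. Each offspring genotype is
#' then recoded to the allele inherited from the focal parent (state 0 or 1);
#' genotypes that are impossible under that configuration, or missing, become
#' missing states.
#'
#' @param fd A (QC'd) [family_dataset()].
#' @param parent `"father"` or `"mother"`: whose heterozygous sites to scan.
#' @return Object of class `informative_sites`: list with `parent`, `sites`
#'   (chrom, pos of informative sites, physically ordered), `states` (sites x
#'   offspring integer matrix in {0, 1, NA}), `offspring` and `sexes`.
#' @export
extract_informative_sites <- function(fd, parent = c("father", "mother")) {
  parent <- match.arg(parent)
  focal <- parent_id(fd, parent)
  other <- parent_id(fd, setdiff(c("mother", "father"), parent))
  off <- offspring_ids(fd)

  gfoc <- fd$geno[, focal]
  goth <- fd$geno[, other]
  keep <- !is.na(gfoc) & !is.na(goth) & gfoc == 1L & goth %in% c(0L, 2L)
  if (!any(keep)) {
    warning("no informative sites for the ", parent)
  }
  states <- fd$geno[keep, off, drop = FALSE]
  goth <- goth[keep]
  ## inherited focal-parent allele = offspring dosage minus the (constant)
  ## allele contributed by the homozygous parent; anything else is impossible
  states <- sweep(states, 1, goth / 2L)
  states[!(states %in% c(0, 1))] <- NA
  storage.mode(states) <- "integer"

  sites <- fd$sites[keep, c("chrom", "pos"), drop = FALSE]
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  structure(list(parent = parent,
                 sites = {
                   s <- sites[ord, , drop = FALSE]; rownames(s) <- NULL; s
                 },
                 states = states[ord, , drop = FALSE],
                 offspring = off,
                 sexes = fd$pedigree$sex[match(off, fd$pedigree$id)],
                 phased = FALSE),
            class = "informative_sites")
}

#' @export
print.informative_sites <- function(x, ...) {
  cat(sprintf("informative_sites (%s): %d sites x %d offspring%s\n",
              x$parent, nrow(x$states), ncol(x$states),
              if (isTRUE(x$phased)) ", phased" else ""))
  invisible(x)
}

#' Phase inheritance states along each chromosome
#'
#' Chooses the relative phase of adjacent markers that minimises the implied
#' number of recombinants summed over offspring, walking each chromosome in
#' physical order. The first marker's phase is arbitrary; on a tie the current
#' phase is kept.
#'
#' @param iss An `informative_sites` object.
#' @return The object with states recoded to a consistent phase and
#'   `phased = TRUE`.
#' @export
phase_states <- function(iss) {
  st <- iss$states
  for (chrom in unique(iss$sites$chrom)) {
    idx <- which(iss$sites$chrom == chrom)
    if (length(idx) < 2) next
    prev <- st[idx[1], ]
    for (k in idx[-1]) {
      cur <- st[k, ]
      both <- !is.na(prev) & !is.na(cur)
      mism <- sum(prev[both] != cur[both])
      conc <- sum(both) - mism
      ## flip the current marker when that reduces implied recombinants;
      ## ties keep the current coding
      if (mism > conc) st[k, ] <- 1L - cur
      ## compare against the (possibly flipped) current marker next round
      if (any(!is.na(st[k, ]))) prev <- st[k, ]
    }
  }
  iss$states <- st
  iss$phased <- TRUE
  iss
}

#' Mask double-recombinant state runs as putative genotyping errors
#'
#' Within each offspring and chromosome, any maximal run of identical
#' inheritance state that is flanked on both sides by the opposite state and
#' whose flank-to-flank physical span is at most `window_bp` implies two
#' crossovers in a small window; such runs are far more likely to be
#' genotyping errors and are set to missing. The procedure iterates to a
#' fixed point. Runs touching a chromosome end are never masked.
#'
#' @param iss A phased `informative_sites` object.
#' @param window_bp Maximum flank-to-flank span of a masked run (default
#'   10 Mb).
#' @return The object with masked states, plus attribute `n_masked`.
#' @export
mask_double_recombinants <- function(iss, window_bp = 1e7) {
  if (!isTRUE(iss$phased)) stop("states must be phased first (phase_states)")
  st <- iss$states
  n_masked <- 0L
  for (chrom in unique(iss$sites$chrom)) {
    idx <- which(iss$sites$chrom == chrom)
    pos <- iss$sites$pos[idx]
    for (j in seq_len(ncol(st))) {
      repeat {
        obs <- which(!is.na(st[idx, j]))
        if (length(obs) < 3) break
        s <- st[idx[obs], j]
        r <- rle(s)
        if (length(r$lengths) < 3) break
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        masked_any <- FALSE
        for (k in seq_along(r$lengths)[-c(1, length(r$lengths))]) {
          left_flank <- pos[obs[ends[k - 1]]]
          right_flank <- pos[obs[starts[k + 1]]]
          if (right_flank - left_flank <= window_bp) {
            st[idx[obs[starts[k]:ends[k]]], j] <- NA_integer_
            n_masked <- n_masked + r$lengths[k]
            masked_any <- TRUE
          }
        }
        if (!masked_any) break
      }
    }
  }
  iss$states <- st
  attr(iss, "n_masked") <- n_masked
  iss
}

#' Exact conditional two-by-two association p-value
#'
#' Conditional (hypergeometric) exact test for a 2x2 table, two-sided by
#' doubling the smaller tail (capped at 1). Vectorised over tables.
#'
#' @param x Count in cell (state 1, group 1).
#' @param k Total state-1 count (row margin).
#' @param n Total count.
#' @param g1 Group-1 size (column margin).
#' @return Two-sided p-values.
#' @export
exact_2x2_p <- function(x, k, n, g1) {
  lower <- stats::phyper(x, k, n - k, g1)
  upper <- stats::phyper(x - 1, k, n - k, g1, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Test association between inheritance state and offspring sex
#'
#' Per site, tabulates phased inheritance state against phenotypic sex and
#' computes a two-sided exact conditional p-value (doubled-tail hypergeometric;
#' a chi-squared approximation is available), then optionally applies
#' Benjamini-Hochberg FDR across sites. Sites with no scoreable offspring get
#' p = 1 and are flagged.
#'
#' @param iss An `informative_sites` object (phased and masked, normally).
#' @param apply_fdr Compute BH q-values across the scanned sites.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return Data frame of class `sexlink_result`: chrom, pos, parent, the four
#'   state-by-sex counts, `n_masked` states, `p` and (optionally) `q`.
#' @export
test_sex_association <- function(iss, apply_fdr = TRUE,
                                 method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (length(unique(iss$sexes)) < 2) {
    stop("offspring of both sexes are required")
  }
  male <- iss$sexes == "male"
  st <- iss$states
  n1m <- rowSums(st[, male, drop = FALSE] == 1L, na.rm = TRUE)
  n0m <- rowSums(st[, male, drop = FALSE] == 0L, na.rm = TRUE)
  n1f <- rowSums(st[, !male, drop = FALSE] == 1L, na.rm = TRUE)
  n0f <- rowSums(st[, !male, drop = FALSE] == 0L, na.rm = TRUE)
  n <- n1m + n0m + n1f + n0f

  if (method == "exact") {
    p <- exact_2x2_p(x = n1m, k = n1m + n1f, n = n, g1 = n1m + n0m)
  } else {
    p <- vapply(seq_along(n1m), function(i) {
      tab <- matrix(c(n1m[i], n0m[i], n1f[i], n0f[i]), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }, numeric(1))
  }
  p[n == 0] <- 1

  out <- data.frame(chrom = iss$sites$chrom, pos = iss$sites$pos,
                    parent = iss$parent,
                    het_male = n1m, hom_male = n0m,
                    het_female = n1f, hom_female = n0f,
                    n_scored = n, all_missing = n == 0,
                    p = p, stringsAsFactors = FALSE)
  if (apply_fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("sexlink_result", "data.frame")
  out
}

#' Run the full parent-of-origin sex-linkage scan
#'
#' Convenience wrapper: extract informative sites, phase, mask double
#' recombinants, and test association with sex.
#'
#' @param fd A (QC'd) [family_dataset()].
#' @param parent `"father"` or `"mother"`.
#' @param window_bp Double-recombinant masking window (bp); `NULL` disables
#'   masking.
#' @param apply_fdr Apply BH FDR across sites (skip for very small families).
#' @param method Association test, `"exact"` or `"chisq"`.
#' @return A `sexlink_result` data frame (see [test_sex_association()]).
#' @export
sex_linkage_scan <- function(fd, parent = c("father", "mother"),
                             window_bp = 1e7, apply_fdr = TRUE,
                             method = "exact") {
  iss <- extract_informative_sites(fd, match.arg(parent))
  iss <- phase_states(iss)
  if (!is.null(window_bp)) iss <- mask_double_recombinants(iss, window_bp)
  test_sex_association(iss, apply_fdr = apply_fdr, method = method)
}
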