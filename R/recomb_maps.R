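#' Kosambi map distance
#'
#' Converts a recombination fraction to centimorgans with the Kosambi mapping
#' function, d = 25 ln((1 + 2r) / (1 - 2r)) cM, which partially accounts for
#' crossover interference.
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @return Map distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fractions must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Haldane map distance
#'
#' d = -50 ln(1 - 2r) cM (no interference).
#'
#' @inheritParams kosambi_cm
#' @return Map distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fractions must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Per-interval recombination fractions from phased inheritance states
#'
#' For each pair of physically adjacent informative markers, the recombination
#' fraction is the number of offspring whose (masked, phased) inheritance
#' state flips between them, divided by the number of offspring scored at
#' both. Marker pairs with fewer than `min_informative` scoreable offspring
#' are merged into the next interval.
#'
#' @param iss A phased (and normally masked) `informative_sites` object.
#' @param min_informative Minimum scored offspring per interval (default 5).
#' @return Data frame: chrom, start_pos, end_pos, n_informative,
#'   n_recombinant, r.
#' @export
interval_recombination_fractions <- function(iss, min_informative = 5) {
  if (!isTRUE(iss$phased)) stop("states must be phased first (phase_states)")
  st <- iss$states
  out <- lapply(unique(iss$sites$chrom), function(chrom) {
    idx <- which(iss$sites$chrom == chrom)
    if (length(idx) < 2) return(NULL)
    pos <- iss$sites$pos[idx]
    rows <- list()
    a <- 1L
    b <- 2L
    while (b <= length(idx)) {
      sa <- st[idx[a], ]; sb <- st[idx[b], ]
      both <- !is.na(sa) & !is.na(sb)
      if (sum(both) < min_informative && b < length(idx)) {
        b <- b + 1L
        next
      }
      if (sum(both) >= min_informative) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start_pos = pos[a], end_pos = pos[b],
          n_informative = sum(both),
          n_recombinant = sum(sa[both] != sb[both]),
          stringsAsFactors = FALSE)
        a <- b
      }
      b <- b + 1L
    }
    if (length(rows) == 0) return(NULL)
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), n_informative = integer(),
                      n_recombinant = integer(), r = numeric()))
  }
  out$r <- out$n_recombinant / out$n_informative
  out
}

#' Build a sex-specific linkage map for one parent
#'
#' Extracts the focal parent's informative markers, phases them, masks double
#' recombinants within `window_bp`, estimates per-interval recombination
#' fractions in physical marker order, and converts them to map distances.
#' Recombination fractions at or above 0.5 are truncated just below 0.5 (the
#' mapping functions diverge there; such intervals reflect effectively
#' unlinked markers).
#'
#' @param fd A (QC'd) [family_dataset()].
#' @param parent `"mother"` (female map) or `"father"` (male map).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param window_bp Double-recombinant masking window; `NULL` disables.
#' @param min_informative Minimum scored offspring per interval.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp) for
#'   percent-covered reporting.
#' @return Object of class `sex_specific_map`: `intervals` (with cM),
#'   `per_chromosome` (chrom, n_markers, bp_covered, total_cM,
#'   pct_covered), `parent`, `mapping_function`, and `iss` (the masked states,
#'   for crossover localisation).
#' @export
build_linkage_map <- function(fd, parent = c("mother", "father"),
                              mapping_function = c("kosambi", "haldane"),
                              window_bp = 1e7, min_informative = 5,
                              chrom_lengths = NULL) {
  parent <- match.arg(parent)
  mapping_function <- match.arg(mapping_function)
  iss <- phase_states(extract_informative_sites(fd, parent))
  if (!is.null(window_bp)) iss <- mask_double_recombinants(iss, window_bp)
  intervals <- interval_recombination_fractions(iss, min_informative)
  fn <- if (mapping_function == "kosambi") kosambi_cm else haldane_cm
  intervals$cM <- fn(pmin(intervals$r, 0.5 - 1e-9))

  per_chrom <- do.call(rbind, lapply(unique(iss$sites$chrom), function(chrom) {
    idx <- iss$sites$chrom == chrom
    ivl <- intervals[intervals$chrom == chrom, , drop = FALSE]
    bp <- if (sum(idx) >= 2) diff(range(iss$sites$pos[idx])) else 0
    data.frame(chrom = chrom, n_markers = sum(idx), bp_covered = bp,
               total_cM = sum(ivl$cM),
               pct_covered = if (!is.null(chrom_lengths) &&
                                 chrom %in% names(chrom_lengths)) {
                 100 * bp / chrom_lengths[[chrom]]
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(intervals = intervals, per_chromosome = per_chrom,
                 parent = parent, sex = if (parent == "mother") "female" else "male",
                 mapping_function = mapping_function, iss = iss),
            class = "sex_specific_map")
}

#' @export
print.sex_specific_map <- function(x, ...) {
  cat(sprintf("%s (%s) linkage map, %s function: total %.1f cM, %d markers\n",
              x$sex, x$parent, x$mapping_function,
              sum(x$per_chromosome$total_cM), sum(x$per_chromosome$n_markers)))
  print(x$per_chromosome, row.names = FALSE)
  invisible(x)
}

#' Locate crossover events from masked inheritance states
#'
#' One event per state flip between consecutive non-missing markers of an
#' offspring; the event is localised to the flanking-marker interval and its
#' midpoint.
#'
#' @param iss A phased, masked `informative_sites` object.
#' @return Data frame of class `crossover_events`: offspring, chrom, left_pos,
#'   right_pos, midpoint, parent.
#' @export
locate_crossovers <- function(iss) {
  if (!isTRUE(iss$phased)) stop("states must be phased first (phase_states)")
  st <- iss$states
  rows <- list()
  for (chrom in unique(iss$sites$chrom)) {
    idx <- which(iss$sites$chrom == chrom)
    pos <- iss$sites$pos[idx]
    for (j in seq_len(ncol(st))) {
      obs <- which(!is.na(st[idx, j]))
      if (length(obs) < 2) next
      s <- st[idx[obs], j]
      flips <- which(diff(s) != 0)
      for (f in flips) {
        rows[[length(rows) + 1L]] <- data.frame(
          offspring = iss$offspring[j], chrom = chrom,
          left_pos = pos[obs[f]], right_pos = pos[obs[f + 1]],
          midpoint = (pos[obs[f]] + pos[obs[f + 1]]) / 2,
          parent = iss$parent, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(offspring = character(), chrom = character(),
               left_pos = numeric(), right_pos = numeric(),
               midpoint = numeric(), parent = character())
  }
  class(out) <- c("crossover_events", "data.frame")
  out
}

#' Quartile crossover density and tip bias
#'
#' Bins crossover midpoints into four equal physical quartiles of their
#' chromosome, pools counts across chromosomes, and reports the tip bias
#' (Q1 + Q4) / total.
#'
#' @param events Data frame with `chrom` and `midpoint` (bp), e.g. from
#'   [locate_crossovers()] or simulated truth.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return List with `counts` (Q1..Q4) and `tip_bias`.
#' @export
quartile_density <- function(events, chrom_lengths) {
  if (nrow(events) == 0) stop("no crossover events")
  if (!all(events$chrom %in% names(chrom_lengths))) {
    stop("chromosome lengths missing for some events")
  }
  frac <- events$midpoint / chrom_lengths[events$chrom]
  q <- pmin(pmax(ceiling(frac * 4), 1L), 4L)
  counts <- table(factor(q, levels = 1:4))
  names(counts) <- paste0("Q", 1:4)
  list(counts = c(counts),
       tip_bias = unname((counts[1] + counts[4]) / sum(counts)))
}

#' Linear model of map length on sex, family and physical coverage
#'
#' Fits `maplength ~ sex * family + sex:family:bpcovered` by ordinary least
#' squares: main and interaction effects of sex and family, plus a separate
#' slope of map length on covered base pairs for every sex-by-family cell.
#' Per-cell slopes are reported with t-based 95% confidence intervals, along
#' with a Shapiro-Wilk residual-normality diagnostic.
#'
#' @param data Data frame with numeric `maplength` (cM) and `bpcovered`, and
#'   factors/characters `sex` and `family`; one row per chromosome map.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `maplength_model`: `fit` (the `lm`), `coefficients`
#'   (estimates with CIs), `slopes` (per sex-by-family slope of cM on
#'   bpcovered with CI), `residual_normality_p`.
#' @export
maplength_model <- function(data, conf_level = 0.95) {
  stopifnot(all(c("maplength", "sex", "family", "bpcovered") %in% names(data)))
  data$sex <- factor(data$sex)
  data$family <- factor(data$family)
  fit <- stats::lm(maplength ~ sex * family + sex:family:bpcovered,
                   data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: need at least two chromosomes per ",
         "sex-by-family cell")
  }
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(term = names(stats::coef(fit)),
                      estimate = unname(stats::coef(fit)),
                      lo = ci[, 1], hi = ci[, 2], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  sl <- coefs[grepl(":bpcovered$", coefs$term), , drop = FALSE]
  sl$sex <- sub("^sex([^:]+):.*", "\\1", sl$term)
  sl$family <- sub("^.*family([^:]+):bpcovered$", "\\1", sl$term)
  rownames(sl) <- NULL
  res_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                    error = function(e) NA_real_)
  structure(list(fit = fit, coefficients = coefs, slopes = sl,
                 residual_normality_p = res_p),
            class = "maplength_model")
}

#' @export
print.maplength_model <- function(x, ...) {
  cat("map length ~ sex * family + sex:family:bpcovered\n")
  print(x$slopes[, c("sex", "family", "estimate", "lo", "hi")],
        row.names = FALSE)
  cat(sprintf("residual normality (Shapiro) p = %.3f\n",
              x$residual_normality_p))
  invisible(x)
}
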