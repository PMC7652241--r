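#' Per-individual nucleotide diversity of expressed transcripts
#'
#' For a diploid, within-individual pairwise nucleotide diversity equals the
#' fraction of callable sites that are heterozygous. Site-level genotype calls
#' are filtered (depth below `min_dp`, genotype quality below `min_gq`, or map
#' quality below `min_mq` are removed), then per transcript pi = heterozygous
#' sites / callable sites, and the individual summary over a transcript set is
#' the site-weighted pool sum(het) / sum(callable). Both the site-weighted
#' summary and the mean of per-transcript pi are reported.
#'
#' @param calls Data frame of per-site calls: `individual`, `transcript_id`,
#'   `het` (logical), `dp`, `gq`, `mq`.
#' @param transcripts Transcript metadata with `transcript_id` and `is_sl`
#'   (whether the transcript lies in the sex-linked region), or `chrom`/`start`
#'   plus a `region` argument.
#' @param region Optional list (`chrom`, `start`, `end`) used to derive
#'   `is_sl` from transcript start coordinates when `transcripts$is_sl` is
#'   absent.
#' @param min_dp,min_gq,min_mq Genotype filters (defaults 4 / 20 / 20;
#'   genotypes strictly below any threshold are removed).
#' @return Object of class `pi_profile`: list with `per_transcript` (long data
#'   frame: individual, transcript_id, is_sl, callable, het, pi) and `summary`
#'   (per individual: callable/het/pi for the SL set and the background set,
#'   both site-weighted and transcript-averaged). Individuals with zero
#'   callable SL sites get `NA` with a flag.
#' @export
per_individual_pi <- function(calls, transcripts, region = NULL,
                              min_dp = 4, min_gq = 20, min_mq = 20) {
  stopifnot(all(c("individual", "transcript_id", "het", "dp", "gq", "mq")
                %in% names(calls)))
  keep <- calls$dp >= min_dp & calls$gq >= min_gq & calls$mq >= min_mq
  calls <- calls[keep, , drop = FALSE]
  if (is.null(transcripts$is_sl)) {
    if (is.null(region)) stop("provide transcripts$is_sl or a region")
    region <- as.list(region)
    transcripts$is_sl <- transcripts$chrom == region$chrom &
      transcripts$start >= as.numeric(region$start) &
      transcripts$start <= as.numeric(region$end)
  }
  agg <- stats::aggregate(cbind(callable = rep(1L, nrow(calls)),
                                het = as.integer(calls$het)),
                          by = list(individual = calls$individual,
                                    transcript_id = calls$transcript_id),
                          FUN = sum)
  agg$is_sl <- transcripts$is_sl[match(agg$transcript_id,
                                       transcripts$transcript_id)]
  agg$pi <- agg$het / agg$callable
  pi_profile_from_summary(agg)
}

#' Build a pi profile from transcript-level heterozygosity summaries
#'
#' @param het_summary Data frame with `individual`, `transcript_id`, `is_sl`,
#'   `callable`, `het` (e.g. from [simulate_expression()] or
#'   [per_individual_pi()] pre-aggregation).
#' @return A `pi_profile` (see [per_individual_pi()]).
#' @export
pi_profile_from_summary <- function(het_summary) {
  stopifnot(all(c("individual", "transcript_id", "is_sl", "callable", "het")
                %in% names(het_summary)),
            all(het_summary$het <= het_summary$callable))
  het_summary$pi <- ifelse(het_summary$callable > 0,
                           het_summary$het / het_summary$callable, NA_real_)
  summ <- do.call(rbind, lapply(split(het_summary, het_summary$individual),
                                function(d) {
    pool <- function(dd) {
      cal <- sum(dd$callable); het <- sum(dd$het)
      c(callable = cal, het = het,
        pi = if (cal > 0) het / cal else NA_real_,
        pi_transcript_mean = mean(dd$pi, na.rm = TRUE))
    }
    sl <- pool(d[d$is_sl, , drop = FALSE])
    bg <- pool(d[!d$is_sl, , drop = FALSE])
    data.frame(individual = d$individual[1],
               callable_sl = sl[["callable"]], het_sl = sl[["het"]],
               pi_sl = sl[["pi"]],
               pi_sl_transcript_mean = sl[["pi_transcript_mean"]],
               callable_bg = bg[["callable"]], het_bg = bg[["het"]],
               pi_bg = bg[["pi"]],
               pi_bg_transcript_mean = bg[["pi_transcript_mean"]],
               undefined_sl = sl[["callable"]] == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (any(summ$undefined_sl)) {
    warning("individual(s) with zero callable sex-linked sites: ",
            paste(summ$individual[summ$undefined_sl], collapse = ", "))
  }
  structure(list(per_transcript = het_summary, summary = summ),
            class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("pi_profile: %d individuals\n", nrow(x$summary)))
  print(x$summary[, c("individual", "pi_sl", "pi_bg")], row.names = FALSE)
  invisible(x)
}

#' Split one sex's diversity values into one or two levels
#'
#' Largest-gap rule: sort the values, find the largest gap, and accept a
#' two-group split only when that gap exceeds `min_sep` times the spread of
#' background (non-sex-linked) diversity across individuals. Deterministic;
#' one individual always forms a single group.
#'
#' @param values Named numeric vector of per-individual SL-region pi (names =
#'   individual ids).
#' @param background_spread Spread (range) of background pi across
#'   individuals, the natural scale of within-level variation.
#' @param min_sep Required gap-to-spread ratio (default 3).
#' @return List with `k` (1 or 2) and `level` (named `"low"`/`"high"`
#'   assignments; all `"low"` when k = 1).
#' @export
split_two_levels <- function(values, background_spread, min_sep = 3) {
  stopifnot(length(values) >= 1, background_spread >= 0)
  if (length(values) == 1) {
    return(list(k = 1L, level = stats::setNames("low", names(values))))
  }
  ord <- order(values)
  v <- values[ord]
  gaps <- diff(v)
  gi <- which.max(gaps)
  if (gaps[gi] > min_sep * background_spread && gaps[gi] > 0) {
    lev <- rep("low", length(v))
    lev[(gi + 1):length(v)] <- "high"
    k <- 2L
  } else {
    lev <- rep("low", length(v))
    k <- 1L
  }
  list(k = k, level = stats::setNames(lev[order(ord)], names(values)))
}

#' Assign sex-chromosome genotypes from diversity levels
#'
#' Given the number of diversity levels observed within daughters and within
#' sons, finds the parental crosses consistent with the observations: a cross
#' is a candidate when, for each observed sex, it produces at least as many
#' distinct offspring genotypes as levels observed (a cross with two possible
#' genotypes per sex remains consistent when sampling happens to show only
#' one), and when the observed sex ratio is not rejected against the cross's
#' expected female fraction (exact binomial, level `ratio_alpha`). Two levels
#' in each sex resolve a WZ x WY cross uniquely.
#'
#' Within a sex with two levels, the high-diversity group receives the more
#' diverged genotype pair (WZ over WW in daughters, WY over ZY in sons). When
#' one sex shows a single level but the cross allows two genotypes for it, the
#' level is anchored against the other sex's two levels: the group mean is
#' compared with the midpoint of the other sex's low and high level means
#' (valid because the W-containing heterogametic pairs share the high
#' divergence scale, while ZY divergence sits near the low end). When no
#' candidate cross, or more than one, is consistent, all calls abstain.
#'
#' @param pi_summary The `summary` data frame of a `pi_profile`.
#' @param sexes Named vector of phenotypic sexes (names = individual ids).
#' @param candidate_crosses Data frame of crosses to consider (default
#'   [enumerate_crosses()]).
#' @param min_sep Separation rule passed to [split_two_levels()].
#' @param ratio_alpha Level of the exact binomial sex-ratio consistency check
#'   (default 0.01).
#' @return Object of class `genotype_calls`: data frame (individual, sex,
#'   level, genotype, note) plus attributes `cross` (resolved mother/father or
#'   `NULL`) and `levels` (per-sex split results).
#' @export
assign_genotypes <- function(pi_summary, sexes,
                             candidate_crosses = enumerate_crosses(),
                             min_sep = 3, ratio_alpha = 0.01) {
  sexes <- sexes[pi_summary$individual]
  stopifnot(!anyNA(sexes))
  bg_spread <- diff(range(pi_summary$pi_bg, na.rm = TRUE))

  splits <- list()
  vals_by_sex <- list()
  for (sx in c("female", "male")) {
    ids <- pi_summary$individual[sexes == sx]
    if (length(ids) == 0) next
    vals <- stats::setNames(pi_summary$pi_sl[match(ids, pi_summary$individual)],
                            ids)
    vals_by_sex[[sx]] <- vals
    splits[[sx]] <- split_two_levels(vals, bg_spread, min_sep)
  }
  n_f <- sum(sexes == "female"); n_m <- sum(sexes == "male")

  consistent <- vapply(seq_len(nrow(candidate_crosses)), function(i) {
    ce <- cross_expectation(candidate_crosses$mother[i],
                            candidate_crosses$father[i])
    gts <- names(ce$offspring)
    ok <- TRUE
    for (sx in names(splits)) {
      ok <- ok && sum(sex_of(gts) == sx) >= splits[[sx]]$k
    }
    ## observed sex ratio must be plausible under the cross
    if (ok && n_f + n_m > 0) {
      ff <- ce$female_fraction
      p_ratio <- if (ff %in% c(0, 1)) {
        as.numeric((ff == 1) == (n_m == 0))
      } else {
        stats::binom.test(n_f, n_f + n_m, ff)$p.value
      }
      ok <- p_ratio >= ratio_alpha
    }
    ok
  }, logical(1))

  calls <- data.frame(individual = pi_summary$individual,
                      sex = unname(sexes),
                      level = NA_character_, genotype = NA_character_,
                      note = "", stringsAsFactors = FALSE)
  for (sx in names(splits)) {
    lv <- splits[[sx]]$level
    calls$level[match(names(lv), calls$individual)] <- lv
  }

  ## group mean pi of the low/high levels within one sex
  level_means <- function(sx) {
    lv <- splits[[sx]]$level
    vapply(c("low", "high"), function(l) {
      if (any(lv == l)) mean(vals_by_sex[[sx]][names(lv)[lv == l]]) else NA_real_
    }, numeric(1))
  }

  cross <- NULL
  if (sum(consistent) == 1) {
    i <- which(consistent)
    ce <- cross_expectation(candidate_crosses$mother[i],
                            candidate_crosses$father[i])
    cross <- list(mother = ce$mother, father = ce$father)
    for (sx in names(splits)) {
      gts <- names(ce$offspring)[sex_of(names(ce$offspring)) == sx]
      ## rank candidate genotypes by expected SL divergence: heterogametic
      ## pairs involving W are most diverged, ZY intermediate-low, same-type
      ## pairs lowest
      div_rank <- c(WW = 0, ZZ = 0, ZY = 1, WZ = 2, WY = 2)
      gts <- gts[order(div_rank[gts])]
      lv <- splits[[sx]]$level
      sel <- match(names(lv), calls$individual)
      if (splits[[sx]]$k == 2) {
        calls$genotype[sel] <- unname(c(low = gts[1], high = gts[2])[lv])
      } else if (length(gts) == 1) {
        calls$genotype[sel] <- gts[1]
      } else {
        ## single observed level but two possible genotypes: anchor against
        ## the other sex's two levels
        other <- setdiff(names(splits), sx)
        if (length(other) == 1 && splits[[other]]$k == 2) {
          anchors <- level_means(other)
          midpoint <- mean(anchors)
          own <- mean(vals_by_sex[[sx]])
          calls$genotype[sel] <- if (own > midpoint) gts[2] else gts[1]
        } else {
          calls$note[sel] <- "single diversity level unanchored; abstained"
        }
      }
    }
    bad <- !is.na(calls$genotype) & sex_of(calls$genotype) != calls$sex
    if (any(bad)) {
      stop("internal error: inferred genotype conflicts with phenotypic sex")
    }
  } else {
    calls$note <- if (sum(consistent) == 0) {
      "no candidate cross consistent; abstained"
    } else {
      "multiple candidate crosses consistent; abstained"
    }
  }
  structure(calls, cross = cross, levels = splits,
            class = c("genotype_calls", "data.frame"))
}

#' Infer the origin of the Y chromosome from class-level diversity
#'
#' The Y is inferred to derive from the Z when divergence between Z and Y
#' (the SL diversity of ZY individuals) is lower than divergence between W and
#' Z or W and Y; symmetrically for an origin from the W. Support is assessed
#' by bootstrap resampling of transcripts.
#'
#' @param per_transcript Long per-transcript pi table (as in a `pi_profile`),
#'   restricted to SL transcripts internally.
#' @param genotype_calls Calls from [assign_genotypes()] (or any data frame
#'   with `individual` and `genotype`).
#' @param B Bootstrap replicates (default 1000).
#' @param support_threshold Required bootstrap support (default 0.95).
#' @param seed Optional seed.
#' @return List of class `y_origin`: `call` (`"from_Z"`, `"from_W"` or
#'   `"undetermined"`), `class_pi` (site-weighted mean pi per genotype class)
#'   and `support` (bootstrap support for each hypothesis).
#' @export
infer_y_origin <- function(per_transcript, genotype_calls, B = 1000,
                           support_threshold = 0.95, seed = NULL) {
  gt <- stats::setNames(genotype_calls$genotype, genotype_calls$individual)
  d <- per_transcript[per_transcript$is_sl, , drop = FALSE]
  d$genotype <- gt[d$individual]
  d <- d[!is.na(d$genotype) & d$genotype %in% c("WZ", "WY", "ZY"), ,
         drop = FALSE]
  classes <- c("WZ", "WY", "ZY")
  if (!all(classes %in% unique(d$genotype))) {
    return(structure(list(call = "undetermined",
                          class_pi = NULL, support = NULL),
                     class = "y_origin"))
  }
  class_pi <- function(dd) {
    vapply(classes, function(g) {
      sub <- dd[dd$genotype == g, ]
      sum(sub$het) / sum(sub$callable)
    }, numeric(1))
  }
  obs <- class_pi(d)
  ## per-transcript per-class pooled sums, so resampling transcripts is a
  ## matrix row-resample rather than a data-frame rebuild
  tx <- factor(d$transcript_id)
  gcls <- factor(d$genotype, levels = classes)
  hetm <- tapply(d$het, list(tx, gcls), sum, default = 0)
  calm <- tapply(d$callable, list(tx, gcls), sum, default = 0)
  boot <- function() {
    hits_z <- 0L; hits_w <- 0L
    for (b in seq_len(B)) {
      take <- sample.int(nrow(hetm), nrow(hetm), replace = TRUE)
      cp <- colSums(hetm[take, , drop = FALSE]) /
        colSums(calm[take, , drop = FALSE])
      if (is.finite(cp["ZY"]) && cp["ZY"] < min(cp["WZ"], cp["WY"])) {
        hits_z <- hits_z + 1L
      }
      if (is.finite(cp["WY"]) && cp["WY"] < min(cp["WZ"], cp["ZY"])) {
        hits_w <- hits_w + 1L
      }
    }
    c(from_Z = hits_z / B, from_W = hits_w / B)
  }
  support <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())

  call <- "undetermined"
  if (obs["ZY"] < min(obs["WZ"], obs["WY"]) &&
      support["from_Z"] >= support_threshold) {
    call <- "from_Z"
  } else if (obs["WY"] < min(obs["WZ"], obs["ZY"]) &&
             support["from_W"] >= support_threshold) {
    call <- "from_W"
  }
  structure(list(call = call, class_pi = obs, support = support),
            class = "y_origin")
}

#' @export
print.y_origin <- function(x, ...) {
  cat("Y-origin inference:", x$call, "\n")
  if (!is.null(x$class_pi)) {
    cat("  class mean pi:",
        paste(names(x$class_pi), signif(x$class_pi, 3), sep = "=",
              collapse = ", "), "\n")
    cat("  bootstrap support:",
        paste(names(x$support), x$support, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
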