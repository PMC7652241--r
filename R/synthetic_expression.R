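#' Simulate gonadal RNA-seq counts and per-transcript heterozygosity
#'
#' Generates a transcripts x individuals raw count matrix and per-individual
#' per-transcript heterozygosity summaries with the structure expected of an
#' early-gonadal-differentiation dataset from a WZY system:
#'
#' * sex-biased expression is assigned at the gene level and shared by a
#'   gene's transcripts; a configurable fraction of sex-linked (SL) region
#'   genes is male-biased, a configurable subset of those male-specific
#'   (zero expression in females);
#' * counts are negative binomial with the male/female means separated by the
#'   gene's true log2 fold change;
#' * for each individual, the number of heterozygous sites in an SL transcript
#'   is binomial with per-bp rate equal to the divergence of that individual's
#'   true sex-chromosome genotype pair (d_WZ, d_WY, d_ZY, or the within-type
#'   polymorphism for WW/ZZ); non-SL transcripts use the within-type rate.
#'
#' @param config A [sim_config()].
#' @param individuals Data frame with columns `id`, `sex`, and `sl_genotype`
#'   (true sex-chromosome genotype, e.g. from [sample_offspring_genotypes()]
#'   or a [simulate_family()] truth block).
#' @param seed Optional seed.
#' @return List of class `expression_dataset` with `counts` (integer matrix),
#'   `transcripts` (metadata with true logFC and bias class), `het_summary`
#'   (long data frame: individual, transcript_id, callable, het) and
#'   `individuals`.
#' @export
simulate_expression <- function(config, individuals, seed = NULL) {
  stopifnot(all(c("id", "sex", "sl_genotype") %in% names(individuals)))
  run <- function() simulate_expression_impl(config, individuals)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_expression_impl <- function(cfg, individuals) {
  n_sl <- cfg$n_transcripts_SL
  n_bg <- cfg$n_transcripts_background
  bg_chrom <- setdiff(names(cfg$chromosomes), cfg$sex_chrom)[1]
  if (is.na(bg_chrom)) stop("config needs at least one non-sex chromosome")

  start_sl <- sort(round(stats::runif(n_sl, cfg$sl_start + 1, cfg$sl_end - 3000)))
  start_bg <- sort(round(stats::runif(n_bg, 1, cfg$chromosomes[[bg_chrom]] - 3000)))
  len <- sample(500:3000, n_sl + n_bg, replace = TRUE)
  tx <- data.frame(
    transcript_id = sprintf("tx%05d", seq_len(n_sl + n_bg)),
    chrom = c(rep(cfg$sex_chrom, n_sl), rep(bg_chrom, n_bg)),
    start = c(start_sl, start_bg),
    stringsAsFactors = FALSE)
  tx$end <- tx$start + len
  tx$length_bp <- len
  tx$is_sl <- c(rep(TRUE, n_sl), rep(FALSE, n_bg))

  ## genes of 1-3 transcripts, never spanning the SL boundary
  gene_of <- function(n, prefix) {
    sizes <- sample(1:3, n, replace = TRUE)
    sizes <- sizes[cumsum(sizes) <= n]
    if (sum(sizes) < n) sizes <- c(sizes, n - sum(sizes))
    rep(sprintf("%s%04d", prefix, seq_along(sizes)), sizes)
  }
  tx$gene_id <- c(gene_of(n_sl, "gSL"), gene_of(n_bg, "gBG"))

  ## gene-level sex effects
  genes <- unique(tx$gene_id)
  is_sl_gene <- startsWith(genes, "gSL")
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  class_g <- stats::setNames(rep("unbiased", length(genes)), genes)
  eff <- function(k) stats::runif(k, cfg$logfc_effect_range[1],
                                  cfg$logfc_effect_range[2])
  sl_biased <- is_sl_gene & stats::runif(length(genes)) < cfg$sl_male_bias_fraction
  sl_specific <- sl_biased & stats::runif(length(genes)) < cfg$sl_male_specific_fraction
  lfc[sl_biased] <- eff(sum(sl_biased))
  class_g[sl_biased] <- "male_biased"
  class_g[sl_specific] <- "male_specific"
  bg_biased <- !is_sl_gene & stats::runif(length(genes)) < cfg$background_bias_fraction
  dir <- sample(c(-1, 1), sum(bg_biased), replace = TRUE)
  lfc[bg_biased] <- dir * eff(sum(bg_biased))
  class_g[bg_biased] <- ifelse(dir > 0, "male_biased", "female_biased")

  tx$true_logfc <- unname(lfc[tx$gene_id])
  tx$true_class <- unname(class_g[tx$gene_id])

  ## counts
  n_tx <- nrow(tx)
  ids <- individuals$id
  base <- stats::rlnorm(n_tx, log(100), 1)
  mu_m <- base * 2^(tx$true_logfc / 2)
  mu_f <- base * 2^(-tx$true_logfc / 2)
  mu_f[tx$true_class == "male_specific"] <- 0
  mu_m[tx$true_class == "female_specific"] <- 0
  counts <- matrix(0L, n_tx, length(ids), dimnames = list(tx$transcript_id, ids))
  for (j in seq_along(ids)) {
    mu <- if (individuals$sex[j] == "male") mu_m else mu_f
    pos <- mu > 0
    counts[pos, j] <- stats::rnbinom(sum(pos), mu = mu[pos],
                                     size = cfg$nb_dispersion)
  }

  ## per-individual heterozygosity summaries
  het_summary <- do.call(rbind, lapply(seq_along(ids), function(j) {
    d_sl <- sl_pair_divergence(cfg, individuals$sl_genotype[j])
    rate <- ifelse(tx$is_sl, d_sl, cfg$within_type_theta)
    callable <- stats::rpois(n_tx, cfg$transcript_callable_bp)
    data.frame(individual = ids[j], transcript_id = tx$transcript_id,
               is_sl = tx$is_sl, callable = callable,
               het = stats::rbinom(n_tx, callable, rate),
               stringsAsFactors = FALSE)
  }))

  structure(list(counts = counts, transcripts = tx, het_summary = het_summary,
                 individuals = individuals, config = cfg),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d transcripts x %d individuals (%d SL)\n",
              nrow(x$counts), ncol(x$counts), sum(x$transcripts$is_sl)))
  cat(sprintf("  true bias classes: %s\n",
              paste(names(table(x$transcripts$true_class)),
                    table(x$transcripts$true_class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate site-level RNA-seq genotype calls
#'
#' Expands an individual x transcript design into per-site diploid calls with
#' depth, genotype quality and map quality, for exercising the genotype-filter
#' path of [per_individual_pi()]. Sites failing the standard filters are
#' included (that is the point); heterozygosity among passing sites follows
#' the divergence of the individual's true sex-chromosome genotype, exactly as
#' in [simulate_expression()]. Intended for small configurations.
#'
#' @param config A [sim_config()] (use small transcript counts).
#' @param individuals As in [simulate_expression()].
#' @param fail_rate Fraction of sites that fail at least one quality filter.
#' @param seed Optional seed.
#' @return List with `calls` (individual, transcript_id, chrom, pos, het, dp,
#'   gq, mq) and `transcripts` metadata.
#' @export
expression_site_calls <- function(config, individuals, fail_rate = 0.1,
                                  seed = NULL) {
  run <- function() {
    expr <- simulate_expression_impl(config, individuals)
    tx <- expr$transcripts
    calls <- do.call(rbind, lapply(seq_len(nrow(individuals)), function(j) {
      d_sl <- sl_pair_divergence(config, individuals$sl_genotype[j])
      do.call(rbind, lapply(seq_len(nrow(tx)), function(t) {
        n <- stats::rpois(1, config$transcript_callable_bp)
        if (n == 0) return(NULL)
        rate <- if (tx$is_sl[t]) d_sl else config$within_type_theta
        fails <- stats::runif(n) < fail_rate
        dp <- ifelse(fails & stats::runif(n) < 1 / 3, sample(0:3, n, TRUE),
                     3 + stats::rpois(n, config$expr_depth_mean))
        gq <- ifelse(fails & stats::runif(n) < 1 / 2, sample(0:19, n, TRUE),
                     sample(20:99, n, TRUE))
        mq <- ifelse(fails, sample(c(5:19, 20:60), n, TRUE),
                     sample(20:60, n, TRUE))
        data.frame(individual = individuals$id[j],
                   transcript_id = tx$transcript_id[t],
                   chrom = tx$chrom[t],
                   pos = tx$start[t] + sort(sample(seq_len(tx$length_bp[t]), n)) - 1,
                   het = stats::rbinom(n, 1, rate) == 1,
                   dp = as.integer(dp), gq = as.integer(gq),
                   mq = as.integer(mq), stringsAsFactors = FALSE)
      }))
    }))
    list(calls = calls, transcripts = tx, individuals = individuals)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
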