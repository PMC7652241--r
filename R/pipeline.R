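#' Configuration for an end-to-end run
#'
#' Bundles inputs, per-stage parameter blocks and the global seed. Inputs may
#' be file paths (VCF + sample sheet, counts TSV + transcript BED, optional DE
#' table) or `NULL`, in which case the corresponding stage runs on data
#' simulated from `sim` with the global seed.
#'
#' @param vcf,sample_sheet Paths to family genotype inputs (or `NULL` to
#'   simulate).
#' @param counts,transcript_bed,de_table Paths to expression inputs (or
#'   `NULL`).
#' @param sim A [sim_config()] used when inputs are simulated.
#' @param qc A [qc_config()].
#' @param scan_parent Parent for the sex-linkage scan (`"father"` or
#'   `"mother"`).
#' @param scan_window_bp Double-recombinant masking window.
#' @param scan_fdr Apply FDR in the scan.
#' @param fst_window,fst_band_mode,fst_B FST scan parameters.
#' @param sl_region Sex-linked region as `list(chrom, start, end)` or a
#'   `"chrom:start-end"` string; defaults to the simulation's region.
#' @param fdr_alpha,logfc_min,prior Expression-bias thresholds.
#' @param seed Global seed; all stage seeds derive from it.
#' @param outdir Output directory (created); `NULL` disables file output.
#' @param stages Character vector choosing stages among `qc`,
#'   `scan-linkage`, `scan-fst`, `expression`, `infer-genotypes`, `maps`.
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf = NULL, sample_sheet = NULL, counts = NULL,
                       transcript_bed = NULL, de_table = NULL,
                       sim = sim_config(), qc = qc_config(),
                       scan_parent = "father", scan_window_bp = 1e7,
                       scan_fdr = TRUE, fst_window = 50,
                       fst_band_mode = "bootstrap-mean", fst_B = 1000,
                       sl_region = NULL, fdr_alpha = 0.05, logfc_min = 2,
                       prior = 0.125, seed = 1L, outdir = NULL,
                       stages = c("qc", "scan-linkage", "scan-fst",
                                  "expression", "infer-genotypes", "maps")) {
  for (p in c(vcf, sample_sheet, counts, transcript_bed, de_table)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (is.character(sl_region)) sl_region <- parse_region(sl_region)
  if (is.null(sl_region)) {
    sl_region <- list(chrom = sim$sex_chrom, start = sim$sl_start,
                      end = sim$sl_end)
  }
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(config, stage) {
  ## distinct, stable sub-seeds; kept small (< 2^31)
  offsets <- c(simulate = 101L, qc = 202L, `scan-linkage` = 303L,
               `scan-fst` = 404L, expression = 505L,
               `infer-genotypes` = 606L, maps = 707L)
  (as.integer(config$seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order: genotype QC, parent-of-origin
#' sex-linkage scan, between-sex FST scan, expression-bias calling with
#' region enrichment, nucleotide-diversity genotype inference with Y-origin
#' inference, and sex-specific linkage maps. Missing inputs are simulated from
#' the configuration's `sim` block so the whole pipeline is exercisable
#' end-to-end without external data. All randomness derives from the global
#' seed, and outputs (TSV/JSON) are written under `outdir` when set, each
#' carrying a stage/version/config-hash header.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: per-stage result objects and summaries,
#'   package version, config hash and the seeds used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list()
  seeds <- list()
  results <- list()
  emit <- if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    TRUE
  } else FALSE
  cfg_hash <- config_hash(config)
  hdr <- function(stage) {
    sprintf("# trisexscan %s | stage=%s | config=%s",
            as.character(utils::packageVersion("trisexscan")), stage, cfg_hash)
  }
  write_tsv <- function(df, stage, file) {
    if (!emit) return(invisible(NULL))
    path <- file.path(config$outdir, file)
    writeLines(hdr(stage), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  write_json <- function(x, file) {
    if (!emit) return(invisible(NULL))
    jsonlite::write_json(x, file.path(config$outdir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  ## family data: read or simulate
  fd <- if (!is.null(config$vcf) && !is.null(config$sample_sheet)) {
    read_family_dataset(config$vcf, config$sample_sheet)
  } else {
    seeds$simulate <- stage_seed(config, "simulate")
    simulate_family(config$sim, seed = seeds$simulate)
  }

  if ("qc" %in% config$stages) {
    qc <- apply_qc(fd, config$qc)
    fd <- qc$dataset
    results$qc <- qc$report
    write_tsv(qc$report$steps, "qc", "qc_report.tsv")
  }

  if ("scan-linkage" %in% config$stages) {
    scan <- sex_linkage_scan(fd, parent = config$scan_parent,
                             window_bp = config$scan_window_bp,
                             apply_fdr = config$scan_fdr)
    results$scan_linkage <- scan
    write_tsv(as.data.frame(scan), "scan-linkage", "sex_linkage.tsv")
  }

  if ("scan-fst" %in% config$stages) {
    seeds$scan_fst <- stage_seed(config, "scan-fst")
    pop <- simulate_population(config$sim, seed = seeds$scan_fst)
    track <- fst_scan(pop$geno, pop$sites, pop$samples$sex,
                      sex_chrom = config$sim$sex_chrom,
                      window_size = config$fst_window,
                      band_mode = config$fst_band_mode, B = config$fst_B,
                      seed = seeds$scan_fst)
    results$fst <- track
    write_tsv(track$windows, "scan-fst", "fst_windows.tsv")
    write_json(list(band = as.list(track$band),
                    peak = as.list(track$peak),
                    estimator = track$estimator), "fst_band.json")
  }

  expr <- NULL
  if (any(c("expression", "infer-genotypes") %in% config$stages)) {
    if (!is.null(config$counts) && !is.null(config$transcript_bed)) {
      counts <- as.matrix(utils::read.delim(config$counts, row.names = 1,
                                            check.names = FALSE))
      meta <- read_transcript_bed(config$transcript_bed)
      meta <- meta[match(rownames(counts), meta$transcript_id), ]
      stop_if <- anyNA(meta$transcript_id)
      if (stop_if) stop("count rows missing from the transcript BED")
      expr <- list(counts = counts, transcripts = meta, het_summary = NULL,
                   individuals = NULL)
    } else {
      seeds$expression <- stage_seed(config, "expression")
      inds <- sample_offspring_genotypes(config$sim$mother, config$sim$father,
                                         n_female = 9, n_male = 5,
                                         seed = seeds$expression)
      inds <- data.frame(id = sprintf("tad%02d", seq_len(nrow(inds))),
                         sex = inds$sex, sl_genotype = inds$genotype,
                         stringsAsFactors = FALSE)
      expr <- simulate_expression(config$sim, inds, seed = seeds$expression)
    }
  }

  if ("expression" %in% config$stages) {
    keep <- rowMeans(expr$counts) >= 1
    counts <- expr$counts[keep, , drop = FALSE]
    meta <- expr$transcripts[keep, , drop = FALSE]
    sexes <- if (!is.null(expr$individuals)) expr$individuals$sex else {
      stop("expression stage on file inputs requires a sample sheet with ",
           "sexes; provide individuals via the sample sheet")
    }
    de <- if (!is.null(config$de_table)) {
      utils::read.delim(config$de_table, stringsAsFactors = FALSE)
    }
    records <- call_bias(counts, meta, sexes, de_table = de,
                         fdr_alpha = config$fdr_alpha,
                         logfc_min = config$logfc_min, prior = config$prior)
    enr <- region_enrichment(records, config$sl_region, "male")
    results$expression <- list(records = records, enrichment = enr)
    write_tsv(as.data.frame(records), "expression", "expression_bias.tsv")
    write_json(list(region = enr$region,
                    counts_inside = as.list(enr$counts_inside),
                    density_per_mb = enr$density_per_mb,
                    p_binomial = enr$p_binomial), "region_enrichment.json")
  }

  if ("infer-genotypes" %in% config$stages) {
    if (is.null(expr$het_summary)) {
      stop("genotype inference requires per-transcript heterozygosity ",
           "(simulated inputs or per_individual_pi output)")
    }
    prof <- pi_profile_from_summary(expr$het_summary)
    sexes <- stats::setNames(expr$individuals$sex, expr$individuals$id)
    calls <- assign_genotypes(prof$summary, sexes)
    seeds$infer <- stage_seed(config, "infer-genotypes")
    yo <- infer_y_origin(prof$per_transcript, calls, seed = seeds$infer)
    results$inference <- list(profile = prof, calls = calls, y_origin = yo)
    write_tsv(prof$summary, "infer-genotypes", "pi_profiles.tsv")
    write_tsv(as.data.frame(calls), "infer-genotypes", "genotype_calls.tsv")
    write_json(list(call = yo$call, class_pi = as.list(yo$class_pi),
                    support = as.list(yo$support)), "y_origin.json")
  }

  if ("maps" %in% config$stages) {
    maps <- lapply(c("mother", "father"), function(par) {
      build_linkage_map(fd, par, window_bp = config$scan_window_bp,
                        chrom_lengths = config$sim$chromosomes)
    })
    names(maps) <- c("female", "male")
    events <- rbind(locate_crossovers(maps$female$iss),
                    locate_crossovers(maps$male$iss))
    results$maps <- list(maps = maps, crossovers = events)
    per_map <- do.call(rbind, lapply(names(maps), function(s) {
      cbind(sex = s, maps[[s]]$per_chromosome)
    }))
    write_tsv(per_map, "maps", "linkage_maps.tsv")
    write_tsv(events, "maps", "crossovers.tsv")
  }

  report <- structure(list(results = results,
                           version = as.character(
                             utils::packageVersion("trisexscan")),
                           config_hash = cfg_hash, seeds = seeds,
                           stages = config$stages),
                      class = "run_report")
  if (emit) {
    write_json(list(version = report$version, config_hash = cfg_hash,
                    seeds = seeds, stages = config$stages), "run_report.json")
  }
  report
}

config_hash <- function(config) {
  cfg <- config
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg, give.attr = FALSE)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("trisexscan run (version %s, config %s)\n", x$version,
              substr(x$config_hash, 1, 8)))
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  invisible(x)
}
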