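#' Generate mutually distant dual barcodes
#'
#' Random barcode pairs whose concatenations are pairwise at least 3
#' mismatches apart, as required for one-error-per-barcode
#' demultiplexing.
#'
#' @param n Number of samples.
#' @param len Barcode length (each of the pair).
#' @return data.frame with `barcode1`, `barcode2`.
#' @export
make_barcodes <- function(n, len = 8) {
  bc1 <- character(0); bc2 <- character(0)
  while (length(bc1) < n) {
    c1 <- rand_dna(len); c2 <- rand_dna(len)
    cand <- paste0(c1, c2)
    if (!length(bc1) ||
        all(hamming(rep(cand, length(bc1)), paste0(bc1, bc2)) >= 3)) {
      bc1 <- c(bc1, c1); bc2 <- c(bc2, c2)
    }
  }
  data.frame(barcode1 = bc1, barcode2 = bc2, stringsAsFactors = FALSE)
}

default_fixture_samples <- function() {
  data.frame(
    id = c("tumA1", "tumA2", "tumB1", "tumB2",
           "nrmA1", "nrmA2", "nrmB1", "nrmB2",
           "bld1", "bld2", "undig1", "undig2"),
    tissue = c("lung", "lung", "colon", "colon",
               "lung", "lung", "colon", "colon",
               "blood", "blood", "lung", "colon"),
    condition = c(rep("tumor", 4), rep("normal", 4), "blood", "blood",
                  "normal", "normal"),
    digested = c(rep(TRUE, 10), FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Build a small on-disk fixture dataset
#'
#' Generates a synthetic panel (20 double-tiled CpG targets, 20
#' reference targets, 8 lambda controls), 12 samples (4 tumor, 4 normal,
#' 2 blood, 2 undigested controls) with dual barcodes, simulates reads,
#' and writes FASTQ (R1/R2/I1/I2, gzipped), panel TSV/FASTA/BED, sample
#' sheet, truth table and the simulation config to `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed; two seeds share the panel structure but
#'   differ in sequences, tags and counts.
#' @param n_molecules Pre-capture depth per target (default 1100: with
#'   two undigested controls at 50% capture efficiency every sample
#'   clears the 5000-count depth threshold and every smMIP the 1000
#'   cumulative-undigested-count efficiency threshold).
#' @return Invisibly, a list with `panel`, `config`, `sim` and the file
#'   `paths`.
#' @export
make_fixtures <- function(dir, seed = 1, n_molecules = 1100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_synthetic_panel(n_cpg = 20, n_ref = 20, n_lambda = 8,
                                seed = seed)
  samples <- default_fixture_samples()
  samples <- cbind(samples, with_seed(seed + 10L, make_barcodes(nrow(samples))))
  config <- sim_config(samples, seed = seed, n_molecules = n_molecules,
                       capture_efficiency = 0.5, pcr_duplication_mean = 1.5,
                       read_error_rate = 0.001)
  sim <- simulate_reads(panel, config)
  paths <- write_fastq_set(sim, dir, config)
  paths["panel_tsv"] <- file.path(dir, "panel.tsv")
  paths["panel_fasta"] <- file.path(dir, "panel.fasta")
  paths["panel_bed"] <- file.path(dir, "targets.bed")
  write_panel(panel, paths[["panel_tsv"]], paths[["panel_fasta"]])
  panel_to_bed(panel, paths[["panel_bed"]])
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "samples")], cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["config"] <- cfg_path
  invisible(list(panel = panel, config = config, sim = sim, paths = paths))
}

write_manifest <- function(dir, stages, params, tallies) {
  jsonlite::write_json(
    list(package = "msremip",
         version = as.character(utils::packageVersion("msremip")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         stages = stages, parameters = params, tallies = tallies),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Run the full pipeline on a fixture-style dataset
#'
#' Executes demultiplexing and counting, sample and smMIP QC,
#' normalization, ensemble training and training-set prediction, writing
#' each stage's artifact (counts, QC report, normalized matrix, model
#' JSON, predictions, manifest) under `out_dir`. Stages can be skipped
#' via `stages`; any failure writes a `FAILED` marker naming the stage.
#'
#' @param input_dir Directory produced by [make_fixtures()] (or with the
#'   same layout).
#' @param out_dir Output directory.
#' @param seed Seed for fold assignment.
#' @param digestion_threshold_pct,min_counts,min_cvauc,min_cum_undigested,n_folds
#'   Pipeline thresholds (assay defaults).
#' @param stages Character vector of stages to run, in order, from
#'   `c("count", "qc", "train")`.
#' @return list with `counts`, `qc`, `model`, `predictions`, `tally`
#'   (elements present for executed stages).
#' @export
run_pipeline <- function(input_dir, out_dir, seed = 1,
                         digestion_threshold_pct = 5, min_counts = 5000,
                         min_cvauc = 0.8, min_cum_undigested = 1000,
                         n_folds = 5, stages = c("count", "qc", "train")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  params <- list(seed = seed,
                 digestion_threshold_pct = digestion_threshold_pct,
                 min_counts = min_counts, min_cvauc = min_cvauc,
                 min_cum_undigested = min_cum_undigested, n_folds = n_folds)
  stage <- "setup"
  tryCatch({
    x <- NULL
    if ("count" %in% stages) {
      stage <- "count"
      panel <- read_panel(file.path(input_dir, "panel.tsv"),
                          file.path(input_dir, "panel.fasta"))
      samples <- read.delim(file.path(input_dir, "samples.tsv"),
                            stringsAsFactors = FALSE)
      pr <- process_reads(file.path(input_dir, "R1.fastq.gz"),
                          file.path(input_dir, "R2.fastq.gz"),
                          file.path(input_dir, "I1.fastq.gz"),
                          file.path(input_dir, "I2.fastq.gz"),
                          panel, samples)
      x <- pr$counts
      res$tally <- pr$tally
      write_counts(x, file.path(out_dir, "counts.tsv"),
                   file.path(out_dir, "samples.tsv"),
                   file.path(out_dir, "smmips.tsv"))
    } else {
      x <- read_counts(file.path(input_dir, "counts.tsv"),
                       file.path(input_dir, "samples.tsv"),
                       file.path(input_dir, "smmips.tsv"))
    }
    res$counts <- x
    if ("qc" %in% stages) {
      stage <- "qc"
      sq <- apply_sample_qc(x, digestion_threshold_pct, min_counts)
      dd <- drop_dead_smmips(sq$counts)
      x <- dd$counts
      res$qc <- list(samples = sq$report, dropped_smmips = dd$dropped,
                     flagged_smmips = dd$flagged)
      write.table(sq$report, file.path(out_dir, "qc_samples.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(res$qc, file.path(out_dir, "qc.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res$counts_qc <- x
    }
    if ("train" %in% stages) {
      stage <- "train"
      if (!any(x$samples$digested & x$samples$condition == "tumor") ||
          !any(x$samples$digested & x$samples$condition != "tumor"))
        stop("empty training set after QC: need digested tumor and non-tumor samples")
      model <- train_ensemble(x, seed = seed, n_folds = n_folds,
                              min_cvauc = min_cvauc,
                              min_cum_undigested = min_cum_undigested)
      res$model <- model
      write_ensemble(model, file.path(out_dir, "model.json"))
      pred <- predict(model, x[, x$samples$digested])
      pred$condition <- x$samples$condition[match(pred$id, x$samples$id)]
      res$predictions <- pred
      write.table(pred, file.path(out_dir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tm <- model$training
      write.table(data.frame(metric = names(tm), value = unlist(tm)),
                  file.path(out_dir, "metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, stages, params, as.list(res$tally))
    res
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
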