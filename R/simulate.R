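#' Simulation configuration for the synthetic assay
#'
#' Bundles every knob of the synthetic assay generator. The methylation
#' model is hierarchical: each CpG target draws one condition-specific
#' mean methylation level (tumor means uniform on `tumor_mean_range`,
#' normal means uniform on `normal_mean_range` — mirroring the panel
#' selection rule that targets be hypermethylated in tumors and
#' hypomethylated in normal tissue and blood — and blood means equal to
#' `blood_factor` times the normal mean, blood being the
#' lowest-methylation condition), and each sample then draws its level
#' from a Beta distribution around the target mean with concentration
#' `concentration`.
#'
#' @param samples data.frame with columns `id`, `tissue`, `condition`
#'   (`tumor`/`normal`/`blood`), `digested` (logical) and optionally
#'   `barcode1`, `barcode2` (required for read-level simulation).
#' @param n_molecules Pre-capture molecules per target per sample.
#' @param capture_efficiency Per-molecule capture probability.
#' @param non_digestion_rate Probability that an unmethylated fragment
#'   escapes digestion (the assay's internal control estimates ~1.3%).
#' @param pcr_duplication_mean Mean PCR duplicates per captured molecule
#'   (geometric, minimum 1).
#' @param read_error_rate Per-base substitution error rate on reads.
#' @param tumor_mean_range,normal_mean_range,blood_factor,concentration
#'   Methylation-model parameters (see above).
#' @param read_len Read length for read-level simulation (nt).
#' @param seed Integer seed; mandatory, all randomness is reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(samples, seed,
                       n_molecules = 500, capture_efficiency = 0.3,
                       non_digestion_rate = 0.013,
                       pcr_duplication_mean = 3, read_error_rate = 0.001,
                       tumor_mean_range = c(0.5, 0.9),
                       normal_mean_range = c(0.05, 0.3),
                       blood_factor = 0.5, concentration = 12,
                       read_len = 50) {
  stopifnot(is.data.frame(samples),
            all(c("id", "tissue", "condition", "digested") %in% names(samples)),
            !anyDuplicated(samples$id),
            all(samples$condition %in% c("tumor", "normal", "blood")))
  probs <- c(capture_efficiency, non_digestion_rate, read_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (pcr_duplication_mean < 1) stop("pcr_duplication_mean must be >= 1")
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- list(samples = samples, seed = as.integer(seed),
              n_molecules = n_molecules,
              capture_efficiency = capture_efficiency,
              non_digestion_rate = non_digestion_rate,
              pcr_duplication_mean = pcr_duplication_mean,
              read_error_rate = read_error_rate,
              tumor_mean_range = tumor_mean_range,
              normal_mean_range = normal_mean_range,
              blood_factor = blood_factor, concentration = concentration,
              read_len = read_len)
  class(cfg) <- "sim_config"
  cfg
}

# Draw per-target condition means, then per-(sample, target) methylated
# fractions. Reference / no-CpG / lambda targets are never methylated in
# a way that matters: survival is category-driven in simulate_counts.
draw_truth <- function(panel, config) {
  tg <- panel$targets
  mu_t <- runif(nrow(tg), config$tumor_mean_range[1], config$tumor_mean_range[2])
  mu_n <- runif(nrow(tg), config$normal_mean_range[1], config$normal_mean_range[2])
  mu_b <- mu_n * config$blood_factor
  kon <- config$concentration
  truth <- expand.grid(sample = config$samples$id, target = tg$id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cond <- config$samples$condition[match(truth$sample, config$samples$id)]
  mu <- ifelse(cond == "tumor", mu_t[match(truth$target, tg$id)],
        ifelse(cond == "normal", mu_n[match(truth$target, tg$id)],
               mu_b[match(truth$target, tg$id)]))
  m <- rbeta(nrow(truth), mu * kon, (1 - mu) * kon)
  is_cpg <- tg$category[match(truth$target, tg$id)] == "cpg"
  truth$m <- ifelse(is_cpg, m, NA_real_)
  attr(truth, "target_means") <- data.frame(target = tg$id, category = tg$category,
                                            mu_tumor = mu_t, mu_normal = mu_n,
                                            mu_blood = mu_b)
  truth
}

# Per-molecule survival probability through digestion for one smMIP.
survival_prob <- function(category, m, digested, eps_nd) {
  if (!digested) return(1)
  switch(category,
         cpg        = m + (1 - m) * eps_nd,
         lambda_cpg = eps_nd,          # lambda DNA is never methylated
         1)                            # reference targets are never cut
}

#' Simulate deduplicated smMIP counts
#'
#' Generates the count matrix the read-level pipeline would produce: for
#' each sample and smMIP, the number of unique captured molecules is
#' Binomial(n_molecules, capture_efficiency x survival), where survival
#' through the digest is `m + (1 - m) * eps_nd` for a CpG target with
#' methylated fraction `m` and incomplete-digestion rate `eps_nd`, 1 for
#' reference targets (no recognition site / no CpG), `eps_nd` for lambda
#' CpG targets (lambda DNA is unmethylated), and 1 for every target in an
#' undigested control.
#'
#' @param panel A `mip_panel`.
#' @param config A [sim_config()].
#' @param truth Optional pre-drawn truth table (used for spike-in series);
#'   by default drawn from the config's methylation model.
#' @return list with `counts` (a [mip_counts()]) and `truth` (data.frame
#'   sample, target, m).
#' @export
simulate_counts <- function(panel, config, truth = NULL) {
  stopifnot(inherits(panel, "mip_panel"), inherits(config, "sim_config"))
  if (!any(panel$smmips$category == "lambda_cpg") ||
      !any(panel$smmips$category == "lambda_ref"))
    stop("panel must contain lambda control smMIPs (digestion QC)")
  with_seed(config$seed, {
    if (is.null(truth)) truth <- draw_truth(panel, config)
    sm <- panel$smmips
    n_sm <- nrow(sm); n_sa <- nrow(config$samples)
    counts <- matrix(0L, n_sm, n_sa,
                     dimnames = list(sm$id, config$samples$id))
    key <- paste(truth$sample, truth$target)
    m_of <- setNames(truth$m, key)
    for (j in seq_len(n_sa)) {
      samp <- config$samples[j, ]
      for (i in seq_len(n_sm)) {
        m <- m_of[[paste(samp$id, sm$target_id[i])]]
        p <- survival_prob(sm$category[i], m, samp$digested,
                           config$non_digestion_rate)
        counts[i, j] <- rbinom(1L, config$n_molecules,
                               config$capture_efficiency * p)
      }
    }
    list(counts = mip_counts(counts, config$samples, sm), truth = truth)
  })
}

random_umis <- function(n, len) {
  # distinct tags per molecule set: single-molecule tags are modeled
  # collision-free so UMI collapse recovers molecule counts exactly
  seen <- character(0)
  while (length(seen) < n) {
    need <- n - length(seen) + 4L
    m <- matrix(sample(c("A", "C", "G", "T"), need * len, replace = TRUE),
                nrow = need)
    seen <- unique(c(seen, do.call(paste0, asplit(m, 2))))
  }
  seen[seq_len(n)]
}

add_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    s <- strsplit(reads[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate paired reads with barcodes and UMIs
#'
#' Runs [simulate_counts()] under the same seed, then emits read pairs
#' for every unique captured molecule: each molecule receives a distinct
#' 10 nt single-molecule tag (5 nt per side) and a geometric number of
#' PCR duplicate read pairs (minimum 1, mean `pcr_duplication_mean`).
#' Read 1 carries the first 5 nt of the tag, the ligation arm and the
#' insert prefix; read 2 carries the last 5 nt, the extension arm and
#' the reverse-complemented insert suffix. Index reads I1/I2 carry the
#' sample's dual barcodes. Uniform substitution errors are applied to R1
#' and R2 at `read_error_rate`.
#'
#' @inheritParams simulate_counts
#' @return list with `reads` (data.frame r1, r2, i1, i2, quality-less),
#'   `counts` (the underlying [mip_counts()]) and `truth`.
#' @export
simulate_reads <- function(panel, config, truth = NULL) {
  if (!all(c("barcode1", "barcode2") %in% names(config$samples)))
    stop("read-level simulation requires sample barcodes")
  validate_barcodes(config$samples)
  sim <- simulate_counts(panel, config, truth)
  cm <- sim$counts
  with_seed(config$seed + 1L, {
    sm <- cm$smmips
    insert_of <- setNames(panel$targets$seq, panel$targets$id)
    half <- config$read_len - 5L - nchar(sm$ext_arm[1])  # insert bases per mate
    recs <- list()
    for (j in seq_len(ncol(cm$counts))) {
      samp <- cm$samples[j, ]
      for (i in seq_len(nrow(cm$counts))) {
        n_mol <- cm$counts[i, j]
        if (n_mol == 0L) next
        umis <- random_umis(n_mol, 10L)
        dups <- rgeom(n_mol, 1 / config$pcr_duplication_mean) + 1L
        insert <- insert_of[[sm$target_id[i]]]
        if (sm$tile[i] == "minus") insert <- revcomp(insert)
        r1 <- paste0(substr(umis, 1, 5), sm$lig_arm[i], substr(insert, 1, half))
        r2 <- paste0(substr(umis, 6, 10), sm$ext_arm[i],
                     revcomp(substr(insert, nchar(insert) - half + 1L,
                                    nchar(insert))))
        rep_idx <- rep(seq_len(n_mol), dups)
        recs[[length(recs) + 1L]] <- data.frame(
          r1 = r1[rep_idx], r2 = r2[rep_idx],
          i1 = samp$barcode1, i2 = samp$barcode2,
          true_sample = samp$id, true_smmip = sm$id[i],
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, recs)
    # shuffle so input order carries no information
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
    reads$r1 <- add_seq_errors(reads$r1, config$read_error_rate)
    reads$r2 <- add_seq_errors(reads$r2, config$read_error_rate)
    list(reads = reads, counts = cm, truth = sim$truth)
  })
}

#' Simulate a spike-in dilution series
#'
#' Emulates mixing experiments where tumor (or fully methylated) DNA is
#' spiked into a normal background at known fractions: the methylated
#' fraction of every CpG target in a sample with spike fraction `f` is
#' `f * m_tumor + (1 - f) * m_background`, with per-target `m_tumor`
#' and `m_background` drawn once from the config's tumor and blood-level
#' models.
#'
#' @inheritParams simulate_counts
#' @param fractions Numeric vector of spike-in fractions in `[0, 1]`;
#'   one simulated (digested) sample per fraction, named `spike_<pct>`.
#' @param replicates Samples per fraction.
#' @return list(`counts`, `truth`); `truth` carries a `spike_fraction`
#'   column.
#' @export
simulate_spikein_series <- function(panel, config, fractions,
                                    replicates = 1L) {
  if (any(fractions < 0 | fractions > 1))
    stop("spike fractions must lie in [0, 1]")
  samples <- do.call(rbind, lapply(seq_along(fractions), function(k)
    data.frame(id = sprintf("spike_%g_r%d", 100 * fractions[k],
                            seq_len(replicates)),
               tissue = "mix", condition = "normal", digested = TRUE,
               spike_fraction = fractions[k], stringsAsFactors = FALSE)))
  cfg <- config
  cfg$samples <- samples
  truth <- with_seed(cfg$seed + 2L, {
    tg <- panel$targets
    m_t <- runif(nrow(tg), cfg$tumor_mean_range[1], cfg$tumor_mean_range[2])
    m_b <- runif(nrow(tg), cfg$normal_mean_range[1], cfg$normal_mean_range[2]) *
      cfg$blood_factor
    truth <- expand.grid(sample = samples$id, target = tg$id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    f <- samples$spike_fraction[match(truth$sample, samples$id)]
    i <- match(truth$target, tg$id)
    truth$m <- ifelse(tg$category[i] == "cpg",
                      f * m_t[i] + (1 - f) * m_b[i], NA_real_)
    truth$spike_fraction <- f
    truth
  })
  sim <- simulate_counts(panel, cfg, truth = truth)
  sim$truth <- truth
  sim
}

#' Write simulated reads as gzipped FASTQ
#'
#' Emits R1/R2/I1/I2 FASTQ files (constant qualities; base-call quality
#' is not modeled) plus a sample-sheet TSV and a truth TSV.
#'
#' @param sim Result of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (for the sample sheet).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fastq_set <- function(sim, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("read%07d", seq_len(nrow(sim$reads)))
  paths <- c(R1 = file.path(dir, "R1.fastq.gz"), R2 = file.path(dir, "R2.fastq.gz"),
             I1 = file.path(dir, "I1.fastq.gz"), I2 = file.path(dir, "I2.fastq.gz"))
  for (part in names(paths)) {
    seqs <- Biostrings::DNAStringSet(sim$reads[[tolower(part)]])
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, paths[[part]], format = "fastq",
                                compress = TRUE)
  }
  ss <- file.path(dir, "samples.tsv")
  write.table(config$samples, ss, sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, samples = ss, truth = tt))
}
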