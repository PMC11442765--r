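#' The four methylation-sensitive restriction enzymes of the assay
#'
#' Returns the enzyme set used for the combined digest: HpaII (C^CGG),
#' HpyCH4IV (A^CGT), AciI (C^CGC) and HinP1I (G^CGC). Every recognition
#' motif is a 4-mer with a CpG in the middle, so cleavage is blocked by
#' methylation of that CpG. CCGG, ACGT and GCGC are palindromic; CCGC is
#' not, so its reverse complement GCGG is also a cut site on the forward
#' strand.
#'
#' @return A data.frame with columns `name` and `motif`.
#' @export
msre_enzymes <- function() {
  enz <- data.frame(
    name  = c("HpaII", "HpyCH4IV", "AciI", "HinP1I"),
    motif = c("CCGG", "ACGT", "CCGC", "GCGC"),
    stringsAsFactors = FALSE
  )
  stopifnot(nchar(enz$motif) == 4L, substr(enz$motif, 2L, 3L) == "CG")
  enz
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains non-DNA characters (allowed: A, C, G, T, N)",
         call. = FALSE)
  invisible(seq)
}

#' Scan a sequence for MSRE recognition sites
#'
#' Finds every occurrence of each enzyme motif on the forward strand and,
#' for non-palindromic motifs, occurrences of the reverse complement
#' (reported on the minus strand). Overlapping occurrences are all
#' reported; `N` never matches.
#'
#' @param seq A DNA string over the alphabet ACGTN.
#' @param enzymes Enzyme table as returned by [msre_enzymes()].
#' @return data.frame with columns `enzyme`, `pos` (0-based position of
#'   the motif start) and `strand` (`"+"` or `"-"`), ordered by position.
#' @export
scan_recognition_sites <- function(seq, enzymes = msre_enzymes()) {
  check_dna(seq)
  subject <- Biostrings::DNAString(seq)
  out <- list()
  for (i in seq_len(nrow(enzymes))) {
    motif <- enzymes$motif[i]
    hits <- Biostrings::matchPattern(motif, subject, fixed = TRUE)
    if (length(hits))
      out[[length(out) + 1L]] <- data.frame(
        enzyme = enzymes$name[i], pos = Biostrings::start(hits) - 1L,
        strand = "+", stringsAsFactors = FALSE)
    rc <- revcomp(motif)
    if (rc != motif) {
      hits <- Biostrings::matchPattern(rc, subject, fixed = TRUE)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(
          enzyme = enzymes$name[i], pos = Biostrings::start(hits) - 1L,
          strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(enzyme = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$enzyme), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of CpG sites covered by MSRE recognition sites
#'
#' Every recognition motif carries its methylation-sensing CpG in the
#' middle, so a CpG (CG dinucleotide) counts as covered when it is the
#' central CG of at least one recognition-site occurrence found by
#' [scan_recognition_sites()] (either strand). Combined, the four enzymes
#' cover roughly 39\% of CpGs genome-wide; on a targeted panel the
#' fraction reflects the panel design. The statistic is invariant under
#' reverse complementation of the input.
#'
#' @inheritParams scan_recognition_sites
#' @return Fraction in `[0, 1]`; 0 with a warning when the sequence has
#'   no CpG at all.
#' @export
cpg_coverage_fraction <- function(seq, enzymes = msre_enzymes()) {
  check_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  cg <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  if (cg[1] == -1L) {
    warning("sequence contains no CpG site; coverage fraction undefined, returning 0")
    return(0)
  }
  cpos <- as.integer(cg) - 1L            # 0-based C positions
  sites <- scan_recognition_sites(seq, enzymes)
  if (!nrow(sites)) return(0)
  mean(cpos %in% (sites$pos + 1L))

}

#' Classify a candidate reference region
#'
#' Reference regions normalize for DNA input because they are never
#' cleaved: they either contain no recognition site of the selected MSREs
#' or no CpG site at all. Regions with a recognition site are ineligible.
#'
#' @inheritParams scan_recognition_sites
#' @return One of `"ref_no_cpg"`, `"ref_no_site"`, `"ineligible"`.
#' @export
classify_reference_region <- function(seq, enzymes = msre_enzymes()) {
  check_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  if (!grepl("CG", seq, fixed = TRUE)) return("ref_no_cpg")
  if (nrow(scan_recognition_sites(seq, enzymes)) == 0L) return("ref_no_site")
  "ineligible"
}

#' Select hypermethylated CpG target sites from array beta values
#'
#' Applies the panel selection rule: a site is kept when (a) its mean
#' methylation in the tumor samples is at least `t_tumor` (default 0.5),
#' (b) its mean in every normal tissue group and in blood is at most
#' `t_normal` (default 0.3), and (c) it carries at least one MSRE
#' recognition site. With `mode = "per_type"` (default) the tumor
#' threshold must be cleared by every tumor type separately; with
#' `"pooled"` a single pooled tumor mean is used.
#'
#' @param betas Numeric matrix of methylation levels in `[0, 1]`; rows =
#'   CpG site ids, columns = samples.
#' @param groups data.frame with columns `sample`, `tissue`, `condition`
#'   (`"tumor"`, `"normal"` or `"blood"`) covering every column of
#'   `betas`.
#' @param site_info Named integer vector: recognition-site count per site
#'   id; must cover every row of `betas`.
#' @param t_tumor,t_normal Selection thresholds.
#' @param mode `"per_type"` or `"pooled"` tumor averaging.
#' @return Character vector of selected site ids.
#' @export
select_cpg_targets <- function(betas, groups, site_info,
                               t_tumor = 0.5, t_normal = 0.3,
                               mode = c("per_type", "pooled")) {
  mode <- match.arg(mode)
  if (any(betas < 0 | betas > 1)) stop("beta values must lie in [0, 1]")
  if (!all(colnames(betas) %in% groups$sample))
    stop("every sample column needs a group label")
  if (!all(rownames(betas) %in% names(site_info)))
    stop("every site needs a recognition-site count in `site_info`")
  groups <- groups[match(colnames(betas), groups$sample), , drop = FALSE]
  if (!all(groups$condition %in% c("tumor", "normal", "blood")))
    stop("condition must be tumor, normal or blood")

  grp_mean <- function(cols) rowMeans(betas[, cols, drop = FALSE])
  tum <- groups$condition == "tumor"
  if (mode == "per_type") {
    tum_ok <- Reduce(`&`, lapply(split(which(tum), groups$tissue[tum]),
                                 function(j) grp_mean(j) >= t_tumor))
  } else {
    tum_ok <- grp_mean(which(tum)) >= t_tumor
  }
  nrm <- groups$condition == "normal"
  nrm_ok <- Reduce(`&`, lapply(split(which(nrm), groups$tissue[nrm]),
                               function(j) grp_mean(j) <= t_normal))
  bld <- which(groups$condition == "blood")
  bld_ok <- if (length(bld)) grp_mean(bld) <= t_normal else TRUE
  has_site <- site_info[rownames(betas)] >= 1L
  rownames(betas)[tum_ok & nrm_ok & bld_ok & has_site]
}

#' @export
print.mip_panel <- function(x, ...) {
  cat("smMIP panel:", nrow(x$targets), "targets,", nrow(x$smmips),
      "smMIPs\n")
  print(table(x$targets$category))
  invisible(x)
}

new_mip_panel <- function(targets, smmips, reference) {
  stopifnot(all(smmips$target_id %in% targets$id),
            !anyDuplicated(smmips$id), !anyDuplicated(targets$id))
  if (anyDuplicated(c(smmips$ext_arm, smmips$lig_arm)))
    stop("smMIP arms must be unique across the panel")
  structure(list(targets = targets, smmips = smmips, reference = reference),
            class = "mip_panel")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_dna_no_cg <- function(n) {
  s <- rand_dna(n)
  while (grepl("CG", s, fixed = TRUE))
    s <- sub("CG", paste0("C", sample(c("A", "C", "T"), 1)), s, fixed = TRUE)
  s
}

# insert with >=1 CpG but no recognition site on either strand
rand_insert_ref_no_site <- function(n, enzymes) {
  repeat {
    s <- rand_dna_no_cg(n)
    k <- sample(seq_len(n - 4L), 1)
    s <- paste0(substr(s, 1, k - 1), "TCGT", substr(s, k + 4, n))
    if (grepl("CG", s, fixed = TRUE) &&
        nrow(scan_recognition_sites(s, enzymes)) == 0L) return(s)
  }
}

# insert carrying >=1 recognition site
rand_insert_cpg <- function(n, enzymes, n_motifs = 2L) {
  repeat {
    s <- rand_dna_no_cg(n)
    starts <- sort(sample(seq(1L, n - 4L, by = 5L), n_motifs))
    for (k in starts) {
      motif <- sample(enzymes$motif, 1)
      s <- paste0(substr(s, 1, k - 1), motif, substr(s, k + 4, n))
    }
    if (nrow(scan_recognition_sites(s, enzymes)) >= 1L) return(s)
  }
}

#' Build a synthetic smMIP panel
#'
#' Constructs a small panel with the structure of the real assay: CpG
#' targets carrying one or more MSRE recognition sites (double-tiled, one
#' smMIP per strand), reference targets without any recognition site or
#' without any CpG (always captured, used for normalization), and lambda
#' phage control targets (CpG-containing ones report incomplete
#' digestion, reference ones anchor the control ratio). Targets are laid
#' out contiguously on one synthetic contig per source with unique random
#' ~20 nt binding arms flanking a 50 nt insert.
#'
#' @param n_cpg Number of CpG target sites (each gets 2 smMIP tiles).
#' @param n_ref Number of human-like reference targets (half without
#'   recognition site, half without CpG; single-tiled).
#' @param n_lambda Number of lambda control targets (half CpG, half
#'   reference; single-tiled).
#' @param insert_len,arm_len Insert and binding-arm lengths (nt).
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @return A `mip_panel`: `$targets` (id, source, chrom, start, end,
#'   category, n_sites, seq), `$smmips` (id, target_id, tile, ext_arm,
#'   lig_arm, backbone, umi_len_per_side, category) and `$reference`
#'   (a [Biostrings::DNAStringSet] of contigs).
#' @export
make_synthetic_panel <- function(n_cpg = 20, n_ref = 20, n_lambda = 8,
                                 insert_len = 50, arm_len = 20, seed = 1) {
  enzymes <- msre_enzymes()
  with_seed(seed, {
    spec <- rbind(
      data.frame(source = "human", category = "cpg",
                 n = n_cpg, stringsAsFactors = FALSE),
      data.frame(source = "human", category = "ref_no_site", n = ceiling(n_ref / 2)),
      data.frame(source = "human", category = "ref_no_cpg",  n = floor(n_ref / 2)),
      data.frame(source = "lambda", category = "lambda_cpg", n = ceiling(n_lambda / 2)),
      data.frame(source = "lambda", category = "lambda_ref", n = floor(n_lambda / 2)))
    targets <- list(); smmips <- list(); contigs <- list(hs_syn = "", lambda_syn = "")
    backbone <- rand_dna(30)
    idx <- c(cpg = 0L, ref_no_site = 0L, ref_no_cpg = 0L,
             lambda_cpg = 0L, lambda_ref = 0L)
    for (r in seq_len(nrow(spec))) for (k in seq_len(spec$n[r])) {
      cat_ <- spec$category[r]
      idx[cat_] <- idx[cat_] + 1L
      id <- sprintf("%s_%03d", cat_, idx[cat_])
      insert <- switch(cat_,
        cpg        = rand_insert_cpg(insert_len, enzymes, sample(1:4, 1)),
        lambda_cpg = rand_insert_cpg(insert_len, enzymes, sample(1:2, 1)),
        ref_no_site = rand_insert_ref_no_site(insert_len, enzymes),
        ref_no_cpg = rand_dna_no_cg(insert_len),
        lambda_ref = if (k %% 2L == 1L) rand_insert_ref_no_site(insert_len, enzymes)
                     else rand_dna_no_cg(insert_len))
      n_sites <- nrow(scan_recognition_sites(insert, enzymes))
      chrom <- if (spec$source[r] == "human") "hs_syn" else "lambda_syn"
      up <- rand_dna(arm_len); down <- rand_dna(arm_len)
      start <- nchar(contigs[[chrom]]) + arm_len   # 0-based insert start
      contigs[[chrom]] <- paste0(contigs[[chrom]], up, insert, down)
      targets[[length(targets) + 1L]] <- data.frame(
        id = id, source = spec$source[r], chrom = chrom,
        start = start, end = start + insert_len, category = cat_,
        n_sites = n_sites, seq = insert, stringsAsFactors = FALSE)
      tiles <- if (cat_ == "cpg") c("plus", "minus") else "plus"
      for (tile in tiles) {
        if (tile == "plus") { ext <- up; lig <- down }
        else { ext <- revcomp(down); lig <- revcomp(up) }
        smmips[[length(smmips) + 1L]] <- data.frame(
          id = paste0(id, "_", tile), target_id = id, tile = tile,
          ext_arm = ext, lig_arm = lig, backbone = backbone,
          umi_len_per_side = 5L, category = cat_, stringsAsFactors = FALSE)
      }
    }
    targets <- do.call(rbind, targets); smmips <- do.call(rbind, smmips)
    reference <- Biostrings::DNAStringSet(unlist(contigs))
    new_mip_panel(targets, smmips, reference)
  })
}

#' Write / read a panel to TSV + FASTA
#'
#' The TSV carries one row per smMIP (id, target_id, tile, chrom, start,
#' end, category, ext_arm, lig_arm, n_sites); the FASTA carries the
#' panel contigs. `panel_to_bed()` exports the target intervals
#' (0-based, half-open) as BED.
#'
#' @param panel A `mip_panel`.
#' @param tsv,fasta,bed Output paths.
#' @name panel_io
#' @export
write_panel <- function(panel, tsv, fasta) {
  tab <- merge(panel$smmips,
               panel$targets[, c("id", "chrom", "start", "end", "n_sites", "seq")],
               by.x = "target_id", by.y = "id", sort = FALSE)
  tab <- tab[, c("id", "target_id", "tile", "chrom", "start", "end",
                 "category", "ext_arm", "lig_arm", "backbone",
                 "umi_len_per_side", "n_sites", "seq")]
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(panel$reference, fasta)
  invisible(tsv)
}

#' @rdname panel_io
#' @export
read_panel <- function(tsv, fasta) {
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  targets <- unique(tab[, c("target_id", "chrom", "start", "end",
                            "category", "n_sites", "seq")])
  names(targets)[1] <- "id"
  targets$source <- ifelse(grepl("^lambda", targets$chrom), "lambda", "human")
  smmips <- tab[, c("id", "target_id", "tile", "ext_arm", "lig_arm",
                    "backbone", "umi_len_per_side", "category")]
  new_mip_panel(targets, smmips, Biostrings::readDNAStringSet(fasta))
}

#' @rdname panel_io
#' @export
panel_to_bed <- function(panel, bed) {
  write.table(panel$targets[, c("chrom", "start", "end", "id")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
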