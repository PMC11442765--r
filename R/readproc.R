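hamming <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

#' Validate a dual-barcode design
#'
#' Demultiplexing tolerates one base error per barcode, so unambiguous
#' assignment requires every two samples' barcode pairs to differ by at
#' least 3 mismatches combined.
#'
#' @param samples data.frame with `id`, `barcode1`, `barcode2`.
#' @return Invisibly `TRUE`; errors when the design is ambiguous.
#' @export
validate_barcodes <- function(samples) {
  bc <- paste0(samples$barcode1, samples$barcode2)
  n <- length(bc)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (hamming(bc[i], bc[j]) < 3)
      stop(sprintf("barcode pairs of samples '%s' and '%s' are only %d mismatches apart (need >= 3)",
                   samples$id[i], samples$id[j], hamming(bc[i], bc[j])),
           call. = FALSE)
  invisible(TRUE)
}

# all sequences within Hamming distance <=1 of x
mismatch_neighbors <- function(x) {
  chars <- strsplit(x, "")
  unlist(lapply(seq_along(x), function(k) {
    s <- chars[[k]]
    neigh <- c(x[k], unlist(lapply(seq_along(s), function(p) {
      subs <- setdiff(c("A", "C", "G", "T", "N"), s[p])
      vapply(subs, function(b) {
        t <- s; t[p] <- b; paste(t, collapse = "")
      }, "")
    })))
    setNames(neigh, rep(x[k], length(neigh)))
  }))
}

# one-mismatch dictionary: maps every string within Hamming distance 1 of
# a key to that key's value; neighbors shared by keys with different
# values are ambiguous and map to NA
build_mm1_index <- function(keys, values) {
  neigh <- mismatch_neighbors(keys)
  val <- split(values[match(names(neigh), keys)], neigh)
  vapply(val, function(v) if (length(unique(v)) == 1L) v[[1]]
         else NA_character_, "")
}

#' Demultiplex read pairs by dual sample barcodes
#'
#' A pair is assigned to a sample when each of its two index reads
#' matches that sample's corresponding barcode within Hamming distance 1
#' and exactly one sample matches; otherwise it is unassigned.
#'
#' @param i1,i2 Character vectors of index reads.
#' @param samples data.frame with `id`, `barcode1`, `barcode2` (validated
#'   with [validate_barcodes()]).
#' @return Character vector of sample ids, `NA` for unassigned.
#' @export
demultiplex <- function(i1, i2, samples) {
  validate_barcodes(samples)
  n <- length(i1)
  assigned <- rep(NA_character_, n)
  d1 <- outer_hamming(i1, samples$barcode1)
  d2 <- outer_hamming(i2, samples$barcode2)
  ok <- (d1 <= 1L) & (d2 <= 1L)
  nhit <- rowSums(ok)
  one <- which(nhit == 1L)
  assigned[one] <- samples$id[max.col(ok[one, , drop = FALSE], "first")]
  assigned
}

# Hamming distances of each query against each barcode (queries x barcodes)
outer_hamming <- function(queries, barcodes) {
  qm <- do.call(rbind, strsplit(queries, ""))
  d <- vapply(barcodes, function(b) {
    bm <- strsplit(b, "")[[1]]
    rowSums(qm != matrix(bm, nrow(qm), length(bm), byrow = TRUE))
  }, numeric(length(queries)))
  matrix(d, nrow = length(queries), ncol = length(barcodes))
}

#' Assign read pairs to panel smMIPs by arm sequence
#'
#' After stripping the 5 nt molecular-tag prefix, read 1 must show the
#' ligation arm and read 2 the extension arm of the same smMIP, each
#' within one mismatch and starting within `max_offset` bases (default 5,
#' inclusive) of the expected position. Mates that disagree on the smMIP,
#' exceed the offset margin, or match no arm yield `NA`. A per-pair
#' alignment quality is emitted (`42` for two exact arm matches, minus 14
#' per mismatched arm) for downstream filtering.
#'
#' @param r1,r2 Character vectors of reads (with UMI prefix).
#' @param panel A `mip_panel`.
#' @param umi_len UMI prefix length per read (default 5).
#' @param max_offset Positional error margin in bases (inclusive).
#' @return data.frame with columns `smmip` (id or `NA`), `umi` (10 nt
#'   combined tag), `offset1`, `offset2`, `quality`, `reason` (`assigned`,
#'   `no_arm_match`, `mate_disagreement`).
#' @export
assign_read_pairs <- function(r1, r2, panel, umi_len = 5L, max_offset = 5L) {
  sm <- panel$smmips
  arm_len <- nchar(sm$lig_arm[1])
  lig_idx <- build_mm1_index(sm$lig_arm, sm$id)
  ext_idx <- build_mm1_index(sm$ext_arm, sm$id)
  lig_exact <- setNames(sm$id, sm$lig_arm)
  ext_exact <- setNames(sm$id, sm$ext_arm)

  lookup <- function(reads, idx, exact) {
    hit <- rep(NA_character_, length(reads))
    off <- rep(NA_integer_, length(reads))
    mm <- rep(NA_integer_, length(reads))
    for (o in 0:max_offset) {
      sub <- substr(reads, umi_len + o + 1L, umi_len + o + arm_len)
      todo <- is.na(hit)
      ex <- exact[sub[todo]]
      found <- !is.na(ex)
      hit[todo][found] <- ex[found]
      off[todo][found] <- o
      mm[todo][found] <- 0L
      todo <- is.na(hit)
      nr <- idx[sub[todo]]
      found <- !is.na(nr)
      hit[todo][found] <- nr[found]
      off[todo][found] <- o
      mm[todo][found] <- 1L
    }
    list(id = hit, offset = off, mismatches = mm)
  }
  h1 <- lookup(r1, lig_idx, lig_exact)
  h2 <- lookup(r2, ext_idx, ext_exact)
  smmip <- ifelse(!is.na(h1$id) & !is.na(h2$id) & h1$id == h2$id,
                  h1$id, NA_character_)
  reason <- ifelse(!is.na(smmip), "assigned",
                   ifelse(is.na(h1$id) | is.na(h2$id), "no_arm_match",
                          "mate_disagreement"))
  quality <- 42L - 14L * (ifelse(is.na(h1$mismatches), 0L, h1$mismatches) +
                          ifelse(is.na(h2$mismatches), 0L, h2$mismatches))
  data.frame(smmip = smmip,
             umi = paste0(substr(r1, 1, umi_len), substr(r2, 1, umi_len)),
             offset1 = h1$offset, offset2 = h2$offset,
             quality = quality, reason = reason, stringsAsFactors = FALSE)
}

#' Pair-level quality filter
#'
#' Keeps only properly paired reads (both mates assigned to the same
#' smMIP) with alignment quality strictly above `min_quality`.
#'
#' @param quality Numeric vector of per-pair qualities.
#' @param properly_paired Logical vector.
#' @param min_quality Threshold; pairs must exceed it (strict).
#' @return Logical pass/fail vector.
#' @export
quality_filter <- function(quality, properly_paired, min_quality = 15) {
  properly_paired & quality > min_quality
}

#' Collapse PCR duplicates on the single-molecule tag
#'
#' One representative (the first in input order) is retained per
#' (sample, smMIP, 10 nt tag) key; tags containing `N` are discarded.
#'
#' @param assignments data.frame with columns `sample`, `smmip`, `umi`
#'   (assigned pairs only).
#' @return The deduplicated data.frame, with a `dedup_discarded_n`
#'   attribute counting N-containing tags.
#' @export
deduplicate <- function(assignments) {
  bad <- grepl("N", assignments$umi, fixed = TRUE)
  out <- assignments[!bad, , drop = FALSE]
  key <- paste(out$sample, out$smmip, out$umi, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  attr(out, "dedup_discarded_n") <- sum(bad)
  out
}

#' Count unique molecules per sample and smMIP
#'
#' @param molecules Deduplicated assignment data.frame (`sample`,
#'   `smmip`).
#' @param panel A `mip_panel`.
#' @param samples Sample sheet data.frame (`id`, `tissue`, `condition`,
#'   `digested`); samples without reads keep an all-zero column.
#' @return A [mip_counts()].
#' @export
count_molecules <- function(molecules, panel, samples) {
  tab <- table(factor(molecules$smmip, levels = panel$smmips$id),
               factor(molecules$sample, levels = samples$id))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(panel$smmips$id, samples$id))
  mip_counts(m, samples, panel$smmips)
}

#' Full read-processing pipeline: FASTQ to counts
#'
#' Demultiplexes on the dual barcodes (one error per barcode), assigns
#' pairs to panel smMIPs by arm lookup within the positional margin,
#' applies the pair quality filter, collapses PCR duplicates on the 10 nt
#' single-molecule tag, and counts unique molecules per sample x smMIP.
#'
#' @param r1,r2,i1,i2 Character vectors of reads, or paths to (gzipped)
#'   FASTQ files.
#' @param panel A `mip_panel`.
#' @param samples Sample sheet with barcodes.
#' @param min_quality Pair quality threshold (strictly above).
#' @param max_offset Positional error margin (bases, inclusive).
#' @return list with `counts` (a [mip_counts()]) and `tally` (named
#'   integer vector of per-stage read-pair counts: total, demultiplexed,
#'   assigned, quality_pass, unique_molecules, plus discard reasons).
#' @export
process_reads <- function(r1, r2, i1, i2, panel, samples,
                          min_quality = 15, max_offset = 5L) {
  read_fq <- function(x) {
    if (length(x) == 1L && file.exists(x))
      as.character(Biostrings::readDNAStringSet(x, format = "fastq"))
    else x
  }
  r1 <- read_fq(r1); r2 <- read_fq(r2); i1 <- read_fq(i1); i2 <- read_fq(i2)
  stopifnot(length(r1) == length(r2), length(r1) == length(i1),
            length(r1) == length(i2))
  total <- length(r1)
  sample_id <- demultiplex(i1, i2, samples)
  keep <- !is.na(sample_id)
  asg <- assign_read_pairs(r1[keep], r2[keep], panel,
                           umi_len = panel$smmips$umi_len_per_side[1],
                           max_offset = max_offset)
  asg$sample <- sample_id[keep]
  paired <- !is.na(asg$smmip)
  pass <- quality_filter(asg$quality, paired, min_quality)
  mol <- deduplicate(asg[pass, c("sample", "smmip", "umi")])
  counts <- count_molecules(mol, panel, samples)
  tally <- c(total = total,
             demultiplexed = sum(keep),
             unassigned_barcode = sum(!keep),
             assigned = sum(paired),
             no_arm_match = sum(asg$reason == "no_arm_match"),
             mate_disagreement = sum(asg$reason == "mate_disagreement"),
             quality_pass = sum(pass),
             quality_fail = sum(paired & !pass),
             umi_with_N = attr(mol, "dedup_discarded_n"),
             unique_molecules = nrow(mol))
  list(counts = counts, tally = tally)
}
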