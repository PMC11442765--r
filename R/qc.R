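lambda_ratio <- function(x, sample_id) {
  cpg <- smmip_ids_by_category(x, "lambda_cpg")
  ref <- smmip_ids_by_category(x, "lambda_ref")
  if (!length(cpg) || !length(ref))
    stop("panel has no lambda control smMIPs", call. = FALSE)
  ref_sum <- sum(x$counts[ref, sample_id])
  if (ref_sum == 0)
    stop(sprintf("sample '%s' has zero lambda reference counts", sample_id),
         call. = FALSE)
  sum(x$counts[cpg, sample_id]) / ref_sum
}

#' Percentage of non-digested DNA from the lambda spike-in
#'
#' Unmethylated lambda phage DNA is spiked into every sample, so any
#' signal surviving on lambda CpG targets measures incomplete digestion.
#' The statistic is the sample's lambda CpG/reference count ratio divided
#' by the mean of that ratio over the undigested control samples, times
#' 100.
#'
#' @param x A [mip_counts()].
#' @param sample_id Sample to evaluate.
#' @param undigested_ids Ids of the undigested control samples (default:
#'   all samples with `digested == FALSE`).
#' @return Percentage (0 = complete digestion, 100 = no digestion).
#' @export
digestion_percentage <- function(x, sample_id,
                                 undigested_ids = x$samples$id[!x$samples$digested]) {
  if (!length(undigested_ids))
    stop("no undigested control samples available", call. = FALSE)
  r <- lambda_ratio(x, sample_id)
  r0 <- mean(vapply(undigested_ids, function(s) lambda_ratio(x, s), 0))
  100 * r / r0
}

#' Sample-level quality control
#'
#' Removes samples below the minimum total count and digested samples
#' whose non-digestion percentage strictly exceeds the threshold
#' (undigested controls are exempt from the digestion rule). The
#' undigested-control mean is computed over controls passing the depth
#' filter.
#'
#' @param x A [mip_counts()].
#' @param threshold_pct Maximum tolerated non-digestion percentage
#'   (removal requires strictly exceeding it).
#' @param min_counts Minimum total counts per sample (inclusive).
#' @return list with `counts` (filtered [mip_counts()]) and `report`
#'   (data.frame per sample: total_counts, non_digestion_pct, pass_depth,
#'   pass_digestion, removed, reason).
#' @export
apply_sample_qc <- function(x, threshold_pct = 5, min_counts = 5000) {
  totals <- colSums(x$counts)
  pass_depth <- totals >= min_counts
  deep <- x[, pass_depth]
  und <- deep$samples$id[!deep$samples$digested]
  pct <- rep(NA_real_, ncol(x$counts))
  names(pct) <- colnames(x$counts)
  for (s in colnames(deep$counts))
    pct[s] <- digestion_percentage(deep, s, und)
  pass_dig <- !x$samples$digested | (!is.na(pct) & pct <= threshold_pct)
  keep <- pass_depth & pass_dig
  reason <- ifelse(keep, "",
                   ifelse(!pass_depth, "below_min_counts", "failed_digestion"))
  report <- data.frame(id = colnames(x$counts), total_counts = totals,
                       non_digestion_pct = pct, pass_depth = pass_depth,
                       pass_digestion = pass_dig, removed = !keep,
                       reason = reason, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(counts = x[, keep], report = report)
}

#' Remove dead CpG smMIPs
#'
#' CpG smMIPs with zero counts in every sample carry no information and
#' are removed. Reference and lambda smMIPs are never removed here; an
#' all-zero reference smMIP is only flagged.
#'
#' @param x A [mip_counts()].
#' @return list with `counts` (filtered), `dropped` (removed CpG smMIP
#'   ids) and `flagged` (all-zero reference/lambda smMIP ids).
#' @export
drop_dead_smmips <- function(x) {
  all_zero <- rowSums(x$counts) == 0
  is_cpg <- x$smmips$category == "cpg"
  drop <- all_zero & is_cpg
  list(counts = x[!drop, ],
       dropped = x$smmips$id[drop],
       flagged = x$smmips$id[all_zero & !is_cpg])
}
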