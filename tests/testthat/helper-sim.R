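# Shared synthetic objects, built once per test run.

.tiny_panel <- make_synthetic_panel(n_cpg = 6, n_ref = 6, n_lambda = 4,
                                    seed = 11)

.std_panel <- make_synthetic_panel(seed = 42)

tiny_samples <- function(n_tumor = 3, n_normal = 3, n_blood = 1,
                         n_undigested = 2) {
  data.frame(
    id = c(sprintf("t%d", seq_len(n_tumor)), sprintf("n%d", seq_len(n_normal)),
           if (n_blood) sprintf("b%d", seq_len(n_blood)),
           if (n_undigested) sprintf("u%d", seq_len(n_undigested))),
    tissue = "lung",
    condition = c(rep("tumor", n_tumor), rep("normal", n_normal),
                  rep("blood", n_blood), rep("normal", n_undigested)),
    digested = c(rep(TRUE, n_tumor + n_normal + n_blood),
                 rep(FALSE, n_undigested)),
    stringsAsFactors = FALSE)
}

# minimal hand-built count object for QC arithmetic tests
manual_counts <- function(counts, digested) {
  samples <- data.frame(id = colnames(counts), tissue = "lung",
                        condition = "normal", digested = digested,
                        stringsAsFactors = FALSE)
  smmips <- data.frame(id = rownames(counts),
                       target_id = rownames(counts), tile = "plus",
                       category = sub("_[0-9]+$", "", rownames(counts)),
                       stringsAsFactors = FALSE)
  mip_counts(counts, samples, smmips)
}

# brute-force sliding-window motif scan, independent of the implementation
oracle_scan <- function(seq, enzymes = msre_enzymes()) {
  hits <- list()
  n <- nchar(seq)
  for (i in seq_len(nrow(enzymes))) {
    pats <- unique(c(enzymes$motif[i],
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(enzymes$motif[i])))))
    for (p in pats) {
      strand <- if (p == enzymes$motif[i]) "+" else "-"
      if (n >= 4) for (k in 1:(n - 3))
        if (substr(seq, k, k + 3) == p)
          hits[[length(hits) + 1]] <- data.frame(
            enzyme = enzymes$name[i], pos = k - 1L, strand = strand,
            stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(enzyme = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$pos, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# vector with exact given mean and sample sd
vector_with_moments <- function(mean, sd, n = 10) {
  v <- seq_len(n)
  mean + sd * (v - base::mean(v)) / stats::sd(v)
}
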