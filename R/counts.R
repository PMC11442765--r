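#' Deduplicated smMIP count matrix
#'
#' Container for the pipeline's central object: an integer matrix of
#' unique-molecule counts with smMIPs in rows and samples in columns,
#' plus sample metadata (tissue, condition, digested flag, barcodes) and
#' smMIP metadata (target, tile, category).
#'
#' @param counts Integer matrix, rows = smMIP ids, columns = sample ids.
#' @param samples data.frame with at least columns `id`, `tissue`,
#'   `condition` (`tumor` / `normal` / `blood`), `digested` (logical);
#'   one row per column of `counts`.
#' @param smmips data.frame with at least columns `id`, `target_id`,
#'   `tile`, `category`; one row per row of `counts`.
#' @return An object of class `mip_counts`.
#' @export
mip_counts <- function(counts, samples, smmips) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0)   # empty subsets lose dimnames
    dimnames(counts) <- list(rownames(counts) %||% character(0),
                             colnames(counts) %||% character(0))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs smMIP rownames and sample colnames")
  if (!identical(sort(rownames(counts)), sort(smmips$id)))
    stop("count rows and smMIP metadata disagree")
  if (!identical(sort(colnames(counts)), sort(samples$id)))
    stop("count columns and sample metadata disagree")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  smmips <- smmips[match(rownames(counts), smmips$id), , drop = FALSE]
  samples <- samples[match(colnames(counts), samples$id), , drop = FALSE]
  rownames(smmips) <- NULL; rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples, smmips = smmips),
            class = "mip_counts")
}

#' @export
print.mip_counts <- function(x, ...) {
  cat("mip_counts:", nrow(x$counts), "smMIPs x", ncol(x$counts), "samples\n")
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = ", "),
      "| undigested controls:", sum(!x$samples$digested), "\n")
  invisible(x)
}

#' @export
`[.mip_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  mip_counts(x$counts[i, j, drop = FALSE],
             x$samples[j, , drop = FALSE],
             x$smmips[i, , drop = FALSE])
}

smmip_ids_by_category <- function(x, categories) {
  x$smmips$id[x$smmips$category %in% categories]
}

#' Read / write a count matrix as TSV
#'
#' The counts TSV has smMIPs in rows and samples in columns with an `id`
#' first column; sample and smMIP metadata travel in companion TSVs.
#'
#' @param x A `mip_counts`.
#' @param counts_tsv,samples_tsv,smmips_tsv File paths.
#' @name counts_io
#' @export
write_counts <- function(x, counts_tsv, samples_tsv, smmips_tsv) {
  tab <- data.frame(id = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(tab, counts_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, samples_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$smmips, smmips_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_tsv)
}

#' @rdname counts_io
#' @export
read_counts <- function(counts_tsv, samples_tsv, smmips_tsv) {
  tab <- read.delim(counts_tsv, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  storage.mode(m) <- "integer"
  mip_counts(m,
             read.delim(samples_tsv, stringsAsFactors = FALSE),
             read.delim(smmips_tsv, stringsAsFactors = FALSE))
}
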