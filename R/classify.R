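#' Normalize counts by the summed reference smMIP counts
#'
#' The normalized count of smMIP i in sample A is its deduplicated count
#' divided by the sum of all reference smMIP counts in A, removing the
#' dependence on DNA input amount. Scale-invariant: doubling every count
#' in a sample leaves its normalized values unchanged.
#'
#' @param x A [mip_counts()].
#' @param reference_ids smMIP ids forming the denominator (default: all
#'   `ref_no_site` / `ref_no_cpg` smMIPs in the panel).
#' @return Numeric matrix (same dimnames as the counts) with attribute
#'   `reference_ids`.
#' @export
normalize_counts <- function(x, reference_ids =
                               smmip_ids_by_category(x, c("ref_no_site", "ref_no_cpg"))) {
  if (!length(reference_ids)) stop("empty reference smMIP set")
  missing_ref <- setdiff(reference_ids, rownames(x$counts))
  if (length(missing_ref))
    stop("reference smMIPs absent from counts: ",
         paste(missing_ref, collapse = ", "))
  denom <- colSums(x$counts[reference_ids, , drop = FALSE])
  zero <- names(denom)[denom == 0]
  if (length(zero))
    stop("zero reference counts in sample(s): ", paste(zero, collapse = ", "))
  out <- sweep(x$counts, 2, denom, "/")
  attr(out, "reference_ids") <- reference_ids
  out
}

#' Stratified cross-validation folds
#'
#' Randomly partitions samples into `n_folds` folds, stratified jointly
#' on (tissue, condition) so that tumor types are proportionally
#' represented in every fold; per-stratum fold sizes differ by at most
#' one. Deterministic given the seed.
#'
#' @param samples data.frame with `id`, `tissue`, `condition`.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..n_folds) named by sample
#'   id.
#' @export
stratified_folds <- function(samples, n_folds = 5, seed) {
  if (nrow(samples) < n_folds)
    stop("fewer samples than folds", call. = FALSE)
  with_seed(seed, {
    fold <- integer(nrow(samples))
    strata <- interaction(samples$tissue, samples$condition, drop = TRUE)
    for (g in split(seq_len(nrow(samples)), strata)) {
      if (length(g) < n_folds)
        warning(sprintf("stratum with %d samples spread over %d folds",
                        length(g), n_folds), call. = FALSE)
      fold[sample(g)] <- (sample.int(n_folds, 1L) + seq_along(g) - 2L) %% n_folds + 1L
    }
    setNames(fold, samples$id)
  })
}

#' Fit a univariate linear discriminant model
#'
#' Equal-variance Gaussian discriminant on one normalized-count feature:
#' class means, pooled within-class variance (n - 2 denominator) and
#' priors equal to class proportions. The score is the signed
#' discriminant difference, oriented so that larger values favor the
#' positive (tumor) class; the decision boundary is score = 0.
#'
#' @param values Numeric vector (one smMIP's normalized counts).
#' @param labels Logical vector, `TRUE` = tumor.
#' @return An `lda1d` model list: `mu_pos`, `mu_neg`, `var_pooled`,
#'   `prior_pos`, `degenerate`.
#' @export
fit_lda_1d <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 2 || n_neg < 2)
    stop("both classes need at least 2 samples", call. = FALSE)
  mu_pos <- mean(values[labels]); mu_neg <- mean(values[!labels])
  ss <- sum((values[labels] - mu_pos)^2) + sum((values[!labels] - mu_neg)^2)
  var_pooled <- ss / (n_pos + n_neg - 2)
  structure(list(mu_pos = mu_pos, mu_neg = mu_neg, var_pooled = var_pooled,
                 prior_pos = n_pos / (n_pos + n_neg),
                 degenerate = var_pooled == 0),
            class = "lda1d")
}

#' Score samples under a univariate LDA model
#'
#' @param model An `lda1d` from [fit_lda_1d()].
#' @param x Numeric vector of feature values.
#' @return Numeric scores; larger favors tumor, boundary at 0. Degenerate
#'   models (zero pooled variance) score +/-Inf by side of the class-mean
#'   midpoint and 0 at the midpoint.
#' @export
lda_score <- function(model, x) {
  with(model, {
    if (degenerate) {
      if (mu_pos == mu_neg) return(rep(0, length(x)))
      side <- sign((x - (mu_pos + mu_neg) / 2) * sign(mu_pos - mu_neg))
      return(ifelse(side == 0, 0, side * Inf))
    }
    x * (mu_pos - mu_neg) / var_pooled -
      (mu_pos^2 - mu_neg^2) / (2 * var_pooled) +
      log(prior_pos / (1 - prior_pos))
  })
}

#' Area under the ROC curve
#'
#' Probability that a random positive scores above a random negative,
#' ties counting one half: the Mann-Whitney statistic over all
#' cross-class pairs, computed from ranks.
#'
#' @param scores Numeric scores (larger favors positive).
#' @param labels Logical, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated AUC for one feature
#'
#' For each fold, fits [fit_lda_1d()] on the remaining folds and computes
#' the AUC of the held-out scores; the cvAUC is the mean over evaluable
#' folds. Folds whose held-out set contains a single class are skipped
#' and recorded.
#'
#' @param values Numeric vector (one smMIP's normalized counts).
#' @param labels Logical, `TRUE` = tumor.
#' @param folds Integer fold assignment from [stratified_folds()].
#' @return list with `fold_auc` (per evaluable fold), `cvauc` (their
#'   mean) and `skipped_folds`.
#' @export
cv_auc <- function(values, labels, folds) {
  fold_auc <- c(); skipped <- integer(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (length(unique(labels[test])) < 2 ||
        sum(labels[!test]) < 2 || sum(!labels[!test]) < 2) {
      skipped <- c(skipped, f); next
    }
    model <- fit_lda_1d(values[!test], labels[!test])
    fold_auc <- c(fold_auc, roc_auc(lda_score(model, values[test]),
                                    labels[test]))
  }
  if (!length(fold_auc))
    stop("no evaluable fold (single-class held-out sets)", call. = FALSE)
  list(fold_auc = fold_auc, cvauc = mean(fold_auc), skipped_folds = skipped)
}

#' Filter smMIP models on efficiency and discrimination
#'
#' Keeps smMIPs with at least `min_cum_undigested` cumulative counts over
#' the undigested control samples (capture efficiency) and cvAUC of at
#' least `min_cvauc` (both thresholds inclusive).
#'
#' @param evals data.frame with columns `id`, `cvauc`.
#' @param x A [mip_counts()] containing the undigested samples.
#' @param min_cum_undigested,min_cvauc Thresholds.
#' @return data.frame of surviving rows of `evals`, with a
#'   `cum_undigested` column added.
#' @export
filter_smmips <- function(evals, x, min_cum_undigested = 1000,
                          min_cvauc = 0.8) {
  und <- x$samples$id[!x$samples$digested]
  if (!length(und)) stop("no undigested samples in counts", call. = FALSE)
  cum <- rowSums(x$counts[evals$id, und, drop = FALSE])
  evals$cum_undigested <- as.numeric(cum)
  evals[evals$cum_undigested >= min_cum_undigested &
          evals$cvauc >= min_cvauc, , drop = FALSE]
}

#' Resolve double-tiled CpG sites to one smMIP
#'
#' When a CpG site is targeted by two smMIPs (one per strand), the
#' better-performing one is kept: highest cvAUC, ties broken by higher
#' cumulative undigested count, then lexicographically smaller id.
#'
#' @param evals data.frame with `id`, `target_id`, `cvauc`,
#'   `cum_undigested`.
#' @return data.frame with one row per target site.
#' @export
pick_best_tile <- function(evals) {
  pick <- function(g) {
    g <- g[order(-g$cvauc, -g$cum_undigested, g$id), , drop = FALSE]
    g[1, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(evals, evals$target_id), pick))
  rownames(out) <- NULL
  out[order(out$id), , drop = FALSE]
}

#' Score cutoff minimizing false positives plus false negatives
#'
#' Scans the midpoints between adjacent distinct scores (plus one
#' candidate below the minimum and one above the maximum) for the cutoff
#' of the rule "score >= cutoff is tumor" with the lowest FP + FN; among
#' ties the largest cutoff is returned (favoring specificity).
#'
#' @param scores Numeric scores.
#' @param labels Logical, `TRUE` = tumor.
#' @return The cutoff value.
#' @export
single_model_cutoff <- function(scores, labels) {
  s <- pmin(pmax(scores, -.Machine$double.xmax), .Machine$double.xmax)
  u <- sort(unique(s))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  cost <- vapply(cands, function(cut) {
    pred <- s >= cut
    sum(pred & !labels) + sum(!pred & labels)
  }, 0)
  max(cands[cost == min(cost)])
}

#' Ensemble vote threshold maximizing accuracy
#'
#' Given the tumor votes of every single smMIP model, picks the minimum
#' number of agreeing models k (rule: votes >= k is tumor) with the
#' highest overall accuracy; ties resolve to the smallest k (favoring
#' sensitivity).
#'
#' @param votes Logical matrix, samples x models.
#' @param labels Logical, `TRUE` = tumor.
#' @return list with `k` and `accuracy` (training accuracy at k).
#' @export
ensemble_vote_cutoff <- function(votes, labels) {
  nv <- rowSums(votes)
  ks <- seq_len(ncol(votes))
  acc <- vapply(ks, function(k) mean((nv >= k) == labels), 0)
  k <- ks[which.max(acc)]
  list(k = k, accuracy = max(acc))
}

#' Confusion-table metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total and balanced accuracy (sensitivity+specificity)/2,
#' rounded to three decimals. Metrics with a zero denominator are `NA`.
#'
#' @param tp,tn,fp,fn Confusion-table entries.
#' @param digits Rounding (default 3, the assay's reporting precision).
#' @return Named list: sensitivity, specificity, accuracy,
#'   balanced_accuracy.
#' @export
confusion_metrics <- function(tp, tn, fp, fn, digits = 3) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  acc <- div(tp + tn, tp + tn + fp + fn)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  lapply(list(sensitivity = sens, specificity = spec, accuracy = acc,
              balanced_accuracy = bal), round, digits = digits)
}

confusion_table <- function(truth, pred) {
  c(tp = sum(pred & truth), tn = sum(!pred & !truth),
    fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Train the ensemble tumor/normal classifier
#'
#' The full model-construction procedure on a QC-filtered count matrix:
#' reference normalization; stratified 5-fold cross-validation of a
#' univariate LDA per CpG smMIP (tumor vs non-tumor, blood counting as
#' non-tumor); removal of smMIPs with cvAUC below `min_cvauc` or fewer
#' than `min_cum_undigested` cumulative counts in the undigested
#' controls; resolution of double-tiled sites to the better tile; refit
#' of each surviving model on the full training set with a per-model
#' score cutoff minimizing FP + FN; and selection of the ensemble vote
#' threshold k maximizing training accuracy.
#'
#' Only digested samples are used for training; undigested controls
#' contribute the efficiency filter denominator.
#'
#' @param x A QC-filtered [mip_counts()] (see [apply_sample_qc()],
#'   [drop_dead_smmips()]).
#' @param seed Seed for fold assignment (the only stochastic step).
#' @param n_folds,min_cvauc,min_cum_undigested Procedure parameters.
#' @param reference_ids Normalization denominator smMIPs.
#' @return A `mip_ensemble`: included smMIP ids, per-smMIP `lda1d`
#'   models and cutoffs, vote threshold `k`, normalization reference set,
#'   per-smMIP evaluation table and training metrics.
#' @export
train_ensemble <- function(x, seed, n_folds = 5, min_cvauc = 0.8,
                           min_cum_undigested = 1000,
                           reference_ids =
                             smmip_ids_by_category(x, c("ref_no_site", "ref_no_cpg"))) {
  norm <- normalize_counts(x, reference_ids)
  train <- x$samples$digested
  if (!any(train)) stop("no digested samples to train on", call. = FALSE)
  samples <- x$samples[train, , drop = FALSE]
  labels <- samples$condition == "tumor"
  if (length(unique(labels)) < 2)
    stop("training set needs both tumor and non-tumor samples", call. = FALSE)
  nm <- norm[, samples$id, drop = FALSE]
  folds <- stratified_folds(samples, n_folds, seed)

  cpg_ids <- smmip_ids_by_category(x, "cpg")
  evals <- do.call(rbind, lapply(cpg_ids, function(p) {
    cv <- cv_auc(nm[p, ], labels, folds)
    data.frame(id = p,
               target_id = x$smmips$target_id[x$smmips$id == p],
               cvauc = cv$cvauc, n_folds_used = length(cv$fold_auc),
               stringsAsFactors = FALSE)
  }))
  surv <- filter_smmips(evals, x, min_cum_undigested, min_cvauc)
  if (!nrow(surv))
    stop("no smMIP passed the efficiency and cvAUC filters", call. = FALSE)
  final <- pick_best_tile(surv)

  models <- lapply(final$id, function(p) fit_lda_1d(nm[p, ], labels))
  names(models) <- final$id
  cutoffs <- vapply(final$id, function(p)
    single_model_cutoff(lda_score(models[[p]], nm[p, ]), labels), 0)
  votes <- vapply(final$id, function(p)
    lda_score(models[[p]], nm[p, ]) >= cutoffs[[p]], logical(nrow(samples)))
  vote <- ensemble_vote_cutoff(votes, labels)
  pred <- rowSums(votes) >= vote$k
  ct <- confusion_table(labels, pred)

  structure(list(smmips = final$id, models = models, cutoffs = cutoffs,
                 k = vote$k, reference_ids = attr(norm, "reference_ids"),
                 evals = evals, selected = final, seed = seed,
                 n_folds = n_folds, min_cvauc = min_cvauc,
                 min_cum_undigested = min_cum_undigested,
                 training = c(as.list(ct),
                              confusion_metrics(ct["tp"], ct["tn"],
                                                ct["fp"], ct["fn"]))),
            class = "mip_ensemble")
}

#' @export
print.mip_ensemble <- function(x, ...) {
  cat("smMIP ensemble classifier:", length(x$smmips),
      "single-smMIP LDA models, vote threshold k =", x$k, "\n")
  cat(sprintf("training: sens %.3f spec %.3f acc %.3f\n",
              x$training$sensitivity, x$training$specificity,
              x$training$accuracy))
  invisible(x)
}

#' Predict tumor/normal with a trained ensemble
#'
#' Each included single-smMIP model votes tumor when its score reaches
#' its cutoff; a sample is called tumor when at least k models agree.
#'
#' @param object A `mip_ensemble`.
#' @param x A [mip_counts()] containing every model smMIP and the
#'   normalization reference smMIPs.
#' @param ... Unused.
#' @return data.frame per sample: `id`, `votes`, `call` (`"tumor"` /
#'   `"non_tumor"`).
#' @export
predict.mip_ensemble <- function(object, x, ...) {
  missing_ids <- setdiff(object$smmips, rownames(x$counts))
  if (length(missing_ids))
    stop("model smMIPs absent from counts: ",
         paste(missing_ids, collapse = ", "))
  nm <- normalize_counts(x, object$reference_ids)
  votes <- vapply(object$smmips, function(p)
    lda_score(object$models[[p]], nm[p, ]) >= object$cutoffs[[p]],
    logical(ncol(nm)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  nv <- rowSums(votes)
  data.frame(id = colnames(nm), votes = as.integer(nv),
             call = ifelse(nv >= object$k, "tumor", "non_tumor"),
             stringsAsFactors = FALSE)
}

#' Serialize / restore an ensemble model as JSON
#'
#' @param model A `mip_ensemble`.
#' @param path JSON file path.
#' @name ensemble_io
#' @export
write_ensemble <- function(model, path) {
  obj <- list(smmips = model$smmips,
              models = lapply(model$models, unclass),
              cutoffs = as.list(model$cutoffs), k = model$k,
              reference_ids = model$reference_ids, seed = model$seed,
              n_folds = model$n_folds, min_cvauc = model$min_cvauc,
              min_cum_undigested = model$min_cum_undigested,
              training = model$training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ensemble_io
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj$smmips, function(p)
    structure(as.list(obj$models[[p]]), class = "lda1d"))
  names(models) <- obj$smmips
  structure(list(smmips = obj$smmips, models = models,
                 cutoffs = unlist(obj$cutoffs)[obj$smmips], k = obj$k,
                 reference_ids = obj$reference_ids, seed = obj$seed,
                 n_folds = obj$n_folds, min_cvauc = obj$min_cvauc,
                 min_cum_undigested = obj$min_cum_undigested,
                 training = obj$training),
            class = "mip_ensemble")
}
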