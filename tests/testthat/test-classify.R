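test_that("normalization divides by the per-sample reference sum", {
  m <- rbind(cpg_1 = c(10L, 40L), cpg_2 = c(0L, 0L),
             ref_no_site_1 = c(60L, 300L), ref_no_cpg_1 = c(40L, 200L))
  colnames(m) <- c("a", "b")
  x <- manual_counts(m, digested = c(TRUE, TRUE))
  nm <- normalize_counts(x)
  expect_equal(nm["cpg_1", ], c(a = 0.1, b = 0.08))
  expect_equal(nm["cpg_2", ], c(a = 0, b = 0))
  # scale invariance: doubling a sample's counts changes nothing
  x2 <- x; x2$counts[, "a"] <- 2L * x2$counts[, "a"]
  expect_equal(normalize_counts(x2)[, "a"], nm[, "a"])
  xz <- x; xz$counts[c("ref_no_site_1", "ref_no_cpg_1"), "a"] <- 0L
  expect_error(normalize_counts(xz), "sample\\(s\\): a")
})

test_that("stratified folds balance strata and are seed-deterministic", {
  s <- data.frame(id = sprintf("s%02d", 1:20),
                  tissue = rep("lung", 20),
                  condition = rep(c("tumor", "normal"), each = 10))
  f1 <- stratified_folds(s, 5, seed = 9)
  f2 <- stratified_folds(s, 5, seed = 9)
  expect_identical(f1, f2)
  for (g in split(f1, s$condition))
    expect_true(all(table(factor(g, levels = 1:5)) == 2))
  w <- capture_warnings(
    stratified_folds(data.frame(id = letters[1:6],
                                tissue = c(rep("a", 3), rep("b", 3)),
                                condition = "tumor"), 5, seed = 1))
  expect_match(w, "stratum", all = TRUE)
  expect_length(w, 2)
  expect_error(stratified_folds(s[1:3, ], 5, seed = 1), "fewer samples")
})

test_that("univariate LDA matches hand-derived boundaries and MASS::lda", {
  # symmetric classes, equal priors: boundary at the midpoint 5
  m <- fit_lda_1d(c(1, 2, 3, 7, 8, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(lda_score(m, 5), 0)
  expect_gt(lda_score(m, 4), 0)      # larger score towards the tumor class
  # {0,0,1} vs {2,3,4}: pooled variance 2/3, boundary 5/3
  m2 <- fit_lda_1d(c(0, 0, 1, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(m2$var_pooled, 2 / 3)
  expect_equal(lda_score(m2, 5 / 3), 0)
  # translation equivariance
  m3 <- fit_lda_1d(c(0, 0, 1, 2, 3, 4) + 10,
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(lda_score(m3, 5 / 3 + 10), 0)
  expect_error(fit_lda_1d(1:4, rep(TRUE, 4)), "both classes")
  # degenerate: zero pooled variance scores by side of the midpoint
  md <- fit_lda_1d(c(1, 1, 3, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(md$degenerate)
  expect_equal(lda_score(md, c(0, 2, 4)), c(Inf, 0, -Inf))
  # cross-check posterior boundary against MASS on random data
  skip_if_not_installed("MASS")
  set.seed(31)
  x <- c(rnorm(20, 2), rnorm(25, 0)); lab <- rep(c(TRUE, FALSE), c(20, 25))
  fit <- MASS::lda(x = data.frame(v = x), grouping = lab)
  ours <- fit_lda_1d(x, lab)
  post <- predict(fit, data.frame(v = x))$posterior[, "TRUE"]
  expect_equal(lda_score(ours, x) > 0, post > 0.5)
})

test_that("roc_auc equals the brute-force pair statistic and Mann-Whitney U", {
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                       rep(c(TRUE, FALSE), each = 3)), 8 / 9)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "both classes")
  set.seed(77)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- sample(round(rnorm(n), sample(0:2, 1)))   # rounding induces ties
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab))
    w <- suppressWarnings(wilcox.test(sc[lab], sc[!lab]))
    expect_equal(roc_auc(sc, lab),
                 unname(w$statistic) / (sum(lab) * sum(!lab)))
  }
})

test_that("cross-validated AUC behaves at the separable and null extremes", {
  s <- data.frame(id = sprintf("s%02d", 1:40), tissue = "lung",
                  condition = rep(c("tumor", "normal"), 20))
  folds <- stratified_folds(s, 5, seed = 2)
  lab <- s$condition == "tumor"
  sep <- ifelse(lab, 10, 0) + rnorm(40, sd = 0.01)
  cv <- cv_auc(sep, lab, folds)
  expect_equal(cv$cvauc, 1)
  expect_equal(cv$cvauc, mean(cv$fold_auc))
  set.seed(3)
  nulls <- replicate(40, cv_auc(rnorm(40), lab, folds)$cvauc)
  expect_lt(abs(mean(nulls) - 0.5), 3 * sd(nulls) / sqrt(length(nulls)))
})

test_that("smMIP filters apply inclusive efficiency and cvAUC cutoffs", {
  m <- rbind(cpg_a = c(999L, 0L), cpg_b = c(600L, 400L),
             cpg_c = c(2500L, 2500L), lambda_ref_1 = c(1L, 1L))
  colnames(m) <- c("u1", "u2")
  x <- manual_counts(m, digested = c(FALSE, FALSE))
  evals <- data.frame(id = c("cpg_a", "cpg_b", "cpg_c"),
                      target_id = c("t1", "t2", "t3"),
                      cvauc = c(0.95, 0.80, 0.79))
  out <- filter_smmips(evals, x)
  expect_equal(out$id, "cpg_b")        # 999 fails efficiency, 0.79 fails cvAUC
  expect_equal(out$cum_undigested, 1000)
  expect_error(filter_smmips(evals, manual_counts(m, digested = c(TRUE, TRUE))),
               "no undigested")
})

test_that("double-tile resolution keeps the better tile with stated tie-breaks", {
  evals <- data.frame(
    id = c("t1_plus", "t1_minus", "t2_plus", "t3_plus", "t3_minus"),
    target_id = c("t1", "t1", "t2", "t3", "t3"),
    cvauc = c(0.91, 0.88, 0.85, 0.9, 0.9),
    cum_undigested = c(1500, 9000, 1200, 4000, 2000))
  out <- pick_best_tile(evals)
  expect_setequal(out$id, c("t1_plus", "t2_plus", "t3_plus"))
})

test_that("single-model cutoff minimizes FP+FN with the largest-tie rule", {
  sc <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  lab <- rep(c(TRUE, FALSE), each = 3)
  expect_equal(single_model_cutoff(sc, lab), 0.75)
  # separable: zero errors at the gap midpoint
  expect_equal(single_model_cutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               3.5)
  # identical scores: all called non-tumor when normals outnumber tumors
  cut_all_same <- single_model_cutoff(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_gt(cut_all_same, 2)
  cut_more_tum <- single_model_cutoff(rep(2, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_lt(cut_more_tum, 2)
  # exhaustive-scan oracle on random instances
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    sc <- round(rnorm(n), 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    cut <- single_model_cutoff(sc, lab)
    cost <- function(cands) vapply(cands, function(ct)
      sum((sc >= ct) & !lab) + sum((sc < ct) & lab), 0)
    grid <- sort(unique(c(sc - 0.05, sc + 0.05)))
    expect_equal(cost(cut), min(cost(grid)))
  }
})

test_that("ensemble vote threshold maximizes accuracy, smallest k on ties", {
  votes <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  res <- ensemble_vote_cutoff(votes, lab)
  expect_equal(res$k, 2)
  expect_equal(res$accuracy, 1)
  # all models always vote tumor: every k ties, smallest returned
  all_t <- matrix(TRUE, 4, 3)
  expect_equal(ensemble_vote_cutoff(all_t, c(TRUE, TRUE, TRUE, TRUE))$k, 1)
  # individually perfect models: max accuracy at every k, smallest returned
  perf <- matrix(rep(lab, 3), ncol = 3)
  expect_equal(ensemble_vote_cutoff(perf, lab)$k, 1)
  # exhaustive oracle
  set.seed(21)
  for (i in 1:20) {
    v <- matrix(runif(8 * 5) > 0.5, 8, 5)
    lb <- sample(c(TRUE, FALSE), 8, TRUE)
    res <- ensemble_vote_cutoff(v, lb)
    accs <- vapply(1:5, function(k) mean((rowSums(v) >= k) == lb), 0)
    expect_equal(res$accuracy, max(accs))
    expect_equal(res$k, min(which(accs == max(accs))))
  }
})

test_that("confusion metrics reproduce the multi-cancer and per-type values", {
  m <- confusion_metrics(tp = 104, tn = 135, fp = 14, fn = 6)
  expect_equal(m$sensitivity, 0.945)
  expect_equal(m$specificity, 0.906)
  expect_equal(m$accuracy, 0.923)
  expect_equal(m$balanced_accuracy, 0.926)
  expect_equal(confusion_metrics(tp = 21, tn = 0, fp = 0, fn = 1)$sensitivity,
               0.955)
  expect_equal(confusion_metrics(1, 1, 0, 0),
               list(sensitivity = 1, specificity = 1, accuracy = 1,
                    balanced_accuracy = 1))
  # zero denominators yield NA, not 0
  expect_true(is.na(confusion_metrics(0, 5, 1, 0)$sensitivity))
})

test_that("trained ensembles predict their training data self-consistently", {
  set.seed(6)
  s <- tiny_samples(n_tumor = 10, n_normal = 10, n_blood = 2,
                    n_undigested = 6)
  cfg <- sim_config(s, seed = 61, n_molecules = 800,
                    capture_efficiency = 0.5)
  x <- simulate_counts(.tiny_panel, cfg)$counts
  model <- suppressWarnings(train_ensemble(x, seed = 62))
  pred <- predict(model, x[, x$samples$digested])
  lab <- x$samples$condition[x$samples$digested] == "tumor"
  ct <- c(tp = sum(pred$call == "tumor" & lab),
          tn = sum(pred$call == "non_tumor" & !lab),
          fp = sum(pred$call == "tumor" & !lab),
          fn = sum(pred$call == "non_tumor" & lab))
  expect_equal(as.list(ct), model$training[c("tp", "tn", "fp", "fn")])
  # votes == k is tumor; votes == k - 1 is not
  expect_true(all(pred$call[pred$votes >= model$k] == "tumor"))
  expect_true(all(pred$call[pred$votes < model$k] == "non_tumor"))
  expect_error(predict(model, x[!(rownames(x$counts) %in% model$smmips[1]), ]),
               "absent")
  # JSON round trip preserves predictions
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(model, path)
  model2 <- read_ensemble(path)
  expect_equal(predict(model2, x[, x$samples$digested]), pred)
})
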