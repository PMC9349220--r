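vote_df <- function(votes_dem, votes_non) {
  data.frame(
    true_label = c(rep("dementia", length(votes_dem)),
                   rep("non_dementia", length(votes_non))),
    votes = c(votes_dem, votes_non))
}

test_that("vote threshold selection enumerates thresholds with low ties", {
  # perfect separation: accuracy 1 at every threshold 1..10, tie -> 1
  rec <- vote_df(rep(10L, 6), rep(0L, 7))
  sel <- select_vote_threshold(rec, n_splits = 10)
  expect_identical(sel$threshold, 1L)
  expect_equal(sel$table$accuracy[2:11], rep(1, 10))
  expect_equal(sel$table$accuracy[1], 6 / 13)  # threshold 0: all dementia
  # single dementia record with 3 votes: accuracy 1 for k <= 3, else 0
  one <- vote_df(3L, integer(0))
  sel1 <- select_vote_threshold(one, n_splits = 10)
  expect_equal(sel1$table$accuracy, c(rep(1, 4), rep(0, 7)))
  expect_identical(sel1$threshold, 0L)
})

test_that("threshold 0 reproduces the prevalence baseline accuracy", {
  rec <- vote_df(rep(5L, 193), rep(5L, 239))
  sel <- select_vote_threshold(rec, n_splits = 10)
  expect_equal(sel$table$accuracy[1], 193 / 432)
  expect_equal(round(sel$table$accuracy[1], 3), 0.447)
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # 193 dementia with 23 false negatives; 239 non-dementia with 20 false
  # positives (votes 10 = predicted dementia at threshold 1)
  rec <- vote_df(c(rep(10L, 170), rep(0L, 23)), c(rep(0L, 219), rep(10L, 20)))
  m <- compute_metrics(rec, threshold = 1)
  expect_equal(m$accuracy, (170 + 219) / 432)
  expect_equal(m$sensitivity, 170 / 193)
  expect_equal(m$specificity, 219 / 239)
  expect_equal(round(c(m$accuracy, m$sensitivity, m$specificity), 3),
               c(0.900, 0.881, 0.916))
  expect_identical(m$counts$incorrect, 43L + 0L)
  # identity accuracy = (sens P + spec N) / (P + N), exactly
  expect_identical(m$accuracy, (m$sensitivity * 193 + m$specificity * 239) /
                     432)
  # all-correct boundary
  perfect <- compute_metrics(vote_df(rep(10L, 4), rep(0L, 5)), 1)
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity), c(1, 1, 1))
  expect_error(compute_metrics(rec, 1, filter = rep(FALSE, 432)), "records")
})

test_that("AUC equals brute-force pairwise concordance and the tie
           conventions hold", {
  # 4-sample toy set, hand-enumerated positive-negative pairs
  y <- c(1L, 1L, 0L, 0L)
  brute <- function(s) {
    pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
    mean(ifelse(s[pairs$p] > s[pairs$n], 1, ifelse(s[pairs$p] == s[pairs$n],
                                                   0.5, 0)))
  }
  s1 <- c(0.9, 0.4, 0.6, 0.2)
  s2 <- c(0.9, 0.6, 0.6, 0.2)
  fake <- list(scores = cbind(s1, s2),
               records = data.frame(true_label = ifelse(y == 1, "dementia",
                                                        "non_dementia")))
  auc <- compute_auc(fake)
  expect_equal(unname(auc$aucs), c(brute(s1), brute(s2)))
  expect_equal(unname(auc$aucs), c(0.75, 0.875))
  expect_equal(auc$auc_mean, mean(auc$aucs))
  # indicator scores -> every slot AUC 1; constant scores -> 0.5
  ind <- list(scores = cbind(y, y), records = fake$records)
  expect_equal(unname(compute_auc(ind)$aucs), c(1, 1))
  const <- list(scores = matrix(0.4, 4, 2), records = fake$records)
  expect_equal(unname(compute_auc(const)$aucs), c(0.5, 0.5))
  one_class <- list(scores = cbind(s1), records = data.frame(
    true_label = rep("dementia", 4)))
  expect_error(compute_auc(one_class), "single-class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    y <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(40), 2)  # rounding forces ties
    fake <- list(scores = cbind(s),
                 records = data.frame(true_label = ifelse(y == 1, "dementia",
                                                          "non_dementia")))
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<")))
    expect_equal(unname(compute_auc(fake)$aucs), as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("the Yates chi-square reproduces the printed subgroup statistics
           and clamps at zero", {
  cs <- chi_square_2x2(rbind(c(389, 43), c(297, 27)))
  expect_equal(round(cs$statistic, 3), 0.402)
  expect_equal(round(cs$p_value, 3), 0.526)
  expect_equal(round(chi_square_2x2(rbind(c(145, 17),
                                          c(244, 26)))$statistic, 3), 0.015)
  expect_equal(round(chi_square_2x2(rbind(c(166, 12),
                                          c(223, 31)))$statistic, 3), 2.902)
  # O = E in every cell: the correction clamps the statistic to zero
  expect_identical(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("the Yates implementation matches the textbook oracle on random
           tables", {
  set.seed(7)
  for (i in 1:1000) {
    tab <- matrix(stats::rpois(4, lambda = sample(3:40, 1)) + 1, 2, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("stratified splits keep the 3:1 class allocation within one
           sample per class", {
  for (n1 in c(5, 9, 16, 31)) {
    for (n0 in c(4, 12, 25)) {
      labels <- c(rep("dementia", n1), rep("non_dementia", n0))
      for (seed in 1:5) {
        part <- convoscreen:::.stratified_split(labels, seed)
        expect_identical(sort(c(part$train, part$val)),
                         seq_along(labels))
        for (cls in unique(labels)) {
          n_cls <- sum(labels == cls)
          n_val <- sum(labels[part$val] == cls)
          expect_lte(abs(n_val - n_cls / 4), 1)
          expect_gte(n_val, 1)
          expect_gte(sum(labels[part$train] == cls), 1)
        }
      }
    }
  }
})

test_that("held-out subjects never reach their own training pools", {
  setup <- small_eval_setup()
  samples <- as.data.frame(setup$lab)
  for (i in seq_len(nrow(samples))) {
    pool <- convoscreen:::.training_pool(samples, i)
    expect_false(samples$subject_id[i] %in% samples$subject_id[pool])
    expect_true(all(samples$training_eligible[pool]))
    expect_false(i %in% pool)
  }
})

test_that("the ensemble emits one vote record per session with consistent
           votes, and every family plugs into the evaluation", {
  setup <- small_eval_setup()
  lab <- setup$lab
  vecs <- setup$emb$document_vectors
  cfg <- cv_config(n_splits = 3, seed = 17)
  for (kind in c("gnb", "lr")) {
    fit <- loocv_ensemble(lab, vecs, classifier_spec(kind, seed = 2), cfg)
    expect_identical(nrow(fit$records), nrow(lab))
    expect_true(all(fit$records$votes >= 0 & fit$records$votes <= 3))
    expect_identical(fit$records$votes,
                     as.integer(rowSums(fit$scores >= 0.5)))
  }
  # remaining families on a further reduced slice for substitutability
  keep <- seq_len(24)
  slab <- lab[keep, ]
  for (kind in c("dnn", "svc", "xgb")) {
    spec <- classifier_spec(kind, if (kind == "dnn")
      list(max_epochs = 30L) else list(), seed = 2)
    fit <- loocv_ensemble(slab, vecs[keep, ], spec,
                          cv_config(n_splits = 2, seed = 3))
    expect_identical(nrow(fit$records), length(keep))
    expect_true(all(fit$records$votes %in% 0:2))
  }
})

test_that("a strongly separated cohort yields unanimous, correct votes", {
  dc <- disjoint_corpus(n_per_class = 8, len = 80)
  emb <- train_document_embedder(dc$docs, embedding_config(seed = 6))
  lab <- data.frame(
    subject_id = paste0("S", seq_along(dc$labels)),
    session_id = paste0("S", seq_along(dc$labels), "-1"),
    label = dc$labels, training_eligible = TRUE, excluded = FALSE,
    age = 70, sex = "female")
  fit <- loocv_ensemble(lab, emb$document_vectors,
                        classifier_spec("gnb", seed = 1),
                        cv_config(n_splits = 10, seed = 9))
  expect_identical(fit$records$votes[lab$label == "dementia"], rep(10L, 8))
  expect_identical(fit$records$votes[lab$label == "non_dementia"],
                   rep(0L, 8))
  # each fitted model separates its own training classes: implied by
  # unanimous correct votes plus perfect per-slot AUC
  expect_equal(compute_auc(fit)$auc_mean, 1)
})

test_that("the evaluation refuses a pool missing one class", {
  lab <- data.frame(
    subject_id = c("A", "B", "C"), session_id = c("A-1", "B-1", "C-1"),
    label = c("dementia", "dementia", "non_dementia"),
    training_eligible = c(TRUE, TRUE, FALSE), excluded = FALSE,
    age = 70, sex = "male")
  vecs <- matrix(stats::rnorm(30), 3, 10)
  expect_error(loocv_ensemble(lab, vecs, classifier_spec("gnb"),
                              cv_config(n_splits = 2, seed = 1)),
               "lacks a class")
})

test_that("the letter-length curve uses the 100-letter grid and equals the
           full-length accuracy beyond the longest document", {
  setup <- small_eval_setup()
  lab <- setup$lab
  emb <- setup$emb
  fit <- loocv_ensemble(lab, emb$document_vectors,
                        classifier_spec("gnb", seed = 2),
                        cv_config(n_splits = 3, seed = 17),
                        keep_models = TRUE)
  sel <- select_vote_threshold(fit)
  curve <- letter_length_curve(fit, lab, emb, threshold = sel$threshold,
                               step = 1000)
  expect_identical(curve$length, seq(1000, max(curve$length), by = 1000))
  expect_gte(max(curve$length), max(lab$letter_count))
  full <- compute_metrics(fit, sel$threshold)$accuracy
  expect_identical(curve$accuracy[nrow(curve)], full)
  expect_error(letter_length_curve(fit, lab, emb, step = 0), "positive")
})
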