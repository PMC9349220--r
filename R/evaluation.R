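# Validation architecture: every session is held out once; models never see
# other sessions of the held-out subject nor sessions failing the training
# criteria; ten stratified 3:1 train/validation re-splits give ten models
# whose votes are thresholded into the final screening decision.

#' Cross-validation configuration
#'
#' @param n_splits Number of stratified train/validation re-splits (and so
#'   of models voting) per held-out sample; default 10.
#' @param vote_threshold Optional pre-registered vote threshold in
#'   `0..n_splits`; `NULL` selects the accuracy-maximizing threshold from
#'   the pooled held-out votes.
#' @param seed Base seed. Split `i` for held-out sample `s` uses
#'   `seed + (s - 1) * n_splits + i`, recorded for exact replay.
#' @return A `cv_config`.
#' @export
cv_config <- function(n_splits = 10L, vote_threshold = NULL, seed = 1L) {
  stopifnot(n_splits >= 1)
  if (!is.null(vote_threshold))
    stopifnot(vote_threshold >= 0, vote_threshold <= n_splits)
  structure(list(n_splits = as.integer(n_splits),
                 vote_threshold = vote_threshold, seed = as.integer(seed)),
            class = "cv_config")
}

# Training pool for held-out sample i: every other session that belongs to
# a different subject and meets the training criteria.
.training_pool <- function(samples, i) {
  which(samples$subject_id != samples$subject_id[i] &
          samples$training_eligible)
}

# Stratified 3:1 partition of pool indices; exact allocation up to rounding
# (within one sample per class), at least one of each class in both parts.
.stratified_split <- function(labels, seed) {
  set.seed(seed)
  train <- integer(0)
  val <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    n_val <- max(1L, min(length(idx) - 1L, round(length(idx) / 4)))
    val <- c(val, idx[seq_len(n_val)])
    train <- c(train, idx[-seq_len(n_val)])
  }
  list(train = train, val = val)
}

#' Subject-aware leave-one-out evaluation with ensemble voting
#'
#' For each session `s`: hold out `s`; drop from the remainder every session
#' of the same subject and every session that fails the training criteria;
#' form `n_splits` seeded stratified partitions into training and validation
#' at 3:1 with the dementia/non-dementia ratio preserved; fit one model per
#' partition and score `s` with each. The number of models scoring `s` at or
#' above 0.5 is its vote count. Every session — training-eligible or not —
#' is a test case.
#'
#' @param labeled A `labeled_cohort` from [label_cohort()]; excluded
#'   sessions are dropped.
#' @param vectors Numeric feature matrix aligned row-for-row with the
#'   non-excluded sessions of `labeled` (e.g. `$document_vectors` of a
#'   [train_document_embedder()] fit on those sessions).
#' @param spec A [classifier_spec()].
#' @param config A [cv_config()].
#' @param keep_models Keep the fitted models per held-out sample (required
#'   by [letter_length_curve()]).
#' @param verbose Print progress to standard error.
#' @return A `vote_loocv` object: `$records` (one row per held-out session:
#'   ids, true label, votes, subgroup fields), `$scores` (sessions x
#'   `n_splits` score matrix), the config/spec, and optionally `$models`.
#' @export
loocv_ensemble <- function(labeled, vectors, spec, config = cv_config(),
                           keep_models = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "cv_config"), inherits(spec, "classifier_spec"))
  samples <- as.data.frame(labeled)
  if (!is.null(samples$excluded)) samples <- samples[!samples$excluded, ]
  n <- nrow(samples)
  stopifnot(is.matrix(vectors), nrow(vectors) == n)
  if (anyNA(samples$label)) stop("every sample must carry a label")
  k <- config$n_splits
  scores <- matrix(NA_real_, n, k)
  votes <- integer(n)
  models <- if (keep_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pool <- .training_pool(samples, i)
    # leakage guard: the held-out subject must not reach the training pool
    stopifnot(!samples$subject_id[i] %in% samples$subject_id[pool])
    if (length(unique(samples$label[pool])) < 2L)
      stop("training pool for held-out session ", samples$session_id[i],
           " lacks a class after subject and eligibility exclusions")
    fits <- vector("list", k)
    for (j in seq_len(k)) {
      split_seed <- config$seed + (i - 1L) * k + j
      part <- .stratified_split(samples$label[pool], split_seed)
      tr <- pool[part$train]
      va <- pool[part$val]
      spec_j <- spec
      spec_j$seed <- split_seed
      fit <- fit_classifier(spec_j, vectors[tr, , drop = FALSE],
                            samples$label[tr],
                            vectors[va, , drop = FALSE], samples$label[va])
      scores[i, j] <- predict(fit, vectors[i, , drop = FALSE])
      if (keep_models) fits[[j]] <- fit
    }
    votes[i] <- sum(scores[i, ] >= 0.5)
    if (keep_models) models[[i]] <- fits
    if (verbose) message(sprintf("held out %d/%d: %d votes", i, n, votes[i]))
  }
  records <- data.frame(
    session_id = samples$session_id, subject_id = samples$subject_id,
    true_label = samples$label, votes = votes,
    age = samples$age, sex = samples$sex,
    training_eligible = samples$training_eligible,
    stringsAsFactors = FALSE)
  structure(list(records = records, scores = scores, config = config,
                 spec = spec, models = models),
            class = "vote_loocv")
}

.as_records <- function(x) {
  if (inherits(x, "vote_loocv")) x$records else as.data.frame(x)
}

#' Select the vote threshold
#'
#' Prediction at threshold `k` is dementia iff `votes >= k`, so threshold 0
#' predicts dementia for every sample. Returns the accuracy at every
#' threshold `0..n_splits` and the accuracy-maximizing threshold (smallest
#' on ties). Selecting on the pooled held-out votes mirrors the evaluated
#' procedure but is optimistic; pass a pre-registered threshold to
#' [compute_metrics()] for an unbiased operating point.
#'
#' @param x A `vote_loocv` or a data frame with `votes` and `true_label`.
#' @param n_splits Number of models voting; defaults to the config of `x`
#'   or `max(votes)`.
#' @return List with `threshold` and `table` (threshold, accuracy).
#' @export
select_vote_threshold <- function(x, n_splits = NULL) {
  records <- .as_records(x)
  if (nrow(records) == 0L) stop("no vote records")
  if (is.null(n_splits))
    n_splits <- if (inherits(x, "vote_loocv")) x$config$n_splits
                else max(records$votes)
  acc <- vapply(0:n_splits, function(th) {
    pred <- ifelse(records$votes >= th, "dementia", "non_dementia")
    mean(pred == records$true_label)
  }, numeric(1))
  list(threshold = (0:n_splits)[which.max(acc)],
       table = data.frame(threshold = 0:n_splits, accuracy = acc))
}

#' Screening metrics at a vote threshold
#'
#' Accuracy, sensitivity (dementia-class recall) and specificity
#' (non-dementia-class recall) of the thresholded vote predictions, with
#' the underlying counts. `filter` restricts to any subgroup (e.g. a sex or
#' an age band); the threshold is *not* re-selected on the subgroup.
#'
#' @param x A `vote_loocv` or a data frame with `votes` and `true_label`.
#' @param threshold Vote threshold in `0..n_splits`.
#' @param filter Optional logical vector selecting a subgroup of records.
#' @return A `metrics_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `counts` (total, correct, incorrect, per-class
#'   breakdown).
#' @export
compute_metrics <- function(x, threshold, filter = NULL) {
  records <- .as_records(x)
  if (!is.null(filter)) records <- records[which(filter), , drop = FALSE]
  if (nrow(records) == 0L) stop("no records to evaluate")
  pred <- ifelse(records$votes >= threshold, "dementia", "non_dementia")
  truth <- records$true_label
  p <- sum(truth == "dementia")
  n_neg <- sum(truth == "non_dementia")
  tp <- sum(pred == "dementia" & truth == "dementia")
  tn <- sum(pred == "non_dementia" & truth == "non_dementia")
  sens <- if (p > 0) tp / p else NA_real_
  spec <- if (n_neg > 0) tn / n_neg else NA_real_
  acc <- (tp + tn) / (p + n_neg)
  # exact identity linking the three rates; holds by construction
  if (p > 0 && n_neg > 0)
    stopifnot(abs(acc - (sens * p + spec * n_neg) / (p + n_neg)) < 1e-12)
  structure(list(
    accuracy = acc, sensitivity = sens, specificity = spec,
    threshold = threshold,
    counts = list(total = p + n_neg, correct = tp + tn,
                  incorrect = p + n_neg - tp - tn,
                  dementia = p, non_dementia = n_neg,
                  true_positive = tp, false_negative = p - tp,
                  true_negative = tn, false_positive = n_neg - tn)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("Screening metrics at vote threshold %d\n",
                     "  accuracy    %.3f  (%d/%d, %d incorrect)\n",
                     "  sensitivity %.3f  (%d/%d dementia)\n",
                     "  specificity %.3f  (%d/%d non-dementia)\n"),
              x$threshold, x$accuracy, x$counts$correct, x$counts$total,
              x$counts$incorrect, x$sensitivity, x$counts$true_positive,
              x$counts$dementia, x$specificity, x$counts$true_negative,
              x$counts$non_dementia))
  invisible(x)
}

# Mann-Whitney AUC with midrank ties; identical to the trapezoidal area
# under the tie-grouped ROC curve, and 0.5 for constant scores.
.auc_rank <- function(scores, y01) {
  np <- sum(y01 == 1L)
  nn <- sum(y01 == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC is undefined with a single-class record set")
  r <- rank(scores)
  (sum(r[y01 == 1L]) - np * (np + 1) / 2) / (np * nn)
}

.roc_points <- function(scores, y01) {
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[y01 == 1L] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[y01 == 0L] >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Per-slot ROC curves and averaged AUC
#'
#' Each of the `n_splits` model slots contributes one ROC curve: slot `j`'s
#' curve is built over all held-out sessions using their `j`-th model score.
#' AUC is the trapezoidal area (midrank ties; constant scores give 0.5);
#' the headline figure is the mean of the per-slot AUCs.
#'
#' @param x A `vote_loocv` (or a list with `$scores` and `$records`).
#' @return List with `auc_mean`, `aucs` (per slot) and `roc` (list of
#'   per-slot `fpr`/`tpr` data frames).
#' @export
compute_auc <- function(x) {
  scores <- x$scores
  y01 <- as.integer(.as_records(x)$true_label == "dementia")
  aucs <- apply(scores, 2, .auc_rank, y01 = y01)
  list(auc_mean = mean(aucs), aucs = aucs,
       roc = apply(scores, 2, .roc_points, y01 = y01, simplify = FALSE))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Pearson chi-square with continuity correction, each cell contributing
#' `max(|O - E| - 0.5, 0)^2 / E`; the p-value comes from the chi-square
#' distribution with one degree of freedom. Used to compare subgroup
#' prediction accuracies (correct/incorrect by subgroup).
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return A `chi_square_result`: `statistic`, `p_value`, `table`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins of the 2x2 table must be positive")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum(pmax(abs(table - expected) - 0.5, 0)^2 / expected)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 table = table),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Yates chi-square: X2 = %.3f, p = %.3f\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Prediction accuracy as a function of document length
#'
#' Re-scores every held-out session on prefixes of its transcript in steps
#' of `step` letters: each prefix is re-embedded and scored with the same
#' ten models that scored the session's full document, then thresholded.
#' Sessions shorter than the prefix length use their full text, so the
#' curve equals the full-length accuracy once the length grid passes the
#' longest document.
#'
#' @param fit A `vote_loocv` run with `keep_models = TRUE`.
#' @param labeled The same labeled cohort the fit was run on (non-excluded
#'   rows aligned with the fit's records).
#' @param embedder The `doc_embedder` that produced the fit's vectors.
#' @param threshold Vote threshold; defaults to the selected one.
#' @param step Letter grid step (default 100).
#' @param tokenizer Tokenizer used for the transcripts.
#' @return A `length_curve` data frame with `length` and `accuracy`.
#' @export
letter_length_curve <- function(fit, labeled, embedder, threshold = NULL,
                                step = 100L, tokenizer = default_tokenizer) {
  if (step < 1) stop("step must be a positive number of letters")
  if (is.null(fit$models))
    stop("letter_length_curve needs a fit run with keep_models = TRUE")
  if (is.null(threshold)) threshold <- select_vote_threshold(fit)$threshold
  samples <- as.data.frame(labeled)
  if (!is.null(samples$excluded)) samples <- samples[!samples$excluded, ]
  stopifnot(nrow(samples) == nrow(fit$records),
            all(samples$session_id == fit$records$session_id))
  max_len <- max(samples$letter_count)
  grid <- seq(step, ceiling(max_len / step) * step, by = step)
  acc <- vapply(grid, function(L) {
    correct <- vapply(seq_len(nrow(samples)), function(i) {
      txt <- if (samples$letter_count[i] > L)
        truncate_to_letters(samples$text[i], L) else samples$text[i]
      vec <- predict(embedder, tokenize(txt, tokenizer))
      sc <- vapply(fit$models[[i]], function(m) predict(m, vec), numeric(1))
      pred <- if (sum(sc >= 0.5) >= threshold) "dementia" else "non_dementia"
      pred == samples$label[i]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  structure(data.frame(length = grid, accuracy = acc),
            class = c("length_curve", "data.frame"))
}

#' @export
plot.length_curve <- function(x, ...) {
  graphics::plot(x$length, x$accuracy, type = "b", pch = 16,
                 xlab = "Document length (letters)",
                 ylab = "Prediction accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
print.vote_loocv <- function(x, ...) {
  cat(sprintf(paste0("Subject-aware LOOCV ensemble (%s, %d models per",
                     " held-out session)\n  %d sessions evaluated\n"),
              x$spec$kind, x$config$n_splits, nrow(x$records)))
  sel <- select_vote_threshold(x)
  cat(sprintf("  selected vote threshold: %d (accuracy %.3f)\n",
              sel$threshold,
              sel$table$accuracy[sel$table$threshold == sel$threshold]))
  invisible(x)
}

#' Summarize a leave-one-out ensemble run
#'
#' @param object A `vote_loocv`.
#' @param threshold Vote threshold; defaults to the pre-registered one in
#'   the config, else the accuracy-maximizing selection.
#' @param ... Unused.
#' @return A `summary.vote_loocv`: metrics at the threshold, the threshold
#'   sweep, averaged AUC, and subgroup metrics with Yates chi-square
#'   comparisons (training-criteria subset vs all; sex; age 75 cut).
#' @export
summary.vote_loocv <- function(object, threshold = NULL, ...) {
  sel <- select_vote_threshold(object)
  if (is.null(threshold))
    threshold <- if (!is.null(object$config$vote_threshold))
      object$config$vote_threshold else sel$threshold
  rec <- object$records
  metrics <- compute_metrics(object, threshold)
  subgroup <- function(f) if (any(f)) compute_metrics(object, threshold, f)
                          else NULL
  groups <- list(
    criteria_subset = subgroup(rec$training_eligible),
    male = subgroup(!is.na(rec$sex) & rec$sex == "male"),
    female = subgroup(!is.na(rec$sex) & rec$sex == "female"),
    age_lt_75 = subgroup(!is.na(rec$age) & rec$age < 75),
    age_ge_75 = subgroup(!is.na(rec$age) & rec$age >= 75))
  pair_chi <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NULL)
    tab <- rbind(c(a$counts$correct, a$counts$incorrect),
                 c(b$counts$correct, b$counts$incorrect))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    chi_square_2x2(tab)
  }
  chis <- list(
    # overlapping comparison: the criteria subset is also counted in "all"
    all_vs_criteria = pair_chi(metrics, groups$criteria_subset),
    sex = pair_chi(groups$male, groups$female),
    age = pair_chi(groups$age_lt_75, groups$age_ge_75))
  structure(list(threshold = threshold, selected = sel, metrics = metrics,
                 auc = compute_auc(object), subgroups = groups,
                 chi_square = chis),
            class = "summary.vote_loocv")
}

#' @export
print.summary.vote_loocv <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("  mean AUC over %d model slots: %.3f\n",
              length(x$auc$aucs), x$auc$auc_mean))
  for (nm in names(x$chi_square)) {
    cs <- x$chi_square[[nm]]
    if (!is.null(cs))
      cat(sprintf("  %s: X2 = %.3f, p = %.3f\n", nm, cs$statistic,
                  cs$p_value))
  }
  invisible(x)
}

#' @export
plot.vote_loocv <- function(x, ...) {
  auc <- compute_auc(x)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Per-slot ROC curves (mean AUC %.3f)",
                                auc$auc_mean), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  for (curve in auc$roc)
    graphics::lines(curve$fpr, curve$tpr, col = "#00000055")
  invisible(x)
}
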