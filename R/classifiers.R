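# Uniform train/predict contract over the five compared model families:
# the small fully-connected network (dnn), Gaussian naive Bayes (gnb),
# L2-regularised logistic regression (lr), a support-vector classifier
# (svc) and gradient-boosted trees (xgb). Every fitted model scores a
# feature vector with the probability of dementia in [0, 1]; the binary
# prediction is score >= 0.5.

.classifier_kinds <- c("dnn", "gnb", "lr", "svc", "xgb")

#' Classifier specification
#'
#' @param kind One of `"dnn"`, `"gnb"`, `"lr"`, `"svc"`, `"xgb"`.
#' @param hyperparameters Named list overriding the documented defaults:
#'   dnn — `hidden` (three widths, default 128/64/32), `dropout` (0.2),
#'   `learning_rate` (1e-3), `batch_size` (16), `max_epochs` (200),
#'   `patience` (10); lr — `lambda` (ridge penalty, 0.01); svc — `cost` (1),
#'   `gamma` (1/ncol); xgb — `nrounds` (100), `max_depth` (3), `eta` (0.1).
#' @param seed Integer seed; fits are deterministic at fixed seed.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = .classifier_kinds, hyperparameters = list(),
                            seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "dnn" && !is.null(hyperparameters$hidden) &&
      length(hyperparameters$hidden) != 3L)
    stop("the dnn architecture fixes exactly three hidden layers")
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.check_xy <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  present <- unique(y)
  for (cls in c("dementia", "non_dementia"))
    if (!cls %in% present)
      stop("training set lacks the ", cls, " class")
}

.hyp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (rows = samples).
#' @param y Character labels, `"dementia"` / `"non_dementia"`; both classes
#'   must be present.
#' @param xval,yval Validation split, used for early stopping of the network
#'   (required nonempty).
#' @return A `fitted_classifier`; score vectors with
#'   [predict.fitted_classifier()].
#' @export
fit_classifier <- function(spec, x, y, xval, yval) {
  stopifnot(inherits(spec, "classifier_spec"))
  .check_xy(x, y)
  stopifnot(is.matrix(xval), nrow(xval) >= 1L)
  y01 <- as.integer(y == "dementia")
  yval01 <- as.integer(yval == "dementia")
  seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, globalenv()))
  set.seed(spec$seed)
  fit <- switch(
    spec$kind,
    dnn = .dnn_fit(x, y01, xval, yval01,
                   hidden = .hyp(spec, "hidden", .dnn_defaults$hidden),
                   dropout = .hyp(spec, "dropout", .dnn_defaults$dropout),
                   learning_rate = .hyp(spec, "learning_rate",
                                        .dnn_defaults$learning_rate),
                   batch_size = .hyp(spec, "batch_size",
                                     .dnn_defaults$batch_size),
                   max_epochs = .hyp(spec, "max_epochs",
                                     .dnn_defaults$max_epochs),
                   patience = .hyp(spec, "patience", .dnn_defaults$patience),
                   seed = spec$seed),
    gnb = .gnb_fit(x, y01),
    lr = .lr_fit(x, y01, lambda = .hyp(spec, "lambda", 0.01)),
    svc = .svc_fit(x, y, cost = .hyp(spec, "cost", 1),
                   gamma = .hyp(spec, "gamma", 1 / ncol(x))),
    xgb = .xgb_fit(x, y01, nrounds = .hyp(spec, "nrounds", 100L),
                   max_depth = .hyp(spec, "max_depth", 3L),
                   eta = .hyp(spec, "eta", 0.1), seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit, width = ncol(x)),
            class = "fitted_classifier")
}

#' Score feature vectors with a fitted classifier
#'
#' @param object A `fitted_classifier`.
#' @param newdata Numeric matrix with the training feature width.
#' @param ... Unused.
#' @return Probability-of-dementia scores in `[0, 1]`, one per row, order
#'   preserved; empty input gives an empty vector.
#' @export
predict.fitted_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != object$width)
    stop("feature width ", ncol(newdata), " does not match training width ",
         object$width)
  scores <- switch(object$spec$kind,
                   dnn = .dnn_predict(object$fit, newdata),
                   gnb = .gnb_predict(object$fit, newdata),
                   lr = .lr_predict(object$fit, newdata),
                   svc = .svc_predict(object$fit, newdata),
                   xgb = .xgb_predict(object$fit, newdata))
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  stopifnot(all(is.finite(scores)))
  scores
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf("Fitted %s classifier (%d features, seed %d)\n",
              x$spec$kind, x$width, x$spec$seed))
  invisible(x)
}

# --- Gaussian naive Bayes -------------------------------------------------
# Hand-rolled so that zero-variance (constant) features stay finite: each
# per-class variance is floored by 1e-9 times the largest overall variance.

.gnb_fit <- function(x, y01) {
  stats_for <- function(rows) {
    mu <- colMeans(x[rows, , drop = FALSE])
    va <- apply(x[rows, , drop = FALSE], 2, stats::var)
    va[is.na(va)] <- 0
    list(mu = mu, va = va)
  }
  s0 <- stats_for(y01 == 0L)
  s1 <- stats_for(y01 == 1L)
  floor_v <- 1e-9 * max(c(s0$va, s1$va, 1e-9))
  s0$va <- s0$va + floor_v
  s1$va <- s1$va + floor_v
  list(s0 = s0, s1 = s1, prior1 = mean(y01))
}

.gnb_predict <- function(fit, x) {
  loglik <- function(s) {
    rowSums(sweep(sweep(x, 2, s$mu)^2, 2, -2 * s$va, "/") -
              matrix(0.5 * log(2 * pi * s$va), nrow(x), ncol(x), byrow = TRUE))
  }
  l1 <- loglik(fit$s1) + log(fit$prior1 + 1e-12)
  l0 <- loglik(fit$s0) + log(1 - fit$prior1 + 1e-12)
  1 / (1 + exp(pmin(pmax(l0 - l1, -700), 700)))
}

# --- L2-regularised logistic regression ----------------------------------

.lr_fit <- function(x, y01, lambda) {
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = 0,
                        standardize = TRUE)
  list(glmnet = fit, lambda = lambda)
}

.lr_predict <- function(fit, x) {
  as.numeric(stats::predict(fit$glmnet, newx = x, s = fit$lambda,
                            type = "response"))
}

# --- Support-vector classifier -------------------------------------------
# Scores come from a logistic link on the decision margin (sign-aligned so
# positive margins mean dementia), keeping the ROC well-defined without the
# randomized probability calibration.

.svc_fit <- function(x, y, cost, gamma) {
  yf <- factor(y, levels = c("dementia", "non_dementia"))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- if (mean(dv[y == "dementia"]) >= mean(dv[y != "dementia"])) 1 else -1
  list(svm = fit, flip = flip)
}

.svc_predict <- function(fit, x) {
  dv <- attr(stats::predict(fit$svm, x, decision.values = TRUE),
             "decision.values")[, 1]
  stats::plogis(fit$flip * dv)
}

# --- Gradient-boosted trees ----------------------------------------------

.xgb_fit <- function(x, y01, nrounds, max_depth, eta, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

.xgb_predict <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
}
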