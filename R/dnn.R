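# A small fully-connected network for binary classification: input layer,
# three hidden ReLU layers with inverted dropout, sigmoid output. Trained
# with Adam on binary cross-entropy, early-stopped on validation loss.

.dnn_defaults <- list(hidden = c(128L, 64L, 32L), dropout = 0.2,
                      learning_rate = 1e-3, batch_size = 16L,
                      max_epochs = 200L, patience = 10L)

.dnn_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                 sd = sqrt(2 / dims[l])),
                    dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

.dnn_forward <- function(params, x, dropout = 0, training = FALSE) {
  nl <- length(params)
  acts <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  acts[[1]] <- x
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * m / (1 - dropout)  # inverted dropout
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
    }
  }
  list(acts = acts, masks = masks)
}

.dnn_bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

.dnn_fit <- function(x, y, xval, yval, hidden = .dnn_defaults$hidden,
                     dropout = .dnn_defaults$dropout,
                     learning_rate = .dnn_defaults$learning_rate,
                     batch_size = .dnn_defaults$batch_size,
                     max_epochs = .dnn_defaults$max_epochs,
                     patience = .dnn_defaults$patience, seed = 1L) {
  stopifnot(length(hidden) == 3L)  # three hidden layers by architecture
  set.seed(seed)
  params <- .dnn_init(ncol(x), hidden)
  m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  n <- nrow(x)
  best <- list(loss = Inf, params = params)
  stale <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- .dnn_forward(params, xb, dropout, training = TRUE)
      nl <- length(params)
      grads <- vector("list", nl)
      delta <- (fw$acts[[nl + 1L]] - yb) / length(idx)  # dL/dz at sigmoid
      for (l in rev(seq_len(nl))) {
        grads[[l]] <- list(W = crossprod(fw$acts[[l]], delta),
                           b = colSums(delta))
        if (l > 1L) {
          delta <- delta %*% t(params[[l]]$W)
          delta <- delta * (fw$acts[[l]] > 0)
          if (dropout > 0 && !is.null(fw$masks[[l - 1L]]))
            delta <- delta * fw$masks[[l - 1L]] / (1 - dropout)
        }
      }
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (l in seq_len(nl)) {
        for (slot in c("W", "b")) {
          g <- grads[[l]][[slot]]
          m[[l]][[slot]] <- b1 * m[[l]][[slot]] + (1 - b1) * g
          v[[l]][[slot]] <- b2 * v[[l]][[slot]] + (1 - b2) * g^2
          params[[l]][[slot]] <- params[[l]][[slot]] -
            learning_rate * corr * m[[l]][[slot]] /
            (sqrt(v[[l]][[slot]]) + eps)
        }
      }
    }
    pv <- .dnn_forward(params, xval)$acts[[length(params) + 1L]]
    loss <- .dnn_bce(as.numeric(pv), yval)
    if (loss < best$loss - 1e-9) {
      best <- list(loss = loss, params = params)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(params = best$params, val_loss = best$loss, epochs_run = epoch)
}

.dnn_predict <- function(fit, x) {
  as.numeric(.dnn_forward(fit$params, x)$acts[[length(fit$params) + 1L]])
}

#' Seeded randomized search over network hyperparameters
#'
#' Draws up to `n_trials` configurations (hidden widths, dropout, learning
#' rate), trains each on the training set and keeps the one with the lowest
#' validation loss. A lightweight stand-in for a full hyperparameter tuner;
#' the fixed defaults are used when tuning is skipped.
#'
#' @param x,y Training matrix and 0/1 labels.
#' @param xval,yval Validation matrix and 0/1 labels.
#' @param n_trials Number of sampled configurations (default 10, max 25).
#' @param seed Integer seed.
#' @return The best hyperparameter list (fields `hidden`, `dropout`,
#'   `learning_rate`) and its validation loss.
#' @export
tune_dnn <- function(x, y, xval, yval, n_trials = 10L, seed = 1L) {
  n_trials <- min(as.integer(n_trials), 25L)
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    list(hidden = c(sample(c(64L, 128L, 256L), 1),
                    sample(c(32L, 64L, 128L), 1),
                    sample(c(16L, 32L, 64L), 1)),
         dropout = sample(c(0.1, 0.2, 0.3), 1),
         learning_rate = 10^stats::runif(1, -3.5, -2.5))
  })
  best <- NULL
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fit <- .dnn_fit(x, y, xval, yval, hidden = tr$hidden,
                    dropout = tr$dropout, learning_rate = tr$learning_rate,
                    max_epochs = 60L, seed = seed + i)
    if (is.null(best) || fit$val_loss < best$val_loss) {
      best <- tr
      best$val_loss <- fit$val_loss
    }
  }
  best
}
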