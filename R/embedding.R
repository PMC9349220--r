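# Document embedding: a transcript becomes a 200-dimensional feature vector,
# 150 dimensions from the morpheme stream and 50 from the stream of
# part-of-speech bigrams, both trained with a negative-sampling objective.

#' Tokenize a transcript
#'
#' The default tokenizer splits on whitespace and reads an optional
#' `token/POS` suffix; tokens without a suffix get the single `UNK` tag. Any
#' callable mapping text to an aligned list `(morphemes, pos_tags)` — for
#' example an adapter around a Japanese morphological analyzer — satisfies
#' the same contract and can be passed wherever a tokenizer is accepted.
#'
#' @param text A nonempty transcript string.
#' @param tokenizer A function `text -> list(morphemes=, pos_tags=)`;
#'   defaults to the whitespace/`token/POS` tokenizer.
#' @return List with equal-length character vectors `morphemes`, `pos_tags`.
#' @export
tokenize <- function(text, tokenizer = default_tokenizer) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("text must be a single nonempty string")
  doc <- tokenizer(text)
  stopifnot(length(doc$morphemes) == length(doc$pos_tags))
  doc
}

#' @rdname tokenize
#' @export
default_tokenizer <- function(text) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  has_pos <- grepl("/", toks, fixed = TRUE)
  morph <- ifelse(has_pos, sub("/[^/]*$", "", toks), toks)
  pos <- ifelse(has_pos, sub("^.*/", "", toks), "UNK")
  list(morphemes = morph, pos_tags = pos)
}

#' Part-of-speech bigrams of a tokenized document
#'
#' @param doc A tokenized document (see [tokenize()]).
#' @return Character vector of `tag1_tag2` symbols; empty for documents with
#'   fewer than two tokens.
#' @export
pos_bigrams <- function(doc) {
  tags <- doc$pos_tags
  n <- length(tags)
  if (n < 2L) return(character(0))
  paste(tags[-n], tags[-1], sep = "_")
}

#' Embedding configuration
#'
#' @param morpheme_dim Width of the morpheme document vector (default 150).
#' @param pos_bigram_dim Width of the POS-bigram vector (default 50).
#' @param negative_sampling Noise words per positive pair (default 5).
#' @param seed Integer seed; training is bitwise reproducible at fixed seed.
#' @param epochs Training passes over the corpus (default 40; small corpora).
#' @param window Skip-gram context window for the averaging mode (default 5).
#' @param min_count Minimum token count to enter the vocabulary (default 1).
#' @param learning_rate Initial learning rate, linearly decayed (default 0.025).
#' @param mode `"dbow"` trains one vector per document jointly with the
#'   negative-sampling objective (default); `"average"` trains skip-gram
#'   word vectors and averages them per document.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(morpheme_dim = 150L, pos_bigram_dim = 50L,
                             negative_sampling = 5L, seed = 1L,
                             epochs = 40L, window = 5L, min_count = 1L,
                             learning_rate = 0.025,
                             mode = c("dbow", "average")) {
  mode <- match.arg(mode)
  stopifnot(morpheme_dim >= 1, pos_bigram_dim >= 1, negative_sampling >= 1,
            epochs >= 1, window >= 1, min_count >= 1, learning_rate > 0)
  structure(list(morpheme_dim = as.integer(morpheme_dim),
                 pos_bigram_dim = as.integer(pos_bigram_dim),
                 negative_sampling = as.integer(negative_sampling),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 window = as.integer(window), min_count = as.integer(min_count),
                 learning_rate = learning_rate, mode = mode),
            class = "embedding_config")
}

# FNV-1a hash of a string folded to a positive double < 2^31; used to derive
# content-based inference seeds so re-embedding a document is reproducible
# regardless of its position in a batch.
.string_seed <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  h + 1
}

.doc_key <- function(tokens) paste(tokens, collapse = "\x1f")

# one embedding channel: vocabulary + trained matrices
.fit_channel <- function(token_docs, dim, config, seed) {
  counts <- table(unlist(token_docs))
  vocab <- names(counts)[counts >= config$min_count]
  if (length(vocab) == 0L)
    stop("no token reaches min_count; cannot train embedding channel")
  counts <- as.numeric(counts[vocab])
  ids <- lapply(token_docs, function(tk) {
    m <- match(tk, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  chan <- list(vocab = vocab, counts = counts, dim = dim)
  if (config$mode == "dbow") {
    fit <- .cpp_dbow_train(ids, counts, dim, config$negative_sampling,
                           config$epochs, config$learning_rate, seed)
    vecs <- fit$doc_vectors
    empty <- vapply(ids, length, integer(1)) == 0L
    vecs[empty, ] <- 0  # nothing to train on: degenerate docs embed to zero
    chan$w_out <- fit$w_out
    chan$doc_vectors <- vecs
    chan$keys <- vapply(token_docs, .doc_key, character(1))
  } else {
    chan$w_in <- .cpp_skipgram_train(ids, counts, dim,
                                     config$negative_sampling, config$epochs,
                                     config$window, config$learning_rate, seed)
    chan$doc_vectors <- t(vapply(ids, function(id) .channel_average(chan, id),
                                 numeric(dim)))
  }
  chan
}

.channel_average <- function(chan, ids0) {
  if (length(ids0) == 0L) return(numeric(chan$dim))
  colMeans(chan$w_in[ids0 + 1L, , drop = FALSE])
}

.channel_embed <- function(chan, tokens, config, reuse = TRUE) {
  m <- match(tokens, chan$vocab)
  ids0 <- as.integer(m[!is.na(m)] - 1L)
  if (config$mode == "average") return(.channel_average(chan, ids0))
  if (length(ids0) == 0L) return(numeric(chan$dim))
  if (reuse) {
    hit <- match(.doc_key(tokens), chan$keys)
    if (!is.na(hit)) return(chan$doc_vectors[hit, ])
  }
  .cpp_dbow_infer(ids0, chan$w_out, chan$counts, config$negative_sampling,
                  config$epochs, config$learning_rate,
                  .string_seed(.doc_key(tokens)))
}

#' Train the two-channel document embedder
#'
#' Trains (a) a morpheme-level document embedding and (b) an embedding of
#' the same form over each document's POS-bigram stream, both with the
#' configured negative-sampling objective, and concatenates them into one
#' feature vector per document (default 150 + 50 = 200 dimensions).
#' Documents with fewer than two tokens contribute no POS bigrams and embed
#' to the zero vector on that channel.
#'
#' @param corpus List of tokenized documents (see [tokenize()]).
#' @param config An [embedding_config()].
#' @return A `doc_embedder` object; `$document_vectors` holds the trained
#'   corpus matrix (one row per document), and [predict.doc_embedder()] maps
#'   any tokenized document to a vector. In `"dbow"` mode a document whose
#'   token sequence matches a training document reuses its trained vector;
#'   unseen documents are inferred against the frozen output weights with a
#'   content-derived seed.
#' @export
train_document_embedder <- function(corpus, config = embedding_config()) {
  if (!length(corpus)) stop("corpus must be nonempty")
  stopifnot(inherits(config, "embedding_config"))
  morph_docs <- lapply(corpus, `[[`, "morphemes")
  bigram_docs <- lapply(corpus, pos_bigrams)
  morph <- .fit_channel(morph_docs, config$morpheme_dim, config,
                        seed = config$seed)
  pos <- .fit_channel(bigram_docs, config$pos_bigram_dim, config,
                      seed = config$seed + 101L)
  vectors <- cbind(morph$doc_vectors, pos$doc_vectors)
  obj <- structure(list(config = config, morph = morph, pos = pos,
                        document_vectors = vectors),
                   class = "doc_embedder")
  obj
}

#' Embed tokenized documents with a trained embedder
#'
#' @param object A `doc_embedder`.
#' @param newdata One tokenized document or a list of them.
#' @param ... Unused.
#' @return Numeric matrix, one row per document, width
#'   `morpheme_dim + pos_bigram_dim`.
#' @export
predict.doc_embedder <- function(object, newdata, ...) {
  if (!is.null(newdata$morphemes)) newdata <- list(newdata)
  rows <- lapply(newdata, function(doc) {
    c(.channel_embed(object$morph, doc$morphemes, object$config),
      .channel_embed(object$pos, pos_bigrams(doc), object$config))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(is.finite(out)))
  out
}

#' @export
print.doc_embedder <- function(x, ...) {
  cat(sprintf(paste0("Two-channel document embedder (%s mode)\n",
                     "  morphemes: %d-dim, vocab %d\n",
                     "  POS bigrams: %d-dim, vocab %d\n",
                     "  %d training documents embedded\n"),
              x$config$mode, x$config$morpheme_dim, length(x$morph$vocab),
              x$config$pos_bigram_dim, length(x$pos$vocab),
              nrow(x$document_vectors)))
  invisible(x)
}

#' TF-IDF baseline vectorizer
#'
#' Standard term-frequency x inverse-document-frequency weighting over
#' morphemes: raw-count tf, `idf = ln((1 + N) / (1 + df)) + 1`, rows
#' L2-normalized. The vocabulary and document frequencies are fitted on the
#' training corpus only and then applied to held-out documents.
#'
#' @param corpus List of tokenized documents to fit on.
#' @return A `tfidf_vectorizer`; use [predict.tfidf_vectorizer()] to
#'   transform documents, or read `$document_vectors` for the fitted corpus.
#' @export
tfidf_vectorize <- function(corpus) {
  if (!length(corpus)) stop("corpus must be nonempty")
  morph_docs <- lapply(corpus, `[[`, "morphemes")
  vocab <- sort(unique(unlist(morph_docs)))
  df <- rowSums(matrix(vapply(morph_docs, function(tk) vocab %in% tk,
                              logical(length(vocab))),
                       nrow = length(vocab)))
  idf <- log((1 + length(morph_docs)) / (1 + df)) + 1
  obj <- structure(list(vocab = vocab, idf = idf), class = "tfidf_vectorizer")
  obj$document_vectors <- predict(obj, corpus)
  obj
}

#' @rdname tfidf_vectorize
#' @param object A fitted `tfidf_vectorizer`.
#' @param newdata One tokenized document or a list of them.
#' @param ... Unused.
#' @export
predict.tfidf_vectorizer <- function(object, newdata, ...) {
  if (!is.null(newdata$morphemes)) newdata <- list(newdata)
  rows <- t(matrix(vapply(newdata, function(doc) {
    tf <- tabulate(match(doc$morphemes, object$vocab),
                   nbins = length(object$vocab))
    v <- tf * object$idf
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }, numeric(length(object$vocab))), nrow = length(object$vocab)))
  colnames(rows) <- object$vocab
  rows
}
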