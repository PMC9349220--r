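# Shared fixtures, built in code.

# minimal well-formed cohort rows for I/O tests
toy_cohort_df <- function() {
  data.frame(
    subject_id = c("A", "A", "B"),
    session_id = c("A-1", "A-2", "B-1"),
    age = c(70, 71, 80),
    sex = c("female", "female", "male"),
    education_years = c(12, 12, 9),
    cdr = c(0, 0.5, 1),
    mmse = c(29, 26, 18),
    lm2 = c(10, 3, 0),
    gds = c(2, 3, 4),
    dialect_flag = FALSE,
    clinical_diagnosis = NA,
    text = c("ha/N ma/V to/E", "mo ri", "ka/F so/N, ne/E"),
    stringsAsFactors = FALSE
  )
}

# two linearly separable Gaussian clusters for classifier tests
separable_xy <- function(n = 40, d = 4, gap = 4, seed = 99) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(matrix(stats::rnorm(half * d, -gap / 2, 0.5), half, d),
             matrix(stats::rnorm((n - half) * d, gap / 2, 0.5), n - half, d))
  y <- c(rep("non_dementia", half), rep("dementia", n - half))
  list(x = x, y = y)
}

# tokenized corpus with class-disjoint vocabularies
disjoint_corpus <- function(n_per_class = 10, len = 60, seed = 5) {
  set.seed(seed)
  gen <- function(words, tags) {
    w <- sample(words, len, replace = TRUE)
    list(morphemes = w, pos_tags = sample(tags, len, replace = TRUE))
  }
  a <- replicate(n_per_class,
                 gen(paste0("aka", 1:12), c("N", "V")), simplify = FALSE)
  b <- replicate(n_per_class,
                 gen(paste0("umi", 1:12), c("ADJ", "P")), simplify = FALSE)
  list(docs = c(a, b),
       labels = rep(c("dementia", "non_dementia"), each = n_per_class))
}

# brute-force re-statement of the labeling rules, straight from their
# clinical definition, for grid comparison against the engine
oracle_label <- function(cdr, mmse, lm2_below_cutoff) {
  dementia_patterns <- (cdr >= 1 && mmse <= 23) ||
    (cdr >= 1 && mmse >= 24 && lm2_below_cutoff) ||
    (cdr == 0.5 && mmse <= 23 && lm2_below_cutoff)
  if (dementia_patterns) return("dementia")
  if (cdr <= 0.5 && mmse >= 24) return("non_dementia")
  "fallback"
}

oracle_training_eligible <- function(cdr, mmse, lm2_below_cutoff, label) {
  if (label == "dementia")
    return(cdr >= 1 && mmse <= 23 && lm2_below_cutoff)
  if (label == "non_dementia")
    return((cdr == 0.5 && mmse >= 24 && lm2_below_cutoff) ||
             (cdr == 0 && mmse >= 24 && !lm2_below_cutoff))
  FALSE
}

# a small fully labeled synthetic cohort + embedding, cached per session
small_eval_setup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- cohort_spec(n_subjects = 18, sessions_prob = c(0.4, 0.4, 0.2),
                        excluded_fraction = 0, atypical_fraction = 0.1,
                        seed = 21)
    lab <- label_cohort(generate_cohort(spec))
    docs <- lapply(lab$text, tokenize)
    emb <- train_document_embedder(
      docs, embedding_config(seed = 8, epochs = 20))
    cache <<- list(lab = lab, emb = emb)
    cache
  }
})
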