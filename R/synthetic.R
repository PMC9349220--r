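# Synthetic free-conversation cohorts. Clinical scores are drawn from
# truncated normals whose post-truncation mean and SD are fitted to the
# class profiles; transcripts come from a class-conditional token model
# (Markov chain over a small POS grammar, Zipf-weighted vocabularies with
# class-specific subvocabularies and fillers) in which a separation
# parameter delta scales every class difference. delta = 0 makes the
# classes linguistically identical.

# ---- clinical score profiles (per-class mean, SD) ------------------------

.default_profiles <- list(
  dementia = list(
    age = c(79.0, 8.9), mmse = c(16.4, 4.8), lm2 = c(0.5, 1.2),
    letters = c(1755.7, 876.0), cdr_probs = c("1" = 0.8, "2" = 0.1, "3" = 0.1),
    female = 0.767),
  non_dementia = list(
    age = c(71.1, 11.1), mmse = c(28.6, 1.8), lm2 = c(11.8, 5.8),
    letters = c(2489.3, 737.8), cdr_probs = c("0" = 0.8, "0.5" = 0.2),
    female = 0.510)
)

# moments of a normal truncated to [lo, hi]
.tn_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(c(NA, NA))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(m, sqrt(max(v, 0)))
}

# pre-truncation (mu, sd) whose truncated moments best match the target;
# hard ranges can make the target SD unattainable, in which case the
# closest member of the family is used (mean error weighted highest)
.fit_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mm <- .tn_moments(p[1], exp(p[2]), lo, hi)
    if (anyNA(mm)) return(1e6)
    4 * (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(mu = fit$par[1], sd = exp(fit$par[2]), lo = lo, hi = hi)
}

.rtruncnorm <- function(n, f) {
  u <- stats::runif(n, stats::pnorm(f$lo, f$mu, f$sd),
                    stats::pnorm(f$hi, f$mu, f$sd))
  pmin(pmax(stats::qnorm(u, f$mu, f$sd), f$lo), f$hi)
}

# ---- token model ---------------------------------------------------------

.pos_tags <- c("N", "V", "ADJ", "P", "F", "E")

.syllables <- local({
  cons <- c("k", "s", "t", "n", "h", "m", "y", "r", "w", "g", "z", "d")
  as.vector(outer(cons, c("a", "i", "u", "e", "o"), paste0))
})

.make_words <- function(prefix, n) {
  vapply(seq_len(n), function(i) {
    s1 <- .syllables[(i * 7) %% length(.syllables) + 1]
    s2 <- .syllables[(i * 13 + 3) %% length(.syllables) + 1]
    paste0(prefix, s1, s2)
  }, character(1))
}

.vocab <- list(
  shared = list(N = .make_words("no", 30), V = .make_words("vu", 20),
                ADJ = .make_words("aj", 15), P = .make_words("pe", 8),
                F = .make_words("fi", 6), E = .make_words("en", 6)),
  dementia = list(N = .make_words("dn", 10), V = .make_words("dv", 6),
                  ADJ = .make_words("da", 5)),
  non_dementia = list(N = .make_words("hn", 10), V = .make_words("hv", 6),
                      ADJ = .make_words("ha", 5))
)

.tmat <- function(rows) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(.pos_tags[-6], .pos_tags)
  m / rowSums(m)
}

.trans_base <- .tmat(list(
  c(0.12, 0.30, 0.08, 0.30, 0.10, 0.10),   # from N
  c(0.25, 0.08, 0.10, 0.15, 0.12, 0.30),   # from V
  c(0.45, 0.10, 0.05, 0.20, 0.10, 0.10),   # from ADJ
  c(0.35, 0.30, 0.15, 0.02, 0.08, 0.10),   # from P
  c(0.30, 0.20, 0.10, 0.10, 0.15, 0.15)))  # from F

# dementia speech: more fillers, earlier sentence endings
.trans_dementia <- .tmat(lapply(seq_len(5), function(i)
  .trans_base[i, ] + c(0, 0, 0, 0, 0.30, 0.22)))
# non-dementia speech: longer noun/adjective chains
.trans_non_dementia <- .tmat(lapply(seq_len(5), function(i)
  .trans_base[i, ] + c(0.20, 0.05, 0.12, 0.05, 0, 0)))

.start_probs <- c(N = 0.45, V = 0.10, ADJ = 0.10, P = 0.05, F = 0.25,
                  E = 0.05)

# one transcript: "word/TAG" tokens, whitespace-separated, generated until
# the letter budget is reached. lambda = delta / (1 + delta) interpolates
# the class-specific transition matrix, Zipf exponent and subvocabulary.
.gen_text <- function(class, letters_target, lambda) {
  tmat <- (1 - lambda) * .trans_base +
    lambda * (if (class == "dementia") .trans_dementia else .trans_non_dementia)
  zipf_s <- 1.0 + lambda * (if (class == "dementia") 0.5 else -0.3)
  p_class_word <- 0.45 * lambda
  pick_word <- function(tag) {
    class_pool <- .vocab[[class]][[tag]]
    if (!is.null(class_pool) && stats::runif(1) < p_class_word) {
      pool <- class_pool
    } else {
      pool <- .vocab$shared[[tag]]
    }
    w <- (1 / seq_along(pool)^zipf_s)
    pool[sample.int(length(pool), 1L, prob = w)]
  }
  out <- character(0)
  letters <- 0L
  while (letters < letters_target) {
    tag <- sample(.pos_tags, 1L, prob = .start_probs)
    steps <- 0L
    while (tag != "E" && steps < 14L) {
      tok <- paste0(pick_word(tag), "/", tag)
      out <- c(out, tok)
      letters <- letters + nchar(tok)
      tag <- sample(.pos_tags, 1L, prob = tmat[tag, ])
      steps <- steps + 1L
    }
    tok <- paste0(pick_word("E"), "/E")
    out <- c(out, tok)
    letters <- letters + nchar(tok)
  }
  paste(out, collapse = " ")
}

# ---- cohort specification ------------------------------------------------

#' Synthetic cohort specification
#'
#' @param n_subjects Number of subjects (default 60, giving roughly 90
#'   sessions with the default repeat-visit distribution).
#' @param sessions_prob Probabilities of 1, 2 or 3 sessions per subject.
#' @param dementia_fraction Proportion of subjects in the dementia class
#'   (default 0.447, the analyzed prevalence of 193/432 sessions).
#' @param separation delta >= 0 scaling every class difference in the
#'   language model; 0 makes class token distributions identical.
#' @param score_profiles Per-class means/SDs for age, MMSE, LM II, letters,
#'   the discrete CDR distribution and the female fraction; defaults follow
#'   the clinical profile table.
#' @param atypical_fraction Proportion of sessions given score patterns
#'   that fail the training criteria (default 0.25, matching 108/432
#'   test-only sessions); these carry a clinical diagnosis.
#' @param excluded_fraction Proportion of sessions carrying an exclusion
#'   trigger (default 0.27, matching 158/590 screened-out sessions).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60L,
                        sessions_prob = c(0.55, 0.40, 0.05),
                        dementia_fraction = 0.447, separation = 4,
                        score_profiles = .default_profiles,
                        atypical_fraction = 0.25, excluded_fraction = 0.27,
                        seed = 1L) {
  stopifnot(n_subjects >= 2, length(sessions_prob) == 3L,
            dementia_fraction >= 0, dementia_fraction <= 1, separation >= 0,
            atypical_fraction >= 0, atypical_fraction <= 1,
            excluded_fraction >= 0, excluded_fraction <= 1)
  if ((dementia_fraction == 0 || dementia_fraction == 1) &&
      atypical_fraction > 0)
    stop("atypical sessions of both classes are infeasible with a ",
         "single-class cohort")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_prob = sessions_prob / sum(sessions_prob),
                 dementia_fraction = dementia_fraction,
                 separation = separation, score_profiles = score_profiles,
                 atypical_fraction = atypical_fraction,
                 excluded_fraction = excluded_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.sample_int_probs <- function(probs) sample.int(length(probs), 1L, prob = probs)

# Typical scores satisfy exactly the intended labeling rule pattern. The
# non-dementia LM II profile is a mixture of MCI sessions (forced at or
# below the education cutoff) and healthy controls (forced above), so the
# healthy-control mean is solved from the mixture identity against the
# class profile rather than drawn from it directly.
.typical_scores <- function(class, edu, fits, profile) {
  cutoff <- lm2_cutoff(edu)
  cdr <- as.numeric(names(profile$cdr_probs))[.sample_int_probs(profile$cdr_probs)]
  if (class == "dementia") {
    mmse <- round(.rtruncnorm(1, fits$mmse))
    lm2 <- min(max(round(.rtruncnorm(1, fits$lm2)), 0), cutoff)
    list(cdr = cdr, mmse = min(max(mmse, 0), 23), lm2 = lm2, diag = NA)
  } else {
    mmse <- min(max(round(.rtruncnorm(1, fits$mmse)), 24), 30)
    lm2 <- if (cdr == 0.5)
      min(max(round(.rtruncnorm(1, fits$lm2_mci)), 0), cutoff)
    else
      max(round(.rtruncnorm(1, fits$lm2_chc)), cutoff + 1)
    list(cdr = cdr, mmse = mmse, lm2 = lm2, diag = NA)
  }
}

# atypical scores fail the training criteria but remain labelable (by a
# non-typical rule pattern or the clinical-diagnosis fallback)
.atypical_scores <- function(class, edu, variant) {
  cutoff <- lm2_cutoff(edu)
  if (class == "dementia") {
    if (variant %% 2L == 0L)  # dementia rule: CDR >= 1 with preserved MMSE
      list(cdr = 1, mmse = 25, lm2 = max(cutoff - 1, 0), diag = "dementia")
    else                      # fallback region
      list(cdr = 0.5, mmse = 20, lm2 = cutoff + 2, diag = "dementia")
  } else {
    if (variant %% 2L == 0L)  # non-dementia rule, but fails CHC criteria
      list(cdr = 0, mmse = 27, lm2 = max(cutoff - 1, 0),
           diag = "non_dementia")
    else                      # fallback region
      list(cdr = 0, mmse = 22, lm2 = cutoff + 3, diag = "non_dementia")
  }
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject class, per-session clinical scores from the
#' truncated class-conditional profiles, and transcripts from the
#' class-conditional token model. Atypical sessions receive score patterns
#' failing the training criteria together with a clinical diagnosis;
#' excluded sessions carry one of the four exclusion triggers in rotation
#' (age under 45, GDS >= 10, a missing score, dialect flag).
#'
#' @param spec A [cohort_spec()].
#' @return A cohort `data.frame` (see [as_cohort()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, globalenv()))
  set.seed(spec$seed)
  lambda <- spec$separation / (1 + spec$separation)
  profs <- spec$score_profiles
  mmse_rng <- list(dementia = c(0, 23), non_dementia = c(24, 30))
  fits <- lapply(names(profs), function(cls) {
    p <- profs[[cls]]
    out <- list(age = .fit_truncnorm(p$age[1], p$age[2], 45, 100),
                mmse = .fit_truncnorm(p$mmse[1], p$mmse[2],
                                      mmse_rng[[cls]][1], mmse_rng[[cls]][2]),
                lm2 = .fit_truncnorm(p$lm2[1], p$lm2[2], 0, 30),
                letters = .fit_truncnorm(p$letters[1], p$letters[2],
                                         250, 8000))
    if (cls == "non_dementia") {
      # LM II is a mixture of MCI (at/below cutoff) and healthy controls
      # (above); the control mean and variance are solved from the mixture
      # identities against the class profile
      p_mci <- sum(p$cdr_probs[names(p$cdr_probs) == "0.5"])
      p_chc <- max(1 - p_mci, 1e-9)
      m_mci <- 1.5
      s_mci <- 1.2
      m_chc <- (p$lm2[1] - p_mci * m_mci) / p_chc
      between <- p_mci * (m_mci - p$lm2[1])^2 + p_chc * (m_chc - p$lm2[1])^2
      v_chc <- max((p$lm2[2]^2 - between - p_mci * s_mci^2) / p_chc, 1)
      out$lm2_mci <- .fit_truncnorm(m_mci, s_mci, 0, 8)
      out$lm2_chc <- .fit_truncnorm(m_chc, sqrt(v_chc), 3, 30)
    }
    out
  })
  names(fits) <- names(profs)
  rows <- list()
  excl_cycle <- 0L
  atyp_cycle <- 0L
  for (s in seq_len(spec$n_subjects)) {
    class <- if (stats::runif(1) < spec$dementia_fraction) "dementia"
             else "non_dementia"
    prof <- profs[[class]]
    fit <- fits[[class]]
    sex <- if (stats::runif(1) < prof$female) "female" else "male"
    edu <- sample(c(9L, 12L, 16L), 1L, prob = c(0.25, 0.5, 0.25))
    age <- round(.rtruncnorm(1, fit$age))
    n_sess <- sample(1:3, 1L, prob = spec$sessions_prob)
    for (k in seq_len(n_sess)) {
      u <- stats::runif(1)
      status <- if (u < spec$excluded_fraction) "excluded"
                else if (u < spec$excluded_fraction + spec$atypical_fraction)
                  "atypical" else "typical"
      gds <- sample(0:8, 1L, prob = 9:1)
      sc <- if (status == "atypical") {
        atyp_cycle <- atyp_cycle + 1L
        .atypical_scores(class, edu, atyp_cycle)
      } else .typical_scores(class, edu, fit, prof)
      row <- list(subject_id = sprintf("S%03d", s),
                  session_id = sprintf("S%03d-%d", s, k),
                  age = age, sex = sex, education_years = edu,
                  cdr = sc$cdr, mmse = sc$mmse, lm2 = sc$lm2, gds = gds,
                  dialect_flag = FALSE, clinical_diagnosis = sc$diag,
                  text = .gen_text(class, round(.rtruncnorm(1, fit$letters)),
                                   lambda))
      if (status == "excluded") {
        excl_cycle <- excl_cycle + 1L
        trigger <- c("age", "gds", "missing", "dialect")[excl_cycle %% 4L + 1L]
        if (trigger == "age") row$age <- sample(20:44, 1L)
        if (trigger == "gds") row$gds <- sample(10:15, 1L)
        if (trigger == "missing") row$mmse <- NA
        if (trigger == "dialect") row$dialect_flag <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  as_cohort(df)
}

#' Deterministic worked fixture cohort
#'
#' A hand-constructed 12-subject cohort covering every labeling branch and
#' every exclusion reason: the three dementia rule patterns, both
#' training-eligible non-dementia patterns, a rule-matching but
#' test-only pattern, both clinical-fallback branches, all four exclusion
#' triggers, and one subject with three sessions whose labels change when
#' MCI converts to dementia. Regeneration is byte-identical; the same
#' cohort ships as a text fixture.
#'
#' @return A cohort `data.frame`.
#' @export
generate_worked_fixture <- function() {
  seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(seed_state))
    assign(".Random.seed", seed_state, globalenv()))
  txt <- function(i, class, letters) {
    set.seed(9000L + i)
    .gen_text(class, letters, lambda = 0.8)
  }
  row <- function(id, sess, age, sex, edu, cdr, mmse, lm2, gds, dialect,
                  diag, text) {
    data.frame(subject_id = id, session_id = paste0(id, "-", sess),
               age = age, sex = sex, education_years = edu, cdr = cdr,
               mmse = mmse, lm2 = lm2, gds = gds, dialect_flag = dialect,
               clinical_diagnosis = diag, text = text,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    # dementia rule 1: CDR >= 1 and MMSE <= 23 (training-eligible)
    row("F01", 1, 78, "female", 12, 1, 18, 1, 3, FALSE, NA,
        txt(1, "dementia", 420)),
    # dementia rule 2: CDR >= 1, MMSE >= 24, LM II at/below cutoff
    row("F02", 1, 81, "male", 16, 1, 25, 5, 2, FALSE, NA,
        txt(2, "dementia", 380)),
    # dementia rule 3: CDR = 0.5, MMSE <= 23, LM II at/below cutoff
    row("F03", 1, 76, "female", 9, 0.5, 21, 1, 4, FALSE, NA,
        txt(3, "dementia", 400)),
    # healthy control: CDR = 0, MMSE >= 24, LM II above cutoff
    row("F04", 1, 68, "male", 12, 0, 29, 12, 1, FALSE, NA,
        txt(4, "non_dementia", 520)),
    # MCI converting to dementia across three repeat visits
    row("F05", 1, 72, "female", 12, 0.5, 27, 3, 2, FALSE, NA,
        txt(5, "non_dementia", 500)),
    row("F05", 2, 72, "female", 12, 0.5, 25, 2, 3, FALSE, NA,
        txt(6, "non_dementia", 470)),
    row("F05", 3, 73, "female", 12, 1, 20, 1, 3, FALSE, NA,
        txt(7, "dementia", 390)),
    # non-dementia by rule but failing the training criteria
    row("F06", 1, 70, "male", 12, 0, 27, 3, 2, FALSE, NA,
        txt(8, "non_dementia", 510)),
    # fallback region, clinical diagnosis dementia
    row("F07", 1, 79, "female", 12, 0, 20, 2, 4, FALSE, "dementia",
        txt(9, "dementia", 410)),
    # fallback region, clinical diagnosis non-dementia
    row("F08", 1, 66, "female", 16, 0.5, 22, 10, 2, FALSE, "non_dementia",
        txt(10, "non_dementia", 540)),
    # the four exclusion triggers
    row("F09", 1, 40, "male", 12, 0, 28, 11, 2, FALSE, NA,
        txt(11, "non_dementia", 480)),
    row("F10", 1, 74, "female", 12, 0, 27, 10, 12, FALSE, NA,
        txt(12, "non_dementia", 460)),
    row("F11", 1, 77, "male", 12, 1, NA, 1, 3, FALSE, NA,
        txt(13, "dementia", 430)),
    row("F12", 1, 69, "female", 12, 0, 28, 11, 2, TRUE, NA,
        txt(14, "non_dementia", 500))
  )
  as_cohort(df)
}
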