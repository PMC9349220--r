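test_that("cohort generation is byte-identical at a fixed seed", {
  spec <- cohort_spec(n_subjects = 10, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1)
  write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed gives a different cohort
  expect_false(identical(c1, generate_cohort(cohort_spec(n_subjects = 10,
                                                         seed = 43))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_spec(n_subjects = 4, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("class prevalence tracks the dementia fraction", {
  spec <- cohort_spec(n_subjects = 250, excluded_fraction = 0,
                      atypical_fraction = 0, seed = 14)
  lab <- label_cohort(generate_cohort(spec))
  p <- mean(lab$label == "dementia")
  # subject-level binomial tolerance (sessions cluster within subject)
  se <- sqrt(0.447 * 0.553 / 250)
  expect_lt(abs(p - 0.447), 4 * se)
})

test_that("generated score moments match the class profiles", {
  spec <- cohort_spec(n_subjects = 330, excluded_fraction = 0,
                      atypical_fraction = 0, seed = 3)
  lab <- label_cohort(generate_cohort(spec))
  profs <- list(dementia = list(mmse = c(16.4, 4.8), age = c(79.0, 8.9),
                                lm2 = c(0.5, 1.2), letters = c(1755.7, 876),
                                cdr = 1.3),
                non_dementia = list(mmse = c(28.6, 1.8), age = c(71.1, 11.1),
                                    lm2 = c(11.8, 5.8),
                                    letters = c(2489.3, 737.8), cdr = 0.1))
  for (cls in names(profs)) {
    d <- lab[lab$label == cls, ]
    n <- nrow(d)
    for (score in c("mmse", "age", "lm2", "letters")) {
      col <- if (score == "letters") d$letter_count else d[[score]]
      target <- profs[[cls]][[score]]
      expect_lt(abs(mean(col) - target[1]), 3 * target[2] / sqrt(n),
                label = paste(cls, score, "mean"))
    }
    # SDs are checked where the rule ranges leave them free; the hard score
    # ranges (MMSE bands, LM II cutoffs) compress the remaining SDs
    for (score in c("age", "letters")) {
      col <- if (score == "letters") d$letter_count else d[[score]]
      target <- profs[[cls]][[score]]
      expect_lt(abs(stats::sd(col) - target[2]),
                3 * target[2] / sqrt(2 * n),
                label = paste(cls, score, "sd"))
    }
    expect_lt(abs(mean(d$cdr) - profs[[cls]]$cdr), 0.15,
              label = paste(cls, "cdr mean"))
  }
  # headline check: dementia MMSE mean within 0.5 of the profile
  expect_lt(abs(mean(lab$mmse[lab$label == "dementia"]) - 16.4), 0.5)
})

test_that("typical scores satisfy exactly their intended rule and atypical
           sessions are labelable but test-only", {
  spec <- cohort_spec(n_subjects = 60, excluded_fraction = 0,
                      atypical_fraction = 0.3, seed = 8)
  lab <- label_cohort(generate_cohort(spec))
  expect_false(any(lab$excluded))
  atyp <- !lab$training_eligible
  expect_gt(sum(atyp), 0)
  # atypical sessions carry a clinical diagnosis and agree with it
  expect_true(all(!is.na(lab$clinical_diagnosis[atyp])))
  expect_identical(lab$label[atyp], lab$clinical_diagnosis[atyp])
  # typical sessions are labeled by rule
  expect_true(all(lab$label_source[!atyp] == "rule"))
})

test_that("exclusion triggers rotate through all four reasons", {
  spec <- cohort_spec(n_subjects = 50, excluded_fraction = 0.4,
                      atypical_fraction = 0, seed = 5)
  lab <- label_cohort(generate_cohort(spec))
  expect_setequal(unique(stats::na.omit(lab$exclusion_reason)),
                  c("age_under_45", "gds_ge_10", "missing_data", "dialect"))
})

test_that("delta = 0 collapses the class token distributions", {
  spec0 <- cohort_spec(n_subjects = 40, separation = 0,
                       excluded_fraction = 0, atypical_fraction = 0,
                       seed = 11)
  coh <- generate_cohort(spec0)
  lab <- label_cohort(coh)
  toks <- lapply(lab$text, function(t) tokenize(t)$morphemes)
  # no class-exclusive subvocabulary appears at delta 0
  all_tokens <- unlist(toks)
  expect_false(any(grepl("^(dn|dv|da|hn|hv|ha)", all_tokens)))
  # filler rates of the two classes are statistically indistinguishable
  filler_rate <- vapply(toks, function(tk) mean(grepl("^fi", tk)), numeric(1))
  p <- stats::t.test(filler_rate[lab$label == "dementia"],
                     filler_rate[lab$label == "non_dementia"])$p.value
  expect_gt(p, 0.001)
})

test_that("an infeasible specification is rejected", {
  expect_error(cohort_spec(dementia_fraction = 0, atypical_fraction = 0.1),
               "infeasible|single-class")
})

test_that("the worked fixture covers every branch and regenerates
           byte-identically", {
  fx <- generate_worked_fixture()
  expect_identical(fx, generate_worked_fixture())
  lab <- label_cohort(fx)
  # labeling branch coverage
  rules <- lab[!lab$excluded, ]
  expect_true(any(rules$cdr >= 1 & rules$mmse <= 23))              # rule 1
  expect_true(any(rules$cdr >= 1 & rules$mmse >= 24))              # rule 2
  expect_true(any(rules$cdr == 0.5 & rules$mmse <= 23 &
                    rules$label == "dementia" &
                    rules$label_source == "rule"))                 # rule 3
  expect_true(any(rules$label == "non_dementia" & rules$training_eligible))
  expect_true(any(rules$label == "non_dementia" & !rules$training_eligible))
  expect_setequal(unique(rules$label_source), c("rule", "clinical_fallback"))
  expect_setequal(unique(lab$exclusion_reason[lab$excluded]),
                  c("age_under_45", "gds_ge_10", "missing_data", "dialect"))
  # per-session labeling: the repeat-visit subject converts to dementia
  f05 <- lab[lab$subject_id == "F05", ]
  expect_identical(f05$label, c("non_dementia", "non_dementia", "dementia"))
  # regeneration matches the checked-in text fixture byte for byte
  path <- system.file("extdata", "worked_cohort_synthetic.csv",
                      package = "convoscreen")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fx, tmp)
  expect_identical(readLines(tmp), readLines(path))
})
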