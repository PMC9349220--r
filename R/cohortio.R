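#' @useDynLib convoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Column order of the cohort table dialect. `text` is last so the quoted
# free-text field never interferes with eyeballing the clinical columns.
.cohort_columns <- c(
  "subject_id", "session_id", "age", "sex", "education_years", "cdr",
  "mmse", "lm2", "gds", "dialect_flag", "clinical_diagnosis", "text"
)

.cdr_levels <- c(0, 0.5, 1, 2, 3)

#' Count letters in a transcript
#'
#' The unit of document length is the "letter": every Unicode character that
#' is not whitespace. Spaces, tabs and newlines are transcription artifacts
#' and are not counted; punctuation and long-vowel marks count as letters.
#'
#' @param text Character vector of transcript texts.
#' @return Integer vector of non-whitespace character counts.
#' @examples
#' count_letters("ab cd")  # 4
#' count_letters("")       # 0
#' @export
count_letters <- function(text) {
  stopifnot(is.character(text))
  out <- nchar(gsub("[[:space:]]", "", text), type = "chars")
  out[is.na(text)] <- 0L
  as.integer(out)
}

#' Truncate a transcript to a letter budget
#'
#' Returns the prefix of `text` containing `min(n, count_letters(text))`
#' letters. Whitespace interleaved in the prefix is carried through but not
#' counted, so tokenization of the truncated text remains valid.
#'
#' @param text A single transcript string.
#' @param n Positive letter budget.
#' @return The truncated string.
#' @export
truncate_to_letters <- function(text, n) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive integer letter budget")
  n <- as.integer(n)
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  if (length(chars) == 0L) return(text)
  is_letter <- !grepl("[[:space:]]", chars)
  cum <- cumsum(is_letter)
  if (cum[length(cum)] <= n) return(text)
  cut <- which(cum == n & is_letter)[1]
  paste(chars[seq_len(cut)], collapse = "")
}

#' Assemble a cohort table from per-session fields
#'
#' A cohort is a plain `data.frame` with one row per recorded session and the
#' columns `subject_id`, `session_id`, `age`, `sex`, `education_years`,
#' `cdr`, `mmse`, `lm2`, `gds`, `dialect_flag`, `clinical_diagnosis`,
#' `text`, plus derived `session_index` (order of repeat visits within
#' subject) and `letter_count`. Missing clinical fields are `NA`;
#' `clinical_diagnosis` is `NA`, `"dementia"` or `"non_dementia"`.
#'
#' @param df Data frame carrying the cohort columns.
#' @return A validated cohort `data.frame` of class `conv_cohort`.
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols) > 0L)
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, .cohort_columns, drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  df$session_id <- as.character(df$session_id)
  key <- paste(df$subject_id, df$session_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (subject_id, session_id) key: (",
         gsub("\r", ", ", dup, fixed = TRUE), ")")
  }
  for (col in c("age", "education_years", "cdr", "mmse", "lm2", "gds"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad_cdr <- !is.na(df$cdr) & !df$cdr %in% .cdr_levels
  if (any(bad_cdr))
    stop("cdr outside {0, 0.5, 1, 2, 3} in session ",
         df$session_id[which(bad_cdr)[1]])
  bad_mmse <- !is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30)
  if (any(bad_mmse))
    stop("mmse outside [0, 30] in session ", df$session_id[which(bad_mmse)[1]])
  df$sex <- ifelse(df$sex %in% c("male", "female"), df$sex, NA_character_)
  df$dialect_flag <- as.logical(df$dialect_flag)
  cd <- as.character(df$clinical_diagnosis)
  cd[!cd %in% c("dementia", "non_dementia")] <- NA_character_
  df$clinical_diagnosis <- cd
  df$text <- ifelse(is.na(df$text), "", as.character(df$text))
  # session_index by record order within subject (dates are not recorded)
  df$session_index <- stats::ave(seq_len(nrow(df)), df$subject_id,
                                 FUN = seq_along)
  df$letter_count <- count_letters(df$text)
  rownames(df) <- NULL
  class(df) <- c("conv_cohort", "data.frame")
  df
}

#' Read a cohort file
#'
#' Two dialects are accepted: a UTF-8 comma-separated table with a header row
#' and the quoted `text` field, or line-delimited JSON with one object per
#' session carrying the same keys. Rows with unparseable required fields are
#' returned with `NA` markers, never dropped; a duplicated
#' (`subject_id`, `session_id`) key is a validation error.
#'
#' @param path Path to a `.csv` or `.jsonl` cohort file.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @return A cohort `data.frame` (see [as_cohort()]).
#' @export
read_cohort <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8",
                          check.names = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      obj <- jsonlite::fromJSON(l)
      vals <- lapply(.cohort_columns, function(k) {
        v <- obj[[k]]
        if (is.null(v) || length(v) == 0L) NA else v
      })
      names(vals) <- .cohort_columns
      as.data.frame(vals, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  df[] <- lapply(df, function(col) {
    col[!is.na(col) & col == ""] <- NA
    col
  })
  df$text <- ifelse(is.na(df$text), "", df$text)
  as_cohort(df)
}

#' Write a cohort file
#'
#' Emits the identical dialect that [read_cohort()] accepts, so a
#' read-write-read round trip preserves all fields.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  out <- as.data.frame(cohort)[, .cohort_columns, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8", quote = which(
                       .cohort_columns %in% c("text", "clinical_diagnosis",
                                              "sex", "subject_id", "session_id")))
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out)))
      writeLines(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
  }
  invisible(path)
}

#' @export
print.conv_cohort <- function(x, ...) {
  cat(sprintf("Free-conversation cohort: %d sessions from %d subjects\n",
              nrow(x), length(unique(x$subject_id))))
  if (nrow(x) > 0L)
    cat(sprintf("  letters per session: median %.0f (range %d-%d)\n",
                stats::median(x$letter_count), min(x$letter_count),
                max(x$letter_count)))
  NextMethod()
  invisible(x)
}
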