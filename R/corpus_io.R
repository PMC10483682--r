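# Corpus reading/writing, inclusion/exclusion filtering and user
# pseudonymization.
#
# A corpus is a tibble with one row per post and columns
#   tweet_id, user_id, created_at (POSIXct, UTC), text, medication,
#   is_retweet, is_quote
# carrying class "nmu_corpus" so downstream stages can validate input.

CORPUS_COLUMNS <- c(
  "tweet_id", "user_id", "created_at", "text",
  "medication", "is_retweet", "is_quote"
)

#' Construct a corpus from its columns
#'
#' Validates field types and uniqueness, parses timestamps to UTC and
#' attaches the `nmu_corpus` class.  Mostly used by [read_corpus()] and
#' the synthetic generators; end users rarely call it directly.
#'
#' @param df A data frame with columns `tweet_id`, `user_id`,
#'   `created_at` (ISO-8601 string or POSIXct), `text`, `medication`,
#'   `is_retweet`, `is_quote`.
#' @return A tibble of class `nmu_corpus`.
#' @export
as_corpus <- function(df) {
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop_nmu("corpus is missing required column(s): ",
             paste(missing_cols, collapse = ", "),
             class = "nmutext_parse_error")
  }
  df <- tibble::as_tibble(df[CORPUS_COLUMNS])
  df$tweet_id <- as.character(df$tweet_id)
  df$user_id <- as.character(df$user_id)
  df$text <- as.character(df$text)
  df$medication <- as.character(df$medication)
  df$is_retweet <- as.logical(df$is_retweet)
  df$is_quote <- as.logical(df$is_quote)
  if (!inherits(df$created_at, "POSIXct")) {
    df$created_at <- parse_utc(as.character(df$created_at))
  }
  if (anyNA(df$created_at)) {
    bad <- which(is.na(df$created_at))[1]
    stop_nmu("unparseable timestamp in record ", bad,
             class = "nmutext_parse_error")
  }
  if (any(!nzchar(df$tweet_id)) || anyNA(df$tweet_id)) {
    stop_nmu("empty or missing tweet_id", class = "nmutext_parse_error")
  }
  if (anyDuplicated(df$tweet_id)) {
    dup <- df$tweet_id[duplicated(df$tweet_id)][1]
    stop_nmu("duplicate tweet_id: ", dup,
             class = "nmutext_integrity_error")
  }
  class(df) <- c("nmu_corpus", class(df))
  df
}

# ISO-8601 parser for the two shapes we emit: with or without a
# trailing "Z" / offset, seconds required.
#' @noRd
parse_utc <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("\\+00:?00$", "", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%d %H:%M:%S",
                                tz = "UTC")
  }
  out
}

#' @noRd
format_utc <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read a tweet corpus from JSONL or CSV
#'
#' JSONL files hold one JSON object per line with keys `tweet_id`,
#' `user_id`, `created_at` (ISO-8601), `text`, `medication`,
#' `is_retweet`, `is_quote`; CSV files carry the same header.  Records
#' are returned in file order; duplicate ids and missing fields are
#' rejected with the offending line number.
#'
#' @param path Path to the corpus file.
#' @param format Either `"jsonl"` or `"csv"`; default guessed from the
#'   file extension.
#' @return An `nmu_corpus` tibble.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  if (!file.exists(path)) {
    stop_nmu("corpus file not found: ", path, class = "nmutext_io_error")
  }
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE)
    if (nrow(df) == 0 && ncol(df) == 0) {
      df <- empty_corpus_df()
    }
    return(as_corpus(df))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_corpus(empty_corpus_df()))
  }
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop_nmu("malformed JSON on line ", i, ": ", conditionMessage(e),
                 class = "nmutext_parse_error")
      }
    )
    missing_keys <- setdiff(CORPUS_COLUMNS, names(rec))
    if (length(missing_keys) > 0) {
      stop_nmu("record on line ", i, " is missing field(s): ",
               paste(missing_keys, collapse = ", "),
               class = "nmutext_parse_error")
    }
    records[[i]] <- rec[CORPUS_COLUMNS]
  }
  df <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  as_corpus(df)
}

#' @noRd
empty_corpus_df <- function() {
  data.frame(
    tweet_id = character(), user_id = character(),
    created_at = as.POSIXct(character(), tz = "UTC"),
    text = character(), medication = character(),
    is_retweet = logical(), is_quote = logical(),
    stringsAsFactors = FALSE
  )
}

#' Write a corpus to JSONL or CSV
#'
#' @param corpus An `nmu_corpus`.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(corpus)
  df$created_at <- format_utc(df$created_at)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

# Default keyword families: generic name, trade names, street names and
# common misspellings for the four medication classes tracked.
#' Default medication keyword families
#'
#' Generic names, trade names and common misspellings for the four
#' tracked medications: fentanyl and morphine (opioids), alprazolam
#' (benzodiazepine) and adderall (stimulant).
#'
#' @return Named list mapping medication to a character vector of terms.
#' @export
default_keyword_families <- function() {
  list(
    fentanyl   = c("fentanyl", "fentanil", "fentynal", "fentanyl", "fent"),
    morphine   = c("morphine", "morfine", "morphene", "ms-contin"),
    alprazolam = c("alprazolam", "xanax", "xannax", "xanex", "alprazolm",
                   "xannies"),
    adderall   = c("adderall", "adderal", "aderall", "aderal", "addy")
  )
}

#' Build a filter configuration
#'
#' Encodes the corpus inclusion/exclusion rules: a closed UTC date
#' interval, an English-language predicate, at least one medication
#' keyword (matched case-insensitively as whole tokens, misspellings
#' included), a minimum token count, exclusion of retweets and quoted
#' posts, and two pluggable predicates standing in for external
#' bot-account and non-medical-use classifiers (defaults accept all).
#'
#' @param date_start,date_end Closed UTC interval; ISO strings or POSIXct.
#' @param keyword_families Named list medication -> character terms.
#' @param min_tokens Minimum token count to retain a post (default 4;
#'   the threshold is a study choice, so it is configurable).
#' @param language_predicate Function of the text returning TRUE when
#'   the post should be treated as English.  The default heuristic
#'   accepts text with at least 90% Basic-Latin characters and at
#'   least one ASCII letter.
#' @param bot_predicate,nmu_predicate Functions of a one-row corpus
#'   slice returning TRUE to keep the post.  Defaults accept all.
#' @return A list of class `nmu_filter_config`.
#' @export
filter_config <- function(date_start = "2021-05-31T00:00:00Z",
                          date_end = "2021-10-31T23:59:59Z",
                          keyword_families = default_keyword_families(),
                          min_tokens = 4,
                          language_predicate = default_language_predicate,
                          bot_predicate = accept_all,
                          nmu_predicate = accept_all) {
  ds <- if (inherits(date_start, "POSIXct")) date_start else parse_utc(date_start)
  de <- if (inherits(date_end, "POSIXct")) date_end else parse_utc(date_end)
  if (is.na(ds) || is.na(de) || ds > de) {
    stop_nmu("invalid date interval", class = "nmutext_config_error")
  }
  if (length(keyword_families) == 0 ||
      any(vapply(keyword_families, length, 1L) == 0)) {
    stop_nmu("every keyword family must be non-empty",
             class = "nmutext_config_error")
  }
  if (!is.numeric(min_tokens) || min_tokens < 1) {
    stop_nmu("min_tokens must be >= 1", class = "nmutext_config_error")
  }
  structure(
    list(
      date_start = ds, date_end = de,
      keyword_families = lapply(keyword_families, tolower),
      min_tokens = as.integer(min_tokens),
      language_predicate = language_predicate,
      bot_predicate = bot_predicate,
      nmu_predicate = nmu_predicate
    ),
    class = "nmu_filter_config"
  )
}

#' Predicate accepting every record (default bot/NMU gate)
#'
#' @param x Ignored.
#' @return TRUE.
#' @export
accept_all <- function(x) TRUE

#' Heuristic English-language gate
#'
#' Accepts text in which at least 90% of non-space characters fall in
#' the Basic Latin block and at least one ASCII letter occurs.  A
#' proper language identifier can be plugged in through
#' [filter_config()].
#'
#' @param text A character scalar.
#' @return TRUE/FALSE.
#' @export
default_language_predicate <- function(text) {
  chars <- strsplit(gsub("\\s", "", text), "")[[1]]
  if (length(chars) == 0) return(FALSE)
  latin <- vapply(chars, function(ch) utf8ToInt(ch) <= 127, logical(1))
  mean(latin) >= 0.9 && grepl("[A-Za-z]", text)
}

# The fixed attribution order: a removed post is charged to the FIRST
# failing rule, so the report counts partition the removals.
FILTER_RULES <- c("date", "language", "keyword", "length",
                  "retweet_quote", "bot", "nmu")

#' Apply inclusion/exclusion filters to a corpus
#'
#' Retains posts that satisfy every inclusion rule and no exclusion
#' rule.  Each removal is attributed to the first failing rule in the
#' fixed order date, language, keyword, length, retweet_quote, bot,
#' nmu, so the per-rule counts in the report sum to the number removed.
#' Filtering is idempotent.
#'
#' @param corpus An `nmu_corpus`.
#' @param config An `nmu_filter_config` from [filter_config()].
#' @return A list with elements `corpus` (the retained posts) and
#'   `report` (class `nmu_filter_report`: `n_in`, `n_out`,
#'   `counts_removed`).
#' @export
apply_filters <- function(corpus, config = filter_config()) {
  stopifnot(inherits(corpus, "nmu_corpus"),
            inherits(config, "nmu_filter_config"))
  keywords <- unique(tolower(unlist(config$keyword_families)))
  counts <- stats::setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  keep <- logical(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    row <- corpus[i, ]
    rule <- first_failing_rule(row, config, keywords)
    if (is.na(rule)) {
      keep[i] <- TRUE
    } else {
      counts[rule] <- counts[rule] + 1L
    }
  }
  out <- corpus[keep, ]
  class(out) <- class(corpus)
  report <- structure(
    list(n_in = nrow(corpus), n_out = nrow(out),
         counts_removed = as.list(counts[counts > 0L])),
    class = "nmu_filter_report"
  )
  list(corpus = out, report = report)
}

#' @noRd
first_failing_rule <- function(row, config, keywords) {
  ts <- row$created_at
  if (ts < config$date_start || ts > config$date_end) return("date")
  if (!isTRUE(config$language_predicate(row$text))) return("language")
  tokens <- tolower(regmatches(
    row$text, gregexpr("[[:alnum:]][[:alnum:]'-]*", row$text)
  )[[1]])
  if (!any(tokens %in% keywords)) return("keyword")
  if (length(tokens) < config$min_tokens) return("length")
  if (isTRUE(row$is_retweet) || isTRUE(row$is_quote)) return("retweet_quote")
  if (!isTRUE(config$bot_predicate(row))) return("bot")
  if (!isTRUE(config$nmu_predicate(row))) return("nmu")
  NA_character_
}

#' Write a filter report as JSON
#'
#' @param report An `nmu_filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_in = report$n_in, n_out = report$n_out,
         counts_removed = report$counts_removed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Pseudonymize user identifiers
#'
#' Replaces every `user_id` with a keyed one-way digest of (salt,
#' user_id).  The mapping is deterministic for a given salt, never
#' returns the raw id, and a digest collision between distinct users
#' raises an error rather than silently merging them.  All other
#' fields are untouched.
#'
#' @param corpus An `nmu_corpus`.
#' @param salt Non-empty secret string keying the digest.
#' @return The corpus with pseudonymous user ids.
#' @export
deidentify <- function(corpus, salt) {
  if (!is.character(salt) || length(salt) != 1 || !nzchar(salt)) {
    stop_nmu("salt must be a non-empty string",
             class = "nmutext_config_error")
  }
  ids <- corpus$user_id
  uniq <- unique(ids)
  digests <- vapply(uniq, function(u) paste0("u", keyed_digest(salt, u)),
                    character(1))
  if (anyDuplicated(digests)) {
    stop_nmu("digest collision between distinct user ids",
             class = "nmutext_integrity_error")
  }
  if (any(digests == uniq)) {
    stop_nmu("pseudonym equals raw user id", class = "nmutext_integrity_error")
  }
  corpus$user_id <- unname(digests[match(ids, uniq)])
  corpus
}
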