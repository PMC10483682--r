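# Text cleaning, rule-based sentence splitting, tokenization and the
# record-by-token count matrix.
#
# Character offsets are 0-based, half-open [start, end), matching the
# token-span convention used by the chunker.

#' Clean raw post text
#'
#' Removes URLs, @-mentions and control characters (each removal logged
#' with its character span in the raw string), strips `#` from hashtags
#' while keeping the word, lowercases, and normalizes whitespace to
#' single spaces.  Idempotent: cleaning cleaned text changes nothing.
#'
#' @param raw A character scalar (possibly empty).
#' @return A list of class `nmu_clean_text` with `text` and
#'   `removed_spans` (data frame `start`, `end`, `reason`; 0-based
#'   half-open spans into `raw`).
#' @export
clean_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  spans <- data.frame(start = integer(), end = integer(),
                      reason = character(), stringsAsFactors = FALSE)
  find_spans <- function(pattern, reason, text) {
    m <- gregexpr(pattern, text, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               reason = reason, stringsAsFactors = FALSE)
  }
  spans <- rbind(
    spans,
    find_spans("https?://[^\\s]+|www\\.[^\\s]+", "url", raw),
    find_spans("(?<![[:alnum:]])@[[:alnum:]_]+", "mention", raw),
    find_spans("[\\x00-\\x08\\x0b\\x0c\\x0e-\\x1f\\x7f]", "control", raw)
  )
  if (nrow(spans) > 0) spans <- spans[order(spans$start), , drop = FALSE]
  rownames(spans) <- NULL

  # blank out removed spans (keeping a space so neighbours do not merge)
  chars <- strsplit(raw, "")[[1]]
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) {
      idx <- seq.int(spans$start[k] + 1L, spans$end[k])
      chars[idx] <- " "
    }
  }
  text <- paste(chars, collapse = "")
  text <- gsub("#([[:alnum:]])", "\\1", text)
  text <- tolower(text)
  text <- gsub("[\r\n\t]", " ", text)
  text <- gsub(" +", " ", text)
  text <- trimws(text)
  structure(list(text = text, removed_spans = spans),
            class = "nmu_clean_text")
}

#' Split cleaned text into sentence spans
#'
#' Sentence boundaries are runs of terminal punctuation (`.`, `!`,
#' `?`, or the ellipsis character); a run of periods or an ellipsis
#' collapses to a single boundary.  Trailing text without terminal
#' punctuation forms a final sentence.  Spans are 0-based half-open,
#' disjoint, ordered, and together cover every non-whitespace
#' character.
#'
#' @param text An `nmu_clean_text` or a character scalar.
#' @return Data frame with columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  if (inherits(text, "nmu_clean_text")) text <- text$text
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar(text)
  empty <- data.frame(start = integer(), end = integer())
  if (n == 0) return(empty)
  chars <- strsplit(text, "")[[1]]
  terminal <- chars %in% c(".", "!", "?", "…")
  ws <- grepl("\\s", chars)
  starts <- integer()
  ends <- integer()
  i <- 1L
  while (i <= n) {
    while (i <= n && ws[i]) i <- i + 1L
    if (i > n) break
    start <- i
    # advance to the end of a terminal-punctuation run or end of text
    while (i <= n && !terminal[i]) i <- i + 1L
    while (i <= n && terminal[i]) i <- i + 1L
    end <- i - 1L
    while (end > start && ws[end]) end <- end - 1L
    starts <- c(starts, start - 1L)
    ends <- c(ends, end)
  }
  data.frame(start = starts, end = ends)
}

#' Tokenize a cleaned record
#'
#' Tokens are maximal runs of letters/digits or single punctuation
#' marks (emoji and other symbols survive as single tokens).  Each
#' token carries its 0-based half-open character offsets into the
#' cleaned text, and tokens are grouped into the sentences reported by
#' [split_sentences()].
#'
#' @param record_id Identifier carried through to the output.
#' @param text An `nmu_clean_text` or character scalar.
#' @return A list of class `nmu_tokens` with `record_id`, `tokens`
#'   (character vector), `sentences` (list of token character vectors),
#'   and `char_offsets` (data frame `start`, `end`).
#' @export
tokenize <- function(record_id, text) {
  if (inherits(text, "nmu_clean_text")) text <- text$text
  stopifnot(is.character(text), length(text) == 1)
  sent_spans <- split_sentences(text)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(structure(
      list(record_id = record_id, tokens = character(),
           sentences = list(),
           char_offsets = data.frame(start = integer(), end = integer())),
      class = "nmu_tokens"
    ))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  tokens <- substring(text, starts + 1L, ends)
  sentences <- list()
  if (nrow(sent_spans) > 0) {
    for (s in seq_len(nrow(sent_spans))) {
      inside <- starts >= sent_spans$start[s] & ends <= sent_spans$end[s]
      sentences[[s]] <- tokens[inside]
    }
  }
  structure(
    list(record_id = as.character(record_id), tokens = tokens,
         sentences = sentences,
         char_offsets = data.frame(start = starts, end = ends)),
    class = "nmu_tokens"
  )
}

#' Clean and tokenize every record of a corpus
#'
#' @param corpus An `nmu_corpus`.
#' @return List of `nmu_tokens`, one per record, in corpus order.
#' @export
tokenize_corpus <- function(corpus) {
  lapply(seq_len(nrow(corpus)), function(i) {
    tokenize(corpus$tweet_id[i], clean_text(corpus$text[i]))
  })
}

#' Build the record-by-token count matrix
#'
#' Vocabulary indices follow first occurrence across records; entry
#' (i, j) counts occurrences of token j in record i.
#'
#' @param records Non-empty list of `nmu_tokens`.
#' @return List of class `nmu_token_matrix` with `record_ids`,
#'   `vocabulary` (named integer vector, 1-based column index) and
#'   `counts` (dense matrix, records x tokens).
#' @export
build_token_matrix <- function(records) {
  if (length(records) == 0) {
    stop_nmu("record list must be non-empty", class = "nmutext_contract_error")
  }
  all_tokens <- unlist(lapply(records, `[[`, "tokens"), use.names = FALSE)
  vocab_terms <- unique(all_tokens)
  vocab <- stats::setNames(seq_along(vocab_terms), vocab_terms)
  counts <- matrix(0L, nrow = length(records), ncol = length(vocab_terms),
                   dimnames = list(
                     vapply(records, `[[`, character(1), "record_id"),
                     vocab_terms
                   ))
  for (i in seq_along(records)) {
    toks <- records[[i]]$tokens
    if (length(toks) == 0) next
    tab <- table(toks)
    counts[i, names(tab)] <- as.integer(tab)
  }
  structure(
    list(record_ids = rownames(counts), vocabulary = vocab, counts = counts),
    class = "nmu_token_matrix"
  )
}

#' Export a token matrix as sparse-triplet text plus a vocabulary TSV
#'
#' Writes `<path>.mtx` in MatrixMarket coordinate format (1-based row,
#' column, count triplets) and `<path>.vocab.tsv` with columns
#' `index`, `token`.
#'
#' @param tm An `nmu_token_matrix`.
#' @param path Output stem (extensions appended).
#' @export
write_token_matrix <- function(tm, path) {
  nz <- which(tm$counts != 0, arr.ind = TRUE)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(nrow(tm$counts), ncol(tm$counts), nrow(nz)),
    sprintf("%d %d %d", nz[, 1], nz[, 2], tm$counts[nz])
  )
  writeLines(lines, paste0(path, ".mtx"))
  utils::write.table(
    data.frame(index = unname(tm$vocabulary), token = names(tm$vocabulary)),
    paste0(path, ".vocab.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
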