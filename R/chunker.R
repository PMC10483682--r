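# IOB2 tag schema and chunk conversion ("NER enhancer"): IOB tag
# sequences become labelled entity spans, with conlleval-style repair
# of illegal sequences.

#' Build an IOB2 tag schema
#'
#' The tag list is `O` followed by `B-X`, `I-X` for each entity label
#' in order, so `|tags| = 2 * |labels| + 1`.  Indices are 0-based and
#' exposed through `index`.
#'
#' @param entity_labels Ordered character vector of entity type names.
#'   Default mirrors the entity families extracted from medication
#'   chatter: drugs, adverse drug events, symptoms, treatments and the
#'   demographic mentions age and gender.
#' @return A list of class `nmu_tag_schema` with `entity_labels`,
#'   `tags`, and `index` (named 0-based integers).
#' @export
tag_schema <- function(entity_labels = c("DRUG", "ADE", "SYMPTOM",
                                         "TREATMENT", "AGE", "GENDER")) {
  entity_labels <- as.character(entity_labels)
  if (length(entity_labels) == 0 || anyDuplicated(entity_labels)) {
    stop_nmu("entity labels must be non-empty and unique",
             class = "nmutext_config_error")
  }
  tags <- c("O", as.vector(rbind(paste0("B-", entity_labels),
                                 paste0("I-", entity_labels))))
  structure(
    list(entity_labels = entity_labels, tags = tags,
         index = stats::setNames(seq_along(tags) - 1L, tags)),
    class = "nmu_tag_schema"
  )
}

#' @noRd
check_tags_known <- function(tags, schema) {
  unknown <- setdiff(tags, schema$tags)
  if (length(unknown) > 0) {
    stop_nmu("unknown tag(s): ", paste(unknown, collapse = ", "),
             class = "nmutext_contract_error")
  }
}

#' @noRd
tag_entity <- function(tag) sub("^[BI]-", "", tag)

#' Is a tag sequence legal IOB2?
#'
#' @param tags Character vector of tags.
#' @param schema An `nmu_tag_schema`.
#' @return TRUE/FALSE.
#' @export
is_iob_legal <- function(tags, schema) {
  check_tags_known(tags, schema)
  prev <- "O"
  for (t in tags) {
    if (startsWith(t, "I-")) {
      ok <- prev %in% paste0(c("B-", "I-"), tag_entity(t))
      if (!ok) return(FALSE)
    }
    prev <- t
  }
  TRUE
}

#' Repair an illegal IOB sequence
#'
#' A stray `I-X` (no adjacent preceding `B-X`/`I-X`) is rewritten to
#' `B-X`; this is the "treat stray inside as begin" convention used by
#' the CoNLL evaluation script.  Legal sequences pass through
#' unchanged; the operation is idempotent.
#'
#' @param tags Character vector of tags.
#' @param schema An `nmu_tag_schema`.
#' @return Repaired tag vector.
#' @export
repair_iob <- function(tags, schema) {
  check_tags_known(tags, schema)
  out <- tags
  prev <- "O"
  for (i in seq_along(out)) {
    t <- out[i]
    if (startsWith(t, "I-") &&
        !(prev %in% paste0(c("B-", "I-"), tag_entity(t)))) {
      out[i] <- paste0("B-", tag_entity(t))
    }
    prev <- out[i]
  }
  out
}

#' Convert an IOB2 tag sequence to entity spans (chunks)
#'
#' One span per maximal `B-X (I-X)*` run; `O` tokens produce nothing.
#' Spans are 0-based half-open token intervals, ordered by start and
#' non-overlapping, with the surface text joined by single spaces.
#'
#' @param tokens Character vector of tokens.
#' @param tags Parallel tag vector, legal IOB2 (run [repair_iob()]
#'   first otherwise).
#' @param schema An `nmu_tag_schema`.
#' @return Data frame with columns `start`, `end`, `label`, `text`.
#' @export
iob_to_chunks <- function(tokens, tags, schema) {
  stopifnot(length(tokens) == length(tags))
  if (!is_iob_legal(tags, schema)) {
    stop_nmu("illegal IOB2 sequence; call repair_iob() first",
             class = "nmutext_contract_error")
  }
  starts <- integer(); ends <- integer(); labels <- character()
  open <- FALSE; s <- 0L; lab <- ""
  close_run <- function(e) {
    starts <<- c(starts, s); ends <<- c(ends, e); labels <<- c(labels, lab)
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "B-")) {
      if (open) close_run(i - 1L)
      open <- TRUE; s <- i - 1L; lab <- tag_entity(t)
    } else if (t == "O") {
      if (open) close_run(i - 1L)
      open <- FALSE
    }
    # I-X continues the open run (legality guarantees a matching open)
  }
  if (open) close_run(length(tags))
  data.frame(
    start = starts, end = ends, label = labels,
    text = vapply(seq_along(starts), function(k) {
      paste(tokens[(starts[k] + 1L):ends[k]], collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Convert entity spans back to an IOB2 tag sequence
#'
#' Exact inverse of [iob_to_chunks()] on legal input.
#'
#' @param spans Data frame with `start`, `end`, `label` (0-based
#'   half-open, non-overlapping).
#' @param length Sequence length in tokens.
#' @param schema An `nmu_tag_schema`.
#' @return Character tag vector of the given length.
#' @export
chunks_to_iob <- function(spans, length, schema) {
  tags <- rep("O", length)
  if (nrow(spans) == 0) return(tags)
  if (any(spans$start < 0) || any(spans$end > length) ||
      any(spans$start >= spans$end)) {
    stop_nmu("span outside sequence or empty", class = "nmutext_contract_error")
  }
  covered <- logical(length)
  spans <- spans[order(spans$start), , drop = FALSE]
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    if (any(covered[idx])) {
      stop_nmu("overlapping spans", class = "nmutext_contract_error")
    }
    covered[idx] <- TRUE
    if (!spans$label[k] %in% schema$entity_labels) {
      stop_nmu("unknown entity label: ", spans$label[k],
               class = "nmutext_contract_error")
    }
    tags[idx[1]] <- paste0("B-", spans$label[k])
    if (length(idx) > 1) tags[idx[-1]] <- paste0("I-", spans$label[k])
  }
  tags
}

#' Write chunk spans for a corpus as TSV
#'
#' Columns: record_id, start, end, label, text — the per-post entity
#' output feeding downstream tallies such as substance co-mentions and
#' adverse-event frequencies.
#'
#' @param chunks Data frame with a `record_id` column plus the
#'   [iob_to_chunks()] columns.
#' @param path Output path.
#' @export
write_chunks_tsv <- function(chunks, path) {
  utils::write.table(
    chunks[, c("record_id", "start", "end", "label", "text")],
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
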