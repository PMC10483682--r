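# End-to-end pipeline: filter -> pseudonymize -> preprocess -> tag ->
# chunk -> tally -> topics, with every artifact written to disk and a
# MANIFEST recording completeness.  Deterministic per (config, seed).

#' Assemble a pipeline configuration
#'
#' @param input Path to a JSONL/CSV corpus, an `nmu_corpus`, or NULL
#'   to simulate a corpus with [generate_ner_corpus()].
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed driving simulation, training, splits and
#'   any stochastic stage.
#' @param filter An `nmu_filter_config`.
#' @param ner An `nmu_ner_config` (used when training is needed).
#' @param model_path Optional path to a serialized tagger; when absent,
#'   `train_sequences` (or a simulated corpus's gold sequences) are
#'   used to train one.
#' @param train_sequences Optional list of labelled sequences for
#'   training.
#' @param embed_dim Embedding provider dimension (default 32).
#' @param target_dim Reduction dimension for topic modelling.
#' @param min_cluster_size,distance_threshold Clustering parameters.
#' @param top_n Words per topic; `top_k` words scored for coherence.
#' @param top_k See above.
#' @param n_records Simulated corpus size when `input` is NULL.
#' @return A list of class `nmu_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir, seed = 1,
                            filter = filter_config(),
                            ner = ner_config(),
                            model_path = NULL, train_sequences = NULL,
                            embed_dim = 32, target_dim = 5,
                            min_cluster_size = 5, distance_threshold = 0.5,
                            top_n = 5, top_k = 5, n_records = 120) {
  structure(
    list(input = input, out_dir = out_dir, seed = as.integer(seed),
         filter = filter, ner = ner, model_path = model_path,
         train_sequences = train_sequences, embed_dim = embed_dim,
         target_dim = target_dim, min_cluster_size = min_cluster_size,
         distance_threshold = distance_threshold, top_n = top_n,
         top_k = top_k, n_records = n_records),
    class = "nmu_pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Stages: load or simulate the corpus; apply inclusion/exclusion
#' filters (report written as JSON); pseudonymize user ids; clean and
#' tokenize; obtain a tagger (load, or train on the supplied/simulated
#' labelled sequences); tag every record and emit entity chunks as
#' TSV; tally per-label entity frequencies and per-medication
#' substance co-mentions; embed, reduce, cluster and extract topics
#' (JSON), topics-over-time (CSV) and coherence (JSON).  A MANIFEST
#' file lists each artifact with its completion state; reruns with the
#' same config and seed reproduce the chunk TSV and topics JSON bit
#' for bit.
#'
#' @param config An `nmu_pipeline_config`.
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_lines <- c(sprintf("seed: %d", config$seed))
  note <- function(stage, file) {
    manifest[[stage]] <<- list(file = file, complete = TRUE)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  on.exit(write_manifest(), add = TRUE)

  # --- corpus ---------------------------------------------------------
  synth <- NULL
  if (is.null(config$input)) {
    synth <- generate_ner_corpus(n_records = config$n_records,
                                 seed = config$seed)
    corpus <- synth$corpus
    log_lines <- c(log_lines, sprintf("simulated corpus: %d records",
                                      nrow(corpus)))
  } else if (inherits(config$input, "nmu_corpus")) {
    corpus <- config$input
  } else {
    corpus <- read_corpus(config$input)
  }

  # --- filters and pseudonymization ----------------------------------
  filtered <- apply_filters(corpus, config$filter)
  write_filter_report(filtered$report,
                      file.path(config$out_dir, "filter_report.json"))
  note("filter", "filter_report.json")
  corpus <- deidentify(filtered$corpus, salt = paste0("pipeline-",
                                                      config$seed))

  # --- preprocess -----------------------------------------------------
  records <- tokenize_corpus(corpus)
  nonempty <- vapply(records, function(r) length(r$tokens) > 0, logical(1))
  records <- records[nonempty]
  corpus <- corpus[nonempty, ]
  if (nrow(corpus) == 0) {
    stop_nmu("no records survive filtering and cleaning",
             class = "nmutext_pipeline_error")
  }

  # --- tagger ---------------------------------------------------------
  provider <- hash_provider(dim = config$embed_dim, seed = config$seed)
  if (!is.null(config$model_path)) {
    params <- read_ner_model(config$model_path)
  } else {
    train_seqs <- config$train_sequences
    if (is.null(train_seqs) && !is.null(synth)) train_seqs <- synth$sequences
    if (is.null(train_seqs)) {
      stop_nmu("ner stage: no trained model and no training data",
               class = "nmutext_pipeline_error")
    }
    schema <- tag_schema(names(default_gazetteers()))
    fit <- train_ner(train_seqs, schema, config$ner, provider)
    params <- fit$params
    write_ner_model(params, file.path(config$out_dir, "ner_model.json"))
    note("ner_train", "ner_model.json")
    log_lines <- c(log_lines,
                   sprintf("trained tagger: %d epochs, final NLL %.4f",
                           length(fit$report$epoch_nll),
                           utils::tail(fit$report$epoch_nll, 1)))
  }

  # --- tag and chunk --------------------------------------------------
  chunk_rows <- list()
  for (i in seq_along(records)) {
    pred <- predict_tags(records[[i]]$tokens, params, provider)
    spans <- iob_to_chunks(pred$tokens,
                           repair_iob(pred$tags, params$schema),
                           params$schema)
    if (nrow(spans) > 0) {
      spans$record_id <- records[[i]]$record_id
      chunk_rows[[length(chunk_rows) + 1]] <- spans
    }
  }
  chunks <- if (length(chunk_rows) > 0) do.call(rbind, chunk_rows) else
    data.frame(record_id = character(), start = integer(), end = integer(),
               label = character(), text = character())
  write_chunks_tsv(chunks, file.path(config$out_dir, "chunks.tsv"))
  note("chunks", "chunks.tsv")

  # --- entity tallies -------------------------------------------------
  freq <- if (nrow(chunks) > 0) {
    stats::aggregate(list(count = chunks$record_id),
                     by = list(label = chunks$label, term = chunks$text),
                     FUN = length)
  } else {
    data.frame(label = character(), term = character(), count = integer())
  }
  freq <- freq[order(freq$label, -freq$count, freq$term), ]
  utils::write.table(freq, file.path(config$out_dir, "entity_freq.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  note("entity_freq", "entity_freq.tsv")

  med_of <- stats::setNames(corpus$medication, corpus$tweet_id)
  drug_chunks <- chunks[chunks$label == "DRUG", , drop = FALSE]
  comention <- if (nrow(drug_chunks) > 0) {
    df <- data.frame(medication = unname(med_of[drug_chunks$record_id]),
                     substance = drug_chunks$text, stringsAsFactors = FALSE)
    out <- stats::aggregate(list(count = df$substance),
                            by = list(medication = df$medication,
                                      substance = df$substance),
                            FUN = length)
    out[order(out$medication, -out$count, out$substance), ]
  } else {
    data.frame(medication = character(), substance = character(),
               count = integer())
  }
  utils::write.table(comention, file.path(config$out_dir, "comentions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  note("comentions", "comentions.tsv")

  # --- topics ---------------------------------------------------------
  tm <- build_token_matrix(records)
  emb <- embed_corpus(provider, records)
  k <- min(config$target_dim, ncol(emb), nrow(emb) - 1)
  reduced <- reduce_dim(emb, target_dim = k)
  labels <- cluster_docs(reduced,
                         min_cluster_size = config$min_cluster_size,
                         distance_threshold = config$distance_threshold)
  topics <- list(); tot <- NULL; coh <- list(per_topic = NULL, mean = NA)
  if (any(labels >= 0)) {
    ct <- ctfidf(tm, labels)
    sizes <- table(labels[labels >= 0])
    topics <- extract_topics(ct, top_n = config$top_n, sizes = sizes)
    tot <- topics_over_time(tm, labels, corpus$created_at)
    coh <- suppressWarnings(topic_coherence(topics, provider,
                                            top_k = config$top_k))
  }
  write_topics_json(topics, file.path(config$out_dir, "topics.json"))
  note("topics", "topics.json")
  if (!is.null(tot)) {
    utils::write.csv(tot, file.path(config$out_dir, "topics_over_time.csv"),
                     row.names = FALSE)
    note("topics_over_time", "topics_over_time.csv")
  }
  jsonlite::write_json(
    list(per_topic = coh$per_topic, mean = coh$mean),
    file.path(config$out_dir, "coherence.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  note("coherence", "coherence.json")

  log_lines <- c(log_lines,
                 sprintf("records tagged: %d", length(records)),
                 sprintf("chunks: %d", nrow(chunks)),
                 sprintf("topics: %d (outliers %d)", length(topics),
                         sum(labels < 0)))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  write_manifest()
  invisible(list(corpus = corpus, chunks = chunks, freq = freq,
                 comention = comention, topics = topics,
                 topics_over_time = tot, coherence = coh,
                 labels = labels, params = params))
}
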