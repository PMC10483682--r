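# Pluggable token-embedding providers.
#
# The NER tagger and the topic modeller consume embeddings only through
# the provider contract: a function mapping a token vector to an
# (n_tokens x dim) matrix.  The two shipped providers are context-free
# and deterministic; an adapter around an external contextual encoder
# can be supplied wherever a provider is accepted.

#' @noRd
new_provider <- function(name, dim, embed_tokens, deterministic = TRUE) {
  structure(
    list(name = name, dim = as.integer(dim), embed_tokens = embed_tokens,
         deterministic = deterministic),
    class = "nmu_embedding_provider"
  )
}

#' Deterministic hashed embedding provider
#'
#' Maps each token to a unit-norm vector derived from a keyed hash of
#' (token, seed): coordinate i is the normal quantile of a hash of
#' (token, seed, i), and the vector is scaled to Euclidean norm 1.
#' Context-independent, needs no vocabulary, and identical across
#' sessions — the reproducible stand-in for large pre-trained
#' contextual encoders.
#'
#' @param dim Embedding dimension (>= 1); default 32.
#' @param seed Integer key; different seeds give unrelated embeddings.
#' @return An `nmu_embedding_provider`.
#' @export
hash_provider <- function(dim = 32, seed = 0) {
  if (!is.numeric(dim) || dim < 1) {
    stop_nmu("dim must be >= 1", class = "nmutext_config_error")
  }
  dim <- as.integer(dim)
  cache <- new.env(parent = emptyenv())
  embed_one <- function(token) {
    key <- paste0("t", token)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # the keyed hash seeds a well-mixed generator, so coordinates are
    # effectively independent across tokens
    v <- with_local_seed(
      fnv1a32(paste0(token, "\x1f", seed)) %% 2147483647,
      stats::rnorm(dim)
    )
    v <- v / sqrt(sum(v^2))
    cache[[key]] <- v
    v
  }
  new_provider(
    name = sprintf("hash(dim=%d,seed=%d)", dim, seed),
    dim = dim,
    embed_tokens = function(tokens) {
      out <- t(vapply(tokens, embed_one, numeric(dim)))
      dimnames(out) <- NULL
      matrix(out, nrow = length(tokens), ncol = dim)
    }
  )
}

#' Trainable lookup-table embedding provider
#'
#' A (vocabulary x dim) table initialized from seeded uniform(-0.1,
#' 0.1) draws.  Out-of-vocabulary tokens share a single UNK row.  The
#' table is exposed in the returned object so a training loop may
#' update it in place.
#'
#' @param vocabulary Character vector (or named index) of known tokens.
#' @param dim Embedding dimension; default 32.
#' @param seed Integer seed for the initialization.
#' @return An `nmu_embedding_provider` with an extra `table` element
#'   (rows named by token, last row `"<UNK>"`).
#' @export
lookup_provider <- function(vocabulary, dim = 32, seed = 0) {
  if (is.numeric(vocabulary)) vocabulary <- names(vocabulary)
  vocabulary <- unique(as.character(vocabulary))
  if (length(vocabulary) == 0) {
    stop_nmu("vocabulary must be non-empty", class = "nmutext_config_error")
  }
  dim <- as.integer(dim)
  rows <- c(vocabulary, "<UNK>")
  tab <- with_local_seed(seed, {
    matrix(stats::runif(length(rows) * dim, -0.1, 0.1),
           nrow = length(rows), ncol = dim,
           dimnames = list(rows, NULL))
  })
  env <- new.env(parent = emptyenv())
  env$table <- tab
  p <- new_provider(
    name = sprintf("lookup(|V|=%d,dim=%d,seed=%d)", length(vocabulary),
                   dim, seed),
    dim = dim,
    embed_tokens = function(tokens) {
      idx <- match(tokens, rownames(env$table))
      idx[is.na(idx)] <- nrow(env$table)  # UNK row
      m <- env$table[idx, , drop = FALSE]
      dimnames(m) <- NULL
      m
    }
  )
  p$table_env <- env
  p
}

#' Pool token embeddings into a document vector
#'
#' Arithmetic mean of the provider's token rows (mean pooling), the
#' first stage of the topic modeller.
#'
#' @param provider An `nmu_embedding_provider`.
#' @param tokens Non-empty character vector.
#' @return Numeric vector of length `provider$dim`.
#' @export
embed_document <- function(provider, tokens) {
  if (length(tokens) == 0) {
    stop_nmu("cannot embed an empty token list",
             class = "nmutext_contract_error")
  }
  colMeans(provider$embed_tokens(tokens))
}

#' Embed every record of a tokenized corpus
#'
#' Records with no tokens get a zero vector and a warning, so row
#' alignment with the corpus is preserved.
#'
#' @param provider An `nmu_embedding_provider`.
#' @param records List of `nmu_tokens`.
#' @return Matrix (records x dim) with record ids as row names.
#' @export
embed_corpus <- function(provider, records) {
  out <- matrix(0, nrow = length(records), ncol = provider$dim)
  empty <- 0L
  for (i in seq_along(records)) {
    toks <- records[[i]]$tokens
    if (length(toks) == 0) {
      empty <- empty + 1L
      next
    }
    out[i, ] <- embed_document(provider, toks)
  }
  if (empty > 0) {
    warning(empty, " empty record(s) embedded as zero vectors")
  }
  rownames(out) <- vapply(records, `[[`, character(1), "record_id")
  out
}

#' Serialize a lookup table to TSV (header line, then token<TAB>values)
#'
#' @param provider A provider from [lookup_provider()].
#' @param path Output path.
#' @export
write_embedding_table <- function(provider, path) {
  if (is.null(provider$table_env)) {
    stop_nmu("provider has no materialized table",
             class = "nmutext_config_error")
  }
  tab <- provider$table_env$table
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s dim=%d", provider$name, provider$dim), con)
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(c(rownames(tab)[i],
                       format(tab[i, ], digits = 17)), collapse = "\t"), con)
  }
  invisible(path)
}
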