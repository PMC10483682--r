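# Shared fixtures: a tiny schema/config pair, fixed-vector embedding
# providers, and brute-force CRF oracles (path enumeration) kept
# independent of the forward/Viterbi implementations they check.

tiny_schema <- function() tag_schema("DRUG")  # tags: O, B-DRUG, I-DRUG

tiny_config <- function(...) {
  defaults <- list(char_dim = 3, char_filters = 2, char_window = 3,
                   hidden_dim = 3, seed = 7)
  do.call(ner_config, utils::modifyList(defaults, list(...)))
}

# provider returning the same fixed vector for every token
constant_provider <- function(dim, value = 1) {
  structure(
    list(name = "const", dim = dim, deterministic = TRUE,
         embed_tokens = function(tokens) {
           matrix(value, nrow = length(tokens), ncol = dim)
         }),
    class = "nmu_embedding_provider"
  )
}

# provider with an explicit token -> vector table (rows named)
table_provider <- function(tab) {
  structure(
    list(name = "table", dim = ncol(tab), deterministic = TRUE,
         embed_tokens = function(tokens) {
           m <- tab[tokens, , drop = FALSE]
           dimnames(m) <- NULL
           m
         }),
    class = "nmu_embedding_provider"
  )
}

# all K^T path scores by direct summation (no recursions shared with
# the implementation under test)
enumerate_paths <- function(E, params) {
  K <- ncol(E); T_len <- nrow(E)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  apply(grid, 1, function(y) {
    s <- params$start[y[1]] + sum(E[cbind(seq_len(T_len), y)]) +
      params$end[y[T_len]]
    if (T_len > 1) s <- s + sum(params$trans[cbind(y[-T_len], y[-1])])
    unname(s)
  })
}

brute_logZ <- function(E, params) {
  s <- enumerate_paths(E, params)
  s <- s[is.finite(s)]
  log(sum(exp(s)))
}

brute_best <- function(E, params) max(enumerate_paths(E, params))

# random unconstrained CRF parameters over a given schema
random_crf_params <- function(schema, seed) {
  params <- init_ner_params(schema, tiny_config(constrain_transitions = FALSE),
                            word_dim = 4)
  K <- length(schema$tags)
  withr::with_seed(seed, {
    params$trans <- matrix(stats::rnorm(K * K), K, K,
                           dimnames = list(schema$tags, schema$tags))
    params$start <- stats::setNames(stats::rnorm(K), schema$tags)
    params$end <- stats::setNames(stats::rnorm(K), schema$tags)
  })
  params
}

# random legal IOB2 tag sequence
random_legal_tags <- function(len, schema) {
  tags <- character(len)
  prev <- "O"
  for (i in seq_len(len)) {
    opts <- c("O", paste0("B-", schema$entity_labels))
    if (startsWith(prev, "B-") || startsWith(prev, "I-")) {
      opts <- c(opts, paste0("I-", tag_entity_test(prev)))
    }
    tags[i] <- sample(opts, 1)
    prev <- tags[i]
  }
  tags
}

tag_entity_test <- function(tag) sub("^[BI]-", "", tag)

micro_f1 <- function(seqs, params, provider, schema) {
  gold <- list(); pred <- list()
  for (i in seq_along(seqs)) {
    p <- predict_tags(seqs[[i]]$tokens, params, provider)
    gold[[i]] <- iob_to_chunks(seqs[[i]]$tokens, seqs[[i]]$tags, schema)
    pred[[i]] <- iob_to_chunks(p$tokens, p$tags, schema)
  }
  entity_prf(gold, pred)$micro
}
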