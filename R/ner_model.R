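# Hybrid tagger architecture: per-token input is the concatenation of
# a word embedding (from a pluggable provider) and character-level CNN
# features; a bidirectional LSTM encodes context; a linear projection
# yields per-tag emission scores consumed by the linear-chain CRF.
#
# The character inventory is printable ASCII plus a shared UNK row.

NER_CHARSET <- intToUtf8(32:126, multiple = TRUE)

#' @noRd
char_indices <- function(word) {
  codes <- utf8ToInt(word)
  idx <- match(codes, 32:126)
  idx[is.na(idx)] <- length(NER_CHARSET) + 1L  # UNK row
  idx
}

#' Hyperparameters for the NER tagger
#'
#' @param char_dim Character embedding size (default 16).
#' @param char_filters Number of convolution filters (default 16).
#' @param char_window Convolution width, odd (default 3).
#' @param hidden_dim LSTM hidden size per direction (default 32).
#' @param dropout Dropout rate on the concatenated token feature,
#'   training only (default 0).
#' @param learning_rate Step size (default 0.05).
#' @param epochs Training epochs (default 30).
#' @param batch_size Mini-batch size (default 8).
#' @param optimizer `"sgd"` (plain mini-batch gradient descent) or
#'   `"adam"`.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param constrain_transitions Hard-forbid illegal IOB2 transitions
#'   (default TRUE), so decoded paths are always legal.
#' @return A list of class `nmu_ner_config`.
#' @export
ner_config <- function(char_dim = 16, char_filters = 16, char_window = 3,
                       hidden_dim = 32, dropout = 0, learning_rate = 0.05,
                       epochs = 30, batch_size = 8, optimizer = "sgd",
                       seed = 1, constrain_transitions = TRUE) {
  if (char_window %% 2 != 1) {
    stop_nmu("char_window must be odd", class = "nmutext_config_error")
  }
  if (min(char_dim, char_filters, hidden_dim) < 1) {
    stop_nmu("all dimensions must be >= 1", class = "nmutext_config_error")
  }
  if (dropout < 0 || dropout >= 1) {
    stop_nmu("dropout must be in [0, 1)", class = "nmutext_config_error")
  }
  structure(
    list(char_dim = as.integer(char_dim),
         char_filters = as.integer(char_filters),
         char_window = as.integer(char_window),
         hidden_dim = as.integer(hidden_dim),
         dropout = dropout, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         optimizer = match.arg(optimizer, c("sgd", "adam")),
         seed = as.integer(seed),
         constrain_transitions = isTRUE(constrain_transitions)),
    class = "nmu_ner_config"
  )
}

#' @noRd
glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Initialize tagger parameters
#'
#' All trainable tensors, seeded from `config$seed`: character
#' embedding table, convolution kernel, forward/backward LSTM weights,
#' emission projection, and the CRF tag-transition matrix with start
#' and end scores (zero-initialized).  With
#' `config$constrain_transitions`, transitions violating IOB2 (`O ->
#' I-X`; `B-X`/`I-X -> I-Y`, Y != X; starting at `I-X`) hold `-Inf`
#' sentinels that training never touches.
#'
#' @param schema An `nmu_tag_schema`.
#' @param config An `nmu_ner_config`.
#' @param word_dim Dimension of the word-embedding provider.
#' @return A list of class `nmu_ner_params`.
#' @export
init_ner_params <- function(schema, config, word_dim) {
  K <- length(schema$tags)
  h <- config$hidden_dim
  d_in <- word_dim + config$char_filters
  n_chars <- length(NER_CHARSET) + 1L
  params <- with_local_seed(config$seed, {
    lstm_block <- function() {
      list(W = glorot(4 * h, d_in), U = glorot(4 * h, h),
           b = c(rep(0, h), rep(1, h), rep(0, 2 * h)))  # forget bias 1
    }
    list(
      char_embed = matrix(stats::runif(n_chars * config$char_dim, -0.1, 0.1),
                          n_chars, config$char_dim),
      conv_W = glorot(config$char_filters,
                      config$char_window * config$char_dim),
      conv_b = rep(0, config$char_filters),
      lstm_f = lstm_block(),
      lstm_b = lstm_block(),
      proj_W = glorot(2 * h, K),
      proj_b = rep(0, K),
      trans = matrix(0, K, K, dimnames = list(schema$tags, schema$tags)),
      start = stats::setNames(rep(0, K), schema$tags),
      end = stats::setNames(rep(0, K), schema$tags)
    )
  })
  # forbidden-transition masks (TRUE = forbidden)
  trans_mask <- matrix(FALSE, K, K, dimnames = dimnames(params$trans))
  start_mask <- rep(FALSE, K)
  for (j in seq_len(K)) {
    tj <- schema$tags[j]
    if (startsWith(tj, "I-")) {
      ent <- sub("^I-", "", tj)
      legal_prev <- paste0(c("B-", "I-"), ent)
      trans_mask[!(schema$tags %in% legal_prev), j] <- TRUE
      start_mask[j] <- TRUE
    }
  }
  if (config$constrain_transitions) {
    params$trans[trans_mask] <- -Inf
    params$start[start_mask] <- -Inf
  }
  params$schema <- schema
  params$config <- config
  params$word_dim <- as.integer(word_dim)
  params$trans_mask <- trans_mask
  params$start_mask <- start_mask
  class(params) <- "nmu_ner_params"
  params
}

#' Character-level CNN features for one word
#'
#' Embeds each character, zero-pads by `(char_window - 1) / 2` on both
#' sides, applies a width-`char_window` 1-D convolution with tanh
#' nonlinearity, and max-pools over positions, yielding one value per
#' filter.  Robust to misspellings because sub-word windows are shared
#' across surface forms.
#'
#' @param word Non-empty string.
#' @param params An `nmu_ner_params`.
#' @return Numeric vector of length `char_filters`.
#' @export
char_cnn_features <- function(word, params) {
  char_cnn_forward(word, params)$pool
}

# Full forward pass with cached intermediates for backprop.
#' @noRd
char_cnn_forward <- function(word, params) {
  if (!nzchar(word)) {
    stop_nmu("cannot featurize an empty word", class = "nmutext_contract_error")
  }
  cfg <- params$config
  idx <- char_indices(word)
  L <- length(idx)
  p <- (cfg$char_window - 1L) / 2L
  # padded embedding matrix, (L + 2p) x char_dim; pad rows are zero
  M <- rbind(matrix(0, p, cfg$char_dim),
             params$char_embed[idx, , drop = FALSE],
             matrix(0, p, cfg$char_dim))
  Xwin <- matrix(0, cfg$char_window * cfg$char_dim, L)
  for (t in seq_len(L)) {
    Xwin[, t] <- as.vector(t(M[t:(t + cfg$char_window - 1L), , drop = FALSE]))
  }
  Z <- params$conv_W %*% Xwin + params$conv_b
  A <- tanh(Z)
  amax <- max.col(A, ties.method = "first")  # per-filter argmax position
  pool <- A[cbind(seq_len(cfg$char_filters), amax)]
  list(idx = idx, Xwin = Xwin, A = A, amax = amax, pool = pool)
}

# One-direction LSTM over x (d_in x T); returns gate activations and
# states, each (h x T).  Gate row order in W/U/b: input, forget,
# output, candidate.
#' @noRd
lstm_run <- function(x, block, h_dim) {
  T_len <- ncol(x)
  Wx <- block$W %*% x + block$b
  gi <- matrix(0, h_dim, T_len); gf <- gi; go <- gi; gg <- gi
  cs <- gi; hs <- gi
  h_prev <- rep(0, h_dim); c_prev <- rep(0, h_dim)
  sl <- function(k) ((k - 1) * h_dim + 1):(k * h_dim)
  for (t in seq_len(T_len)) {
    z <- Wx[, t] + block$U %*% h_prev
    i_t <- 1 / (1 + exp(-z[sl(1)]))
    f_t <- 1 / (1 + exp(-z[sl(2)]))
    o_t <- 1 / (1 + exp(-z[sl(3)]))
    g_t <- tanh(z[sl(4)])
    c_t <- f_t * c_prev + i_t * g_t
    h_t <- o_t * tanh(c_t)
    gi[, t] <- i_t; gf[, t] <- f_t; go[, t] <- o_t; gg[, t] <- g_t
    cs[, t] <- c_t; hs[, t] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(i = gi, f = gf, o = go, g = gg, c = cs, h = hs)
}

# Full encoder forward pass with caches.  dropout_mask, if given, is a
# (d_in x T) multiplicative mask applied to the concatenated inputs.
#' @noRd
ner_forward <- function(tokens, params, provider, dropout_mask = NULL) {
  if (length(tokens) == 0) {
    stop_nmu("token list must be non-empty", class = "nmutext_contract_error")
  }
  if (provider$dim != params$word_dim) {
    stop_nmu("provider dim (", provider$dim, ") does not match model (",
             params$word_dim, ")", class = "nmutext_config_error")
  }
  cfg <- params$config
  T_len <- length(tokens)
  word_emb <- provider$embed_tokens(tokens)        # T x word_dim
  char_caches <- lapply(tokens, char_cnn_forward, params = params)
  char_feat <- vapply(char_caches, `[[`, numeric(cfg$char_filters), "pool")
  char_feat <- matrix(char_feat, nrow = cfg$char_filters)
  x <- rbind(t(word_emb), char_feat)               # d_in x T
  if (!is.null(dropout_mask)) x <- x * dropout_mask
  fwd <- lstm_run(x, params$lstm_f, cfg$hidden_dim)
  x_rev <- x[, rev(seq_len(T_len)), drop = FALSE]
  bwd <- lstm_run(x_rev, params$lstm_b, cfg$hidden_dim)
  H <- cbind(t(fwd$h), t(bwd$h)[rev(seq_len(T_len)), , drop = FALSE])
  E <- H %*% params$proj_W +
    matrix(params$proj_b, T_len, length(params$proj_b), byrow = TRUE)
  colnames(E) <- params$schema$tags
  list(tokens = tokens, word_emb = word_emb, char_caches = char_caches,
       x = x, x_rev = x_rev, dropout_mask = dropout_mask,
       fwd = fwd, bwd = bwd, H = H, E = E)
}

#' Emission score matrix for a token sequence
#'
#' Runs the character CNN, the bidirectional LSTM and the linear
#' projection, returning one row of per-tag scores per token.
#'
#' @param tokens Non-empty character vector.
#' @param params An `nmu_ner_params`.
#' @param provider An `nmu_embedding_provider` matching
#'   `params$word_dim`.
#' @return Numeric matrix (length(tokens) x |tags|), tag names as
#'   column names.
#' @export
emissions <- function(tokens, params, provider) {
  ner_forward(tokens, params, provider)$E
}
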