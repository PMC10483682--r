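# Exact gradients of the CRF negative log-likelihood through the whole
# encoder (CRF marginals -> projection -> BiLSTM BPTT -> char-CNN ->
# character embeddings), plus the training loop, prediction, and
# CoNLL / model serialization.

#' @noRd
zero_like <- function(params) {
  list(
    char_embed = params$char_embed * 0,
    conv_W = params$conv_W * 0, conv_b = params$conv_b * 0,
    lstm_f = lapply(params$lstm_f, function(m) m * 0),
    lstm_b = lapply(params$lstm_b, function(m) m * 0),
    proj_W = params$proj_W * 0, proj_b = params$proj_b * 0,
    trans = params$trans * 0, start = params$start * 0,
    end = params$end * 0
  )
}

# BPTT through one LSTM direction.  x: d_in x T inputs as fed to the
# cell; st: cached states from lstm_run; dh_ext: h x T gradients
# arriving at the hidden outputs.  Returns weight grads and dx.
#' @noRd
lstm_backward <- function(x, st, block, dh_ext) {
  h_dim <- nrow(st$h); T_len <- ncol(st$h)
  dW <- block$W * 0; dU <- block$U * 0; db <- block$b * 0
  dx <- x * 0
  dh_next <- rep(0, h_dim); dc_next <- rep(0, h_dim)
  for (t in rev(seq_len(T_len))) {
    dh <- dh_ext[, t] + dh_next
    tc <- tanh(st$c[, t])
    do_ <- dh * tc
    dc <- dh * st$o[, t] * (1 - tc^2) + dc_next
    c_prev <- if (t > 1) st$c[, t - 1] else rep(0, h_dim)
    h_prev <- if (t > 1) st$h[, t - 1] else rep(0, h_dim)
    di <- dc * st$g[, t]
    df <- dc * c_prev
    dg <- dc * st$i[, t]
    dz <- c(di * st$i[, t] * (1 - st$i[, t]),
            df * st$f[, t] * (1 - st$f[, t]),
            do_ * st$o[, t] * (1 - st$o[, t]),
            dg * (1 - st$g[, t]^2))
    dW <- dW + tcrossprod(dz, x[, t])
    dU <- dU + tcrossprod(dz, h_prev)
    db <- db + dz
    dx[, t] <- dx[, t] + as.vector(crossprod(block$W, dz))
    dh_next <- as.vector(crossprod(block$U, dz))
    dc_next <- dc * st$f[, t]
  }
  list(dW = dW, dU = dU, db = db, dx = dx)
}

# Gradient routing through one word's char-CNN cache: max-pool argmax
# -> tanh -> kernel -> character embedding rows (pad rows dropped).
#' @noRd
char_cnn_backward <- function(cache, dpool, params, grads) {
  cfg <- params$config
  Fn <- cfg$char_filters
  L <- length(cache$idx)
  p <- (cfg$char_window - 1L) / 2L
  sel <- cbind(seq_len(Fn), cache$amax)
  dZ <- matrix(0, Fn, L)
  dZ[sel] <- dpool * (1 - cache$A[sel]^2)
  grads$conv_W <- grads$conv_W + dZ %*% t(cache$Xwin)
  grads$conv_b <- grads$conv_b + rowSums(dZ)
  dXwin <- crossprod(params$conv_W, dZ)  # (window * char_dim) x L
  for (t in seq_len(L)) {
    for (o in seq_len(cfg$char_window)) {
      r <- t + o - 1L - p  # character position feeding window slot o
      if (r >= 1L && r <= L) {
        rows <- ((o - 1L) * cfg$char_dim + 1L):(o * cfg$char_dim)
        grads$char_embed[cache$idx[r], ] <-
          grads$char_embed[cache$idx[r], ] + dXwin[rows, t]
      }
    }
  }
  grads
}

# Loss and full parameter gradient for one labelled sequence.
#' @noRd
ner_seq_grad <- function(cache, tags, params) {
  schema <- params$schema
  cfg <- params$config
  y <- tags_to_idx(tags, schema)
  T_len <- length(y)
  E <- cache$E
  gold_score <- crf_score(E, params, tags)
  if (!is.finite(gold_score)) {
    stop_nmu("gold path impossible under constrained transitions",
             class = "nmutext_contract_error")
  }
  marg <- crf_marginals(E, params)
  loss <- marg$logZ - gold_score

  grads <- zero_like(params)
  dE <- marg$node
  dE[cbind(seq_len(T_len), y)] <- dE[cbind(seq_len(T_len), y)] - 1
  dTrans <- marg$pair
  if (T_len > 1) {
    for (t in 2:T_len) {
      dTrans[y[t - 1], y[t]] <- dTrans[y[t - 1], y[t]] - 1
    }
  }
  dTrans[params$trans_mask & cfg$constrain_transitions] <- 0
  grads$trans <- dTrans
  ds <- marg$node[1, ]; ds[y[1]] <- ds[y[1]] - 1
  de <- marg$node[T_len, ]; de[y[T_len]] <- de[y[T_len]] - 1
  grads$start <- ds
  grads$end <- de

  grads$proj_W <- crossprod(cache$H, dE)
  grads$proj_b <- colSums(dE)
  dH <- dE %*% t(params$proj_W)  # T x 2h
  h <- cfg$hidden_dim
  dh_f <- t(dH[, 1:h, drop = FALSE])
  dh_b <- t(dH[rev(seq_len(T_len)), (h + 1):(2 * h), drop = FALSE])

  bf <- lstm_backward(cache$x, cache$fwd, params$lstm_f, dh_f)
  bb <- lstm_backward(cache$x_rev, cache$bwd, params$lstm_b, dh_b)
  grads$lstm_f <- list(W = bf$dW, U = bf$dU, b = bf$db)
  grads$lstm_b <- list(W = bb$dW, U = bb$dU, b = bb$db)
  dx <- bf$dx + bb$dx[, rev(seq_len(T_len)), drop = FALSE]
  if (!is.null(cache$dropout_mask)) dx <- dx * cache$dropout_mask

  dchar <- dx[(params$word_dim + 1):nrow(dx), , drop = FALSE]
  for (t in seq_len(T_len)) {
    grads <- char_cnn_backward(cache$char_caches[[t]], dchar[, t],
                               params, grads)
  }
  list(loss = loss, grads = grads)
}

#' Loss and averaged gradients of [crf_nll()] over a batch
#'
#' Runs the full forward pass per sequence, then exact backpropagation:
#' CRF forward-backward marginals drive the emission/transition
#' gradients, which flow through the projection, both LSTM directions,
#' the max-pooled character convolution, and into the character
#' embedding table.  Word embeddings come from the (fixed) provider
#' and receive no gradient.
#'
#' @param params An `nmu_ner_params`.
#' @param batch List of elements with `tokens` and `tags`.
#' @param provider Embedding provider.
#' @param dropout_masks Optional list of per-sequence multiplicative
#'   input masks (training use only).
#' @return List with `nll` (mean loss) and `grads` (mean gradients,
#'   shaped like the parameters).
#' @export
ner_nll_grad <- function(params, batch, provider, dropout_masks = NULL) {
  total <- zero_like(params)
  nll <- 0
  for (b in seq_along(batch)) {
    mask <- if (is.null(dropout_masks)) NULL else dropout_masks[[b]]
    cache <- ner_forward(batch[[b]]$tokens, params, provider, mask)
    res <- ner_seq_grad(cache, batch[[b]]$tags, params)
    nll <- nll + res$loss
    total <- add_grads(total, res$grads)
  }
  n <- length(batch)
  list(nll = nll / n, grads = scale_grads(total, 1 / n))
}

#' @noRd
add_grads <- function(a, b) {
  for (nm in c("char_embed", "conv_W", "conv_b", "proj_W", "proj_b",
               "trans", "start", "end")) {
    a[[nm]] <- a[[nm]] + b[[nm]]
  }
  for (dir in c("lstm_f", "lstm_b")) {
    for (nm in c("W", "U", "b")) a[[dir]][[nm]] <- a[[dir]][[nm]] + b[[dir]][[nm]]
  }
  a
}

#' @noRd
scale_grads <- function(g, s) {
  rapply(g, function(m) m * s, classes = c("numeric", "matrix"),
         how = "replace")
}

# --- flat parameter vector view (used by the optimizer and the
# finite-difference gradient check) ------------------------------------

#' @noRd
free_slots <- function(params) {
  constrained <- params$config$constrain_transitions
  list(
    trans_free = if (constrained) !params$trans_mask else
      matrix(TRUE, nrow(params$trans), ncol(params$trans)),
    start_free = if (constrained) !params$start_mask else
      rep(TRUE, length(params$start))
  )
}

#' Flatten all free (trainable) parameters to a numeric vector
#'
#' `-Inf` transition sentinels are excluded, so the vector is always
#' finite; [ner_unflatten()] is the inverse.
#'
#' @param params An `nmu_ner_params`.
#' @return Numeric vector.
#' @export
ner_flatten <- function(params) {
  fs <- free_slots(params)
  c(as.vector(params$char_embed), as.vector(params$conv_W), params$conv_b,
    as.vector(params$lstm_f$W), as.vector(params$lstm_f$U), params$lstm_f$b,
    as.vector(params$lstm_b$W), as.vector(params$lstm_b$U), params$lstm_b$b,
    as.vector(params$proj_W), params$proj_b,
    params$trans[fs$trans_free], params$start[fs$start_free],
    unname(params$end))
}

#' Rebuild parameters from a flat vector
#'
#' @param params Template `nmu_ner_params` (shapes and masks).
#' @param theta Numeric vector from [ner_flatten()].
#' @return Updated `nmu_ner_params`.
#' @export
ner_unflatten <- function(params, theta) {
  fs <- free_slots(params)
  take <- function(n) {
    out <- theta[seq_len(n)]
    theta <<- theta[-seq_len(n)]
    out
  }
  shape <- function(m) matrix(take(length(m)), nrow(m), ncol(m))
  params$char_embed <- shape(params$char_embed)
  params$conv_W <- shape(params$conv_W)
  params$conv_b <- take(length(params$conv_b))
  for (dir in c("lstm_f", "lstm_b")) {
    params[[dir]]$W <- shape(params[[dir]]$W)
    params[[dir]]$U <- shape(params[[dir]]$U)
    params[[dir]]$b <- take(length(params[[dir]]$b))
  }
  params$proj_W <- shape(params$proj_W)
  params$proj_b <- take(length(params$proj_b))
  params$trans[fs$trans_free] <- take(sum(fs$trans_free))
  params$start[fs$start_free] <- take(sum(fs$start_free))
  params$end[] <- take(length(params$end))
  stopifnot(length(theta) == 0)
  params
}

#' @noRd
ner_flatten_grads <- function(grads, params) {
  fs <- free_slots(params)
  c(as.vector(grads$char_embed), as.vector(grads$conv_W), grads$conv_b,
    as.vector(grads$lstm_f$W), as.vector(grads$lstm_f$U), grads$lstm_f$b,
    as.vector(grads$lstm_b$W), as.vector(grads$lstm_b$U), grads$lstm_b$b,
    as.vector(grads$proj_W), grads$proj_b,
    grads$trans[fs$trans_free], grads$start[fs$start_free],
    unname(grads$end))
}

# --- training ---------------------------------------------------------

#' Train the tagger by gradient descent on the CRF likelihood
#'
#' Seeded initialization, per-epoch shuffling, mini-batches, and either
#' plain gradient descent or Adam on the flat parameter vector.
#' Deterministic for a given seed: identical data and config reproduce
#' the epoch-loss trace bit for bit.  `epochs = 0` returns the
#' initialization untouched.
#'
#' @param corpus List of labelled sequences, each with `tokens` and
#'   `tags` (legal IOB2 over the schema).
#' @param schema An `nmu_tag_schema`.
#' @param config An `nmu_ner_config`.
#' @param provider An `nmu_embedding_provider`.
#' @return List with `params` (trained `nmu_ner_params`) and `report`
#'   (class `nmu_train_report`: per-epoch mean NLL and the config).
#' @export
train_ner <- function(corpus, schema, config, provider) {
  if (length(corpus) < 10 && config$epochs > 0) {
    stop_nmu("need at least 10 training sequences",
             class = "nmutext_contract_error")
  }
  for (s in corpus) check_tags_known(s$tags, schema)
  params <- init_ner_params(schema, config, provider$dim)
  epoch_nll <- numeric(0)
  if (config$epochs > 0) {
    theta <- ner_flatten(params)
    adam_m <- theta * 0; adam_v <- theta * 0; adam_t <- 0
    d_in <- params$word_dim + config$char_filters
    with_local_seed(config$seed, {
      for (ep in seq_len(config$epochs)) {
        order <- sample(length(corpus))
        ep_loss <- 0
        for (b0 in seq(1, length(order), by = config$batch_size)) {
          idx <- order[b0:min(b0 + config$batch_size - 1, length(order))]
          batch <- corpus[idx]
          masks <- NULL
          if (config$dropout > 0) {
            masks <- lapply(batch, function(s) {
              T_len <- length(s$tokens)
              keep <- matrix(stats::runif(d_in * T_len) >= config$dropout,
                             d_in, T_len)
              keep / (1 - config$dropout)
            })
          }
          res <- ner_nll_grad(params, batch, provider, masks)
          if (!is.finite(res$nll)) {
            stop_nmu("non-finite loss at epoch ", ep,
                     class = "nmutext_training_error")
          }
          ep_loss <- ep_loss + res$nll * length(idx)
          g <- ner_flatten_grads(res$grads, params)
          if (config$optimizer == "adam") {
            adam_t <- adam_t + 1
            adam_m <- 0.9 * adam_m + 0.1 * g
            adam_v <- 0.999 * adam_v + 0.001 * g^2
            mhat <- adam_m / (1 - 0.9^adam_t)
            vhat <- adam_v / (1 - 0.999^adam_t)
            theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
          } else {
            theta <- theta - config$learning_rate * g
          }
          params <- ner_unflatten(params, theta)
        }
        epoch_nll <- c(epoch_nll, ep_loss / length(corpus))
      }
    })
  }
  report <- structure(
    list(epoch_nll = epoch_nll, n_train = length(corpus), config = config),
    class = "nmu_train_report"
  )
  list(params = params, report = report)
}

#' Tag a token sequence
#'
#' Emissions followed by Viterbi decoding; with constrained
#' transitions (the default) the output is always IOB2-legal, so
#' `repair_iob()` is a no-op on it.
#'
#' @param tokens Non-empty character vector.
#' @param params A trained `nmu_ner_params`.
#' @param provider The embedding provider used in training.
#' @return List with `tokens` and `tags`.
#' @export
predict_tags <- function(tokens, params, provider) {
  E <- emissions(tokens, params, provider)
  dec <- viterbi_decode(E, params)
  list(tokens = tokens, tags = dec$path)
}

# --- CoNLL and model serialization ------------------------------------

#' Read labelled sequences in CoNLL column format
#'
#' One `token<SPACE>tag` pair per line, blank line between sentences.
#'
#' @param path Input path.
#' @return List of labelled sequences (`tokens`, `tags`).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  seqs <- list(); toks <- character(); tags <- character()
  flush <- function() {
    if (length(toks) > 0) seqs[[length(seqs) + 1]] <<- list(tokens = toks,
                                                            tags = tags)
    toks <<- character(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush()
    } else {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) < 2) {
        stop_nmu("malformed CoNLL line: ", ln, class = "nmutext_parse_error")
      }
      toks <- c(toks, parts[1])
      tags <- c(tags, parts[length(parts)])
    }
  }
  flush()
  seqs
}

#' Write labelled sequences in CoNLL column format
#'
#' @param seqs List of labelled sequences (`tokens`, `tags`).
#' @param path Output path.
#' @export
write_conll <- function(seqs, path) {
  out <- unlist(lapply(seqs, function(s) {
    c(paste(s$tokens, s$tags), "")
  }))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Serialize trained parameters to structured text (JSON)
#'
#' Schema and config travel with the weights; `-Inf` transition
#' sentinels are reconstructed from the schema on load.
#'
#' @param params An `nmu_ner_params`.
#' @param path Output path.
#' @export
write_ner_model <- function(params, path) {
  trans <- params$trans
  trans[!is.finite(trans)] <- 0  # sentinels live in the mask
  obj <- list(
    entity_labels = params$schema$entity_labels,
    config = unclass(params$config),
    word_dim = params$word_dim,
    char_embed = params$char_embed, conv_W = params$conv_W,
    conv_b = params$conv_b,
    lstm_f = params$lstm_f, lstm_b = params$lstm_b,
    proj_W = params$proj_W, proj_b = params$proj_b,
    trans = trans, start = ifelse(is.finite(params$start), params$start, 0),
    end = params$end
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load parameters written by [write_ner_model()]
#'
#' @param path Input path.
#' @return An `nmu_ner_params`.
#' @export
read_ner_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- tag_schema(obj$entity_labels)
  config <- do.call(ner_config, obj$config[setdiff(names(obj$config), NULL)])
  params <- init_ner_params(schema, config, obj$word_dim)
  as_mat <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  params$char_embed <- as_mat(obj$char_embed)
  params$conv_W <- as_mat(obj$conv_W)
  params$conv_b <- as.numeric(obj$conv_b)
  for (dir in c("lstm_f", "lstm_b")) {
    params[[dir]]$W <- as_mat(obj[[dir]]$W)
    params[[dir]]$U <- as_mat(obj[[dir]]$U)
    params[[dir]]$b <- as.numeric(obj[[dir]]$b)
  }
  params$proj_W <- as_mat(obj$proj_W)
  params$proj_b <- as.numeric(obj$proj_b)
  trans <- as_mat(obj$trans)
  dimnames(trans) <- list(schema$tags, schema$tags)
  start <- stats::setNames(as.numeric(obj$start), schema$tags)
  if (config$constrain_transitions) {
    trans[params$trans_mask] <- -Inf
    start[params$start_mask] <- -Inf
  }
  params$trans <- trans
  params$start <- start
  params$end <- stats::setNames(as.numeric(obj$end), schema$tags)
  params
}
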