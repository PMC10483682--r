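# Encoder shape/symmetry contracts, training behaviour, prediction
# legality, and model/CoNLL serialization.

test_that("char CNN features have the filter dimension for any word", {
  params <- init_ner_params(tiny_schema(), tiny_config(), word_dim = 4)
  expect_length(char_cnn_features("x", params), 2)
  expect_length(char_cnn_features("methamphetamine", params), 2)
  # all-zero kernel: tanh(0) = 0 per filter
  z <- params; z$conv_W[] <- 0; z$conv_b[] <- 0
  expect_equal(char_cnn_features("xanax", z), c(0, 0))
  expect_error(char_cnn_features("", params),
               class = "nmutext_contract_error")
})

test_that("char CNN equals a naive window-dot-product-and-max oracle", {
  params <- init_ner_params(tiny_schema(), tiny_config(), word_dim = 4)
  cfg <- params$config
  word <- "adderal"
  codes <- utf8ToInt(word)
  rows <- match(codes, 32:126)
  emb <- params$char_embed[rows, , drop = FALSE]
  pad <- matrix(0, 1, cfg$char_dim)
  M <- rbind(pad, emb, pad)  # window 3 -> one pad row each side
  naive <- rep(-Inf, cfg$char_filters)
  for (t in seq_len(nchar(word))) {
    win <- as.vector(t(M[t:(t + 2), ]))
    a <- tanh(params$conv_W %*% win + params$conv_b)
    naive <- pmax(naive, as.vector(a))
  }
  expect_equal(char_cnn_features(word, params), naive, tolerance = 1e-12)
})

test_that("emissions have the (seq_len x |tags|) shape and linear zero case", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  params <- init_ner_params(schema, tiny_config(), word_dim = 4)
  E <- emissions(c("a", "b", "c"), params, prov)
  expect_equal(dim(E), c(3, 3))
  z <- params
  z$proj_W[] <- 0; z$proj_b[] <- 0
  expect_equal(unname(emissions(c("a", "b"), z, prov)), matrix(0, 2, 3))
  expect_error(emissions(c("a"), params, hash_provider(dim = 9, seed = 1)),
               class = "nmutext_config_error")
})

test_that("reversing tokens and swapping direction blocks reverses emissions", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 2)
  params <- init_ner_params(schema, tiny_config(seed = 3), word_dim = 4)
  toks <- c("took", "two", "xanax", "bars")
  E <- emissions(toks, params, prov)
  swapped <- params
  swapped$lstm_f <- params$lstm_b
  swapped$lstm_b <- params$lstm_f
  h <- params$config$hidden_dim
  swapped$proj_W <- rbind(params$proj_W[(h + 1):(2 * h), , drop = FALSE],
                          params$proj_W[1:h, , drop = FALSE])
  E_rev <- emissions(rev(toks), swapped, prov)
  expect_equal(E_rev, E[rev(seq_len(nrow(E))), ], tolerance = 1e-12)
})

test_that("zero epochs returns the seeded initialization unchanged", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  seqs <- replicate(12, list(tokens = c("a", "b"), tags = c("O", "O")),
                    simplify = FALSE)
  fit <- train_ner(seqs, schema, tiny_config(epochs = 0), prov)
  expect_equal(ner_flatten(fit$params),
               ner_flatten(init_ner_params(schema, tiny_config(epochs = 0),
                                           4)))
  expect_length(fit$report$epoch_nll, 0)
})

test_that("training is bit-deterministic per seed", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  withr::with_seed(31, {
    seqs <- lapply(1:12, function(i) {
      len <- sample(2:5, 1)
      list(tokens = sample(c("aa", "bb", "cc"), len, replace = TRUE),
           tags = random_legal_tags(len, schema))
    })
  })
  cfg <- tiny_config(epochs = 2, dropout = 0.2)
  f1 <- train_ner(seqs, schema, cfg, prov)
  f2 <- train_ner(seqs, schema, cfg, prov)
  expect_identical(f1$report$epoch_nll, f2$report$epoch_nll)
  expect_identical(ner_flatten(f1$params), ner_flatten(f2$params))
  expect_gt(length(f1$report$epoch_nll), 0)
})

test_that("a model trained on all-O data predicts all O", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  withr::with_seed(17, {
    seqs <- lapply(1:20, function(i) {
      len <- sample(3:6, 1)
      list(tokens = sample(c("la", "di", "da"), len, replace = TRUE),
           tags = rep("O", len))
    })
  })
  fit <- train_ner(seqs, schema, tiny_config(epochs = 5), prov)
  pred <- predict_tags(c("la", "di", "da", "la"), fit$params, prov)
  expect_equal(pred$tags, rep("O", 4))
})

test_that("constrained predictions are always IOB2-legal", {
  schema <- tag_schema(c("DRUG", "ADE"))
  prov <- hash_provider(dim = 6, seed = 2)
  params <- init_ner_params(schema, tiny_config(), word_dim = 6)
  withr::with_seed(41, {
    for (i in 1:20) {
      toks <- sample(c("xanax", "fent", "blah", "nausea", "zz9"),
                     sample(1:8, 1), replace = TRUE)
      pred <- predict_tags(toks, params, prov)
      expect_true(is_iob_legal(pred$tags, schema))
      expect_identical(repair_iob(pred$tags, schema), pred$tags)
    }
  })
})

test_that("CoNLL files and model JSON round-trip", {
  seqs <- list(list(tokens = c("took", "xanax"), tags = c("O", "B-DRUG")),
               list(tokens = c("ok"), tags = c("O")))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(seqs, path)
  expect_equal(read_conll(path), seqs)

  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  params <- init_ner_params(schema, tiny_config(), word_dim = 4)
  mpath <- withr::local_tempfile(fileext = ".json")
  write_ner_model(params, mpath)
  back <- read_ner_model(mpath)
  expect_equal(ner_flatten(back), ner_flatten(params), tolerance = 1e-12)
  toks <- c("took", "xanax", "bars")
  expect_equal(emissions(toks, back, prov), emissions(toks, params, prov),
               tolerance = 1e-10)
})
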