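# CRF correctness against brute-force path enumeration, plus the
# worked degenerate cases.

test_that("path score follows the additive emission/transition formula", {
  schema <- tiny_schema()
  params <- random_crf_params(schema, 1)
  E <- withr::with_seed(2, matrix(stats::rnorm(6), 2, 3))
  zero <- params
  zero$trans[] <- 0; zero$start[] <- 0; zero$end[] <- 0
  expect_equal(crf_score(E * 0, zero, c("O", "O")), 0)
  # single token: start + emission + end
  E1 <- E[1, , drop = FALSE]
  expect_equal(crf_score(E1, params, "B-DRUG"),
               params$start[["B-DRUG"]] + E1[1, 2] + params$end[["B-DRUG"]])
  expect_error(crf_score(E, params, "O"), class = "nmutext_contract_error")
})

test_that("path probabilities normalize: sum over enumeration equals 1", {
  schema <- tiny_schema()
  params <- random_crf_params(schema, 5)
  E <- withr::with_seed(6, matrix(stats::rnorm(12), 4, 3))
  logZ <- crf_log_partition(E, params)
  probs <- exp(enumerate_paths(E, params) - logZ)
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  expect_equal(length(probs), 3^4)
})

test_that("log-partition matches enumeration on random instances", {
  expect_equal(crf_log_partition(matrix(0, 3, 2),
                                 list(schema = list(tags = c("A", "B")),
                                      trans = matrix(0, 2, 2),
                                      start = rep(0, 2), end = rep(0, 2))),
               3 * log(2))
  sch <- tiny_schema()
  K <- length(sch$tags)
  withr::with_seed(11, {
    for (r in 1:50) {
      params <- random_crf_params(sch, seed = 100 + r)
      T_len <- sample(1:5, 1)
      E <- matrix(stats::rnorm(T_len * K, sd = 2), T_len, K)
      expect_equal(crf_log_partition(E, params), brute_logZ(E, params),
                   tolerance = 1e-8)
    }
  })
})

test_that("Viterbi returns an enumeration-verified argmax with legal output", {
  schema <- tiny_schema()
  withr::with_seed(12, {
    for (r in 1:100) {
      params <- random_crf_params(schema, seed = 200 + r)
      T_len <- sample(1:5, 1)
      E <- matrix(stats::rnorm(T_len * 3, sd = 2), T_len, 3)
      dec <- viterbi_decode(E, params)
      expect_equal(dec$score, brute_best(E, params), tolerance = 1e-10)
      expect_equal(crf_score(E, params, dec$path), dec$score)
      expect_lte(dec$score, crf_log_partition(E, params) + 1e-12)
    }
  })
  # zero transitions reduce to per-position argmax
  params <- random_crf_params(schema, 3)
  params$trans[] <- 0; params$start[] <- 0; params$end[] <- 0
  E <- withr::with_seed(4, matrix(stats::rnorm(15), 5, 3))
  expect_equal(viterbi_decode(E, params)$path,
               schema$tags[apply(E, 1, which.max)])
})

test_that("constrained decoding never starts inside an entity", {
  schema <- tiny_schema()
  params <- init_ner_params(schema, tiny_config(), word_dim = 4)
  E <- matrix(c(-5, -5, 10,    # I-DRUG strongly favored at position 1
                0, 0, 0), 2, 3, byrow = TRUE)
  dec <- viterbi_decode(E, params)
  expect_false(dec$path[1] == "I-DRUG")
  expect_true(is_iob_legal(dec$path, schema))
})

test_that("NLL is the mean excess of logZ over the gold score", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  params <- init_ner_params(schema, tiny_config(constrain_transitions = FALSE),
                            word_dim = 4)
  # uniform case: zero scores everywhere -> T * ln K
  zero <- params
  zero$char_embed[] <- 0; zero$conv_W[] <- 0; zero$conv_b[] <- 0
  zero$lstm_f <- lapply(zero$lstm_f, function(m) m * 0)
  zero$lstm_b <- lapply(zero$lstm_b, function(m) m * 0)
  zero$proj_W[] <- 0; zero$proj_b[] <- 0
  batch <- list(list(tokens = c("a", "b", "c", "d"),
                     tags = c("O", "B-DRUG", "I-DRUG", "O")))
  expect_equal(crf_nll(zero, batch, prov), 4 * log(3), tolerance = 1e-12)
  # random instance: matches -log of the enumerated path probability
  E <- withr::with_seed(9, matrix(stats::rnorm(9), 3, 3))
  p2 <- random_crf_params(schema, 77)
  gold <- c("O", "B-DRUG", "I-DRUG")
  direct <- crf_log_partition(E, p2) - crf_score(E, p2, gold)
  enum <- -log(exp(crf_score(E, p2, gold) - brute_logZ(E, p2)))
  expect_equal(direct, enum, tolerance = 1e-9)
  expect_gte(direct, 0)
  # impossible gold under constraints is a contract error
  pc <- init_ner_params(schema, tiny_config(), word_dim = 4)
  expect_error(
    crf_nll(pc, list(list(tokens = c("a"), tags = c("I-DRUG"))), prov),
    class = "nmutext_contract_error"
  )
})

test_that("analytic gradients match central finite differences", {
  schema <- tiny_schema()
  prov <- hash_provider(dim = 4, seed = 1)
  batch <- list(list(tokens = c("took", "xanax", "bars"),
                     tags = c("O", "B-DRUG", "I-DRUG")))
  for (constrained in c(FALSE, TRUE)) {
    params <- init_ner_params(
      schema, tiny_config(constrain_transitions = constrained), word_dim = 4
    )
    res <- ner_nll_grad(params, batch, prov)
    g_an <- nmutext:::ner_flatten_grads(res$grads, params)
    theta <- ner_flatten(params)
    h <- 1e-5
    g_fd <- vapply(seq_along(theta), function(j) {
      up <- theta; up[j] <- up[j] + h
      dn <- theta; dn[j] <- dn[j] - h
      (crf_nll(ner_unflatten(params, up), batch, prov) -
         crf_nll(ner_unflatten(params, dn), batch, prov)) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(g_fd), 1e-4)
    expect_lt(max(abs(g_an - g_fd) / denom), 1e-4)
  }
})
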