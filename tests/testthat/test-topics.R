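test_that("identity reduction returns the input; svd at full rank is isometric", {
  X <- withr::with_seed(1, matrix(stats::rnorm(80), 10, 8))
  expect_equal(reduce_dim(X, 8, method = "identity"), X)
  Y <- reduce_dim(X, 8, method = "svd")
  expect_equal(as.matrix(stats::dist(Y)), as.matrix(stats::dist(X)),
               tolerance = 1e-9)
  expect_error(reduce_dim(X, 9), class = "nmutext_config_error")
})

test_that("svd reduction captures low-rank structure with near-zero residual", {
  withr::with_seed(2, {
    basis <- matrix(stats::rnorm(20), 10, 2)  # embed a plane in 10-d
    centers <- matrix(stats::rnorm(6, sd = 5), 3, 2)
    scores <- centers[rep(1:3, each = 20), ] +
      matrix(stats::rnorm(120, sd = 0.01), 60, 2)
    X <- scores %*% t(basis)
  })
  Y <- reduce_dim(X, 2, method = "svd")
  # distances in the plane reproduce the full-space distances
  expect_equal(as.matrix(stats::dist(Y)), as.matrix(stats::dist(X)),
               tolerance = 1e-2)
  expect_identical(reduce_dim(X, 2), Y)  # deterministic incl. sign
})

test_that("single-linkage clustering separates planted blobs and flags outliers", {
  withr::with_seed(3, {
    blob1 <- matrix(stats::rnorm(60, mean = 0, sd = 0.1), 30, 2)
    blob2 <- matrix(stats::rnorm(60, mean = 10, sd = 0.1), 30, 2)
    lone <- matrix(c(50, 50), 1, 2)
    X <- rbind(blob1, blob2, lone)
  })
  lab <- cluster_docs(X, min_cluster_size = 3, distance_threshold = 1)
  expect_equal(sort(unique(lab)), c(-1L, 0L, 1L))
  expect_equal(lab[61], -1L)
  expect_length(unique(lab[1:30]), 1)
  expect_length(unique(lab[31:60]), 1)
  # clusters numbered by decreasing size, ties by first member: blob1 = 0
  expect_equal(lab[1], 0L)
  # duplicates always co-cluster
  Xd <- rbind(X, X[1, , drop = FALSE])
  labd <- cluster_docs(Xd, min_cluster_size = 3, distance_threshold = 1)
  expect_equal(labd[62], labd[1])
  expect_warning(cluster_docs(X[1:2, ], min_cluster_size = 5), "outlier")
})

toy_token_matrix <- function() {
  counts <- matrix(c(2, 0,
                     1, 0,
                     0, 3),
                   nrow = 2,
                   dimnames = list(c("d1", "d2"), c("drug", "pain", "sleep")))
  structure(list(record_ids = rownames(counts),
                 vocabulary = stats::setNames(1:3, colnames(counts)),
                 counts = counts),
            class = "nmu_token_matrix")
}

test_that("c-TF-IDF reproduces the hand-computed two-class example", {
  ct <- ctfidf(toy_token_matrix(), c(0, 1))
  expect_equal(ct$A, 3)
  expect_equal(ct$f[["drug"]], 2)
  expect_equal(ct$W["0", "drug"], 2 * log(1 + 3 / 2), tolerance = 1e-12)
  expect_equal(ct$W["0", "sleep"], 0)  # absent from class
  expect_true(all(ct$W >= 0))
  expect_identical(unname(ct$W == 0), unname(ct$tf == 0))
})

test_that("c-TF-IDF weights are non-negative and zero iff absent on random corpora", {
  withr::with_seed(5, {
    recs <- lapply(1:40, function(i) {
      list(record_id = paste0("r", i),
           tokens = sample(letters[1:10], sample(3:12, 1), replace = TRUE))
    })
    tm <- build_token_matrix(recs)
    labels <- sample(c(-1L, 0L, 1L, 2L), 40, replace = TRUE)
  })
  ct <- ctfidf(tm, labels)
  expect_true(all(ct$W >= 0))
  expect_identical(unname(ct$W == 0), unname(ct$tf == 0))
  # outliers excluded from the pooled counts
  expect_equal(sum(ct$tf),
               sum(tm$counts[labels >= 0, ]))
  expect_error(ctfidf(tm, rep(-1L, 40)), class = "nmutext_contract_error")
})

test_that("topic extraction ranks by weight with lexicographic ties", {
  ct <- ctfidf(toy_token_matrix(), c(0, 1))
  tops <- extract_topics(ct, top_n = 1)
  expect_equal(tops[[1]]$top_words$term, "drug")
  expect_equal(tops[[2]]$top_words$term, "sleep")
  all_terms <- extract_topics(ct, top_n = 99)[[1]]$top_words
  expect_equal(nrow(all_terms), 3)
  expect_true(all(diff(all_terms$weight) <= 0))
  # equal weights fall back to term order
  tie <- ct
  tie$W[1, ] <- c(1, 1, 0)
  expect_equal(extract_topics(tie, top_n = 2)[[1]]$top_words$term,
               c("drug", "pain"))
})

test_that("topics over time conserve per-step document counts", {
  withr::with_seed(6, {
    recs <- lapply(1:60, function(i) {
      list(record_id = paste0("r", i),
           tokens = sample(letters[1:6], 5, replace = TRUE))
    })
  })
  tm <- build_token_matrix(recs)
  labels <- rep(c(0L, 1L, -1L), 20)
  stamps <- rep(as.POSIXct(c("2021-06-05", "2021-06-20", "2021-07-03"),
                           tz = "UTC"), each = 20)
  tot <- topics_over_time(tm, labels, stamps)
  for (s in unique(tot$step)) {
    expect_equal(sum(tot$frequency[tot$step == s]),
                 sum(labels >= 0 &
                       format(stamps, "%Y-%m", tz = "UTC") == s))
  }
  expect_setequal(unique(tot$step), c("2021-06", "2021-07"))
  # single topic, single month degenerates to one row with frequency n
  tot1 <- topics_over_time(tm, rep(0L, 60),
                           rep(stamps[1], 60))
  expect_equal(nrow(tot1), 1)
  expect_equal(tot1$frequency, 60)
})

test_that("planted doubling of a topic shows as a frequency ratio of two", {
  withr::with_seed(7, {
    recs <- lapply(1:30, function(i) {
      list(record_id = paste0("r", i),
           tokens = sample(letters[1:6], 5, replace = TRUE))
    })
  })
  tm <- build_token_matrix(recs)
  labels <- rep(0L, 30)
  stamps <- as.POSIXct(c(rep("2021-06-10", 10), rep("2021-07-10", 20)),
                       tz = "UTC")
  tot <- topics_over_time(tm, labels, stamps)
  expect_equal(tot$frequency[tot$step == "2021-07"] /
                 tot$frequency[tot$step == "2021-06"], 2)
})

test_that("coherence hits its bounds and stays in [0, 1]", {
  topic <- list(list(topic_id = 0,
                     top_words = data.frame(term = c("a", "b", "c"),
                                            weight = 3:1), size = 1))
  same <- constant_provider(4)
  expect_equal(topic_coherence(topic, same, top_k = 3)$mean, 1)
  m2 <- diag(3)
  rownames(m2) <- c("a", "b", "c")  # pairwise orthogonal
  expect_equal(topic_coherence(topic, table_provider(m2), top_k = 3)$mean, 0)
  # random inputs stay bounded
  p <- hash_provider(dim = 8, seed = 9)
  withr::with_seed(10, {
    for (i in 1:10) {
      tp <- list(list(topic_id = i,
                      top_words = data.frame(
                        term = sample(letters, 5), weight = 5:1),
                      size = 1))
      coh <- topic_coherence(tp, p, top_k = 5)$mean
      expect_gte(coh, 0)
      expect_lte(coh, 1)
    }
  })
  # hand-computed three-word case
  tab <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  expected <- mean(pmax(c(1, 0, 0), 0))  # pairs ab, ac, bc
  expect_equal(topic_coherence(topic, table_provider(tab), top_k = 3)$mean,
               expected)
  # replacing a word vector with the centroid never lowers coherence
  tab2 <- rbind(a = c(1, 0), b = c(0.6, 0.8), c = c(0, 1))
  base <- topic_coherence(topic, table_provider(tab2), top_k = 3)$mean
  cen <- colMeans(tab2)
  tab3 <- tab2; tab3["c", ] <- cen
  expect_gte(topic_coherence(topic, table_provider(tab3), top_k = 3)$mean,
             base)
})

test_that("topic recovery on a separable synthetic corpus is near-perfect", {
  synth <- generate_topic_corpus(n_records = 300, seed = 13, noise_rate = 0)
  recs <- tokenize_corpus(synth$corpus)
  prov <- hash_provider(dim = 32, seed = 0)
  emb <- embed_corpus(prov, recs)
  red <- reduce_dim(emb, target_dim = 5)
  lab <- cluster_docs(red, min_cluster_size = 5, distance_threshold = 0.2)
  expect_gte(mclust::adjustedRandIndex(lab, synth$gold_topic), 0.9)
  tm <- build_token_matrix(recs)
  tops <- extract_topics(ctfidf(tm, lab), top_n = 3)
  vocabs <- lapply(default_topic_specs(), `[[`, "vocabulary")
  for (tp in tops) {
    members <- which(lab == tp$topic_id)
    planted <- as.integer(names(which.max(table(synth$gold_topic[members]))))
    expect_true(all(tp$top_words$term %in% vocabs[[planted + 1]]))
  }
})
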