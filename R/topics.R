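# Cluster-based topic modelling: reduce document embeddings, cluster,
# rank terms per cluster with class-based TF-IDF, track topic
# frequencies over time, and score topic coherence with embedding
# cosines.
#
# The deterministic defaults (centered truncated SVD; single-linkage
# agglomeration with a minimum-size outlier rule) make results
# reproducible bit for bit; stochastic manifold/density methods can be
# plugged in through the "external" escape hatches.

#' Reduce document embeddings
#'
#' The `svd` method centers the matrix and projects onto the top-k
#' right singular directions, with the sign of each direction fixed so
#' its largest-magnitude loading is positive.  `identity` requires
#' `target_dim == ncol` and returns the input; `external` applies a
#' user-supplied function.
#'
#' @param embeddings Numeric matrix, documents x dim (n >= 2).
#' @param target_dim Output dimension k <= ncol(embeddings).
#' @param method `"svd"`, `"identity"`, or `"external"`.
#' @param external_fn Function (matrix, k) -> matrix, for
#'   `method = "external"`.
#' @return Numeric matrix, documents x k.
#' @export
reduce_dim <- function(embeddings, target_dim,
                       method = c("svd", "identity", "external"),
                       external_fn = NULL) {
  method <- match.arg(method)
  if (target_dim > ncol(embeddings)) {
    stop_nmu("target_dim exceeds embedding dimension",
             class = "nmutext_config_error")
  }
  if (method == "identity") {
    if (target_dim != ncol(embeddings)) {
      stop_nmu("identity reduction requires target_dim == ncol",
               class = "nmutext_config_error")
    }
    return(embeddings)
  }
  if (method == "external") {
    if (is.null(external_fn)) {
      stop_nmu("external reduction needs external_fn",
               class = "nmutext_config_error")
    }
    return(external_fn(embeddings, target_dim))
  }
  centered <- scale(embeddings, center = TRUE, scale = FALSE)
  sv <- svd(centered, nu = 0, nv = target_dim)
  V <- sv$v
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  out <- centered %*% V
  rownames(out) <- rownames(embeddings)
  out
}

#' Cluster reduced document embeddings
#'
#' The `density` method is single-linkage agglomeration cut at
#' `distance_threshold`; connected components smaller than
#' `min_cluster_size` become outliers (label -1).  Surviving clusters
#' are renumbered 0, 1, ... by decreasing size, ties broken by the
#' smallest member index.  With fewer documents than
#' `min_cluster_size` everything is an outlier (with a warning), not
#' an error.
#'
#' @param reduced Numeric matrix, documents x k.
#' @param min_cluster_size Minimum members per cluster (>= 2).
#' @param distance_threshold Linkage cut height.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param method `"density"` or `"external"`.
#' @param external_fn Function (matrix) -> integer labels, for
#'   `method = "external"` (same -1 outlier convention).
#' @return Integer vector of labels (-1 = outlier, clusters 0-based).
#' @export
cluster_docs <- function(reduced, min_cluster_size = 5,
                         distance_threshold = 0.5,
                         metric = c("euclidean", "cosine"),
                         method = c("density", "external"),
                         external_fn = NULL) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (min_cluster_size < 2) {
    stop_nmu("min_cluster_size must be >= 2", class = "nmutext_config_error")
  }
  n <- nrow(reduced)
  if (method == "external") {
    if (is.null(external_fn)) {
      stop_nmu("external clustering needs external_fn",
               class = "nmutext_config_error")
    }
    return(renumber_clusters(external_fn(reduced), min_cluster_size))
  }
  if (n < min_cluster_size || n < 2) {
    warning("fewer documents than min_cluster_size; all labelled outliers")
    return(rep(-1L, n))
  }
  d <- if (metric == "euclidean") {
    stats::dist(reduced)
  } else {
    norms <- sqrt(rowSums(reduced^2))
    norms[norms == 0] <- 1
    sim <- tcrossprod(reduced / norms)
    stats::as.dist(pmax(1 - sim, 0))
  }
  hc <- stats::hclust(d, method = "single")
  comp <- stats::cutree(hc, h = distance_threshold)
  renumber_clusters(comp, min_cluster_size)
}

# Apply the min-size outlier rule and renumber clusters 0..C-1 by
# decreasing size, ties by smallest member index.
#' @noRd
renumber_clusters <- function(comp, min_cluster_size) {
  labels <- rep(-1L, length(comp))
  keep_ids <- names(which(table(comp) >= min_cluster_size))
  if (length(keep_ids) > 0) {
    sizes <- vapply(keep_ids, function(id) sum(comp == id), integer(1))
    first_member <- vapply(keep_ids, function(id) which(comp == id)[1],
                           integer(1))
    ord <- order(-sizes, first_member)
    for (rank in seq_along(ord)) {
      labels[comp == keep_ids[ord[rank]]] <- rank - 1L
    }
  }
  labels
}

#' Class-based TF-IDF term weights
#'
#' Pools token counts per cluster (outliers excluded) and weights each
#' term by `W(t, c) = tf(t, c) * log(1 + A / f(t))` with the natural
#' log, where `f(t)` is the term's total frequency over non-outlier
#' documents and `A` the average token count per class.  Weights are
#' non-negative and zero exactly where `tf` is zero.
#'
#' @param token_matrix An `nmu_token_matrix` aligned with `labels`.
#' @param labels Integer cluster labels from [cluster_docs()].
#' @return A list of class `nmu_ctfidf` with `classes`, `terms`, `tf`
#'   (classes x terms), `A`, `f`, and `W` (classes x terms).
#' @export
ctfidf <- function(token_matrix, labels) {
  stopifnot(length(labels) == nrow(token_matrix$counts))
  classes <- sort(unique(labels[labels >= 0]))
  if (length(classes) == 0) {
    stop_nmu("no non-outlier documents", class = "nmutext_contract_error")
  }
  tf <- t(vapply(classes, function(cl) {
    colSums(token_matrix$counts[labels == cl, , drop = FALSE])
  }, numeric(ncol(token_matrix$counts))))
  rownames(tf) <- as.character(classes)
  f <- colSums(tf)
  A <- sum(tf) / length(classes)
  idf <- ifelse(f > 0, log(1 + A / f), 0)
  W <- sweep(tf, 2, idf, `*`)
  W[tf == 0] <- 0
  structure(
    list(classes = classes, terms = colnames(token_matrix$counts),
         tf = tf, A = A, f = f, W = W),
    class = "nmu_ctfidf"
  )
}

#' Extract top-word topics from a c-TF-IDF matrix
#'
#' Per class, the `top_n` terms by descending weight, ties broken
#' lexicographically by term.
#'
#' @param ct An `nmu_ctfidf`.
#' @param top_n Words per topic (default 5).
#' @param sizes Optional named vector of per-class document counts.
#' @return List of topics, each with `topic_id`, `top_words` (data
#'   frame `term`, `weight`), and `size`.
#' @export
extract_topics <- function(ct, top_n = 5, sizes = NULL) {
  if (top_n < 1) stop_nmu("top_n must be >= 1", class = "nmutext_config_error")
  lapply(seq_along(ct$classes), function(i) {
    w <- ct$W[i, ]
    ord <- order(-w, ct$terms)
    k <- min(top_n, length(ord))
    list(
      topic_id = ct$classes[i],
      top_words = data.frame(term = ct$terms[ord[seq_len(k)]],
                             weight = unname(w[ord[seq_len(k)]]),
                             stringsAsFactors = FALSE),
      size = if (is.null(sizes)) NA_integer_ else
        unname(sizes[as.character(ct$classes[i])])
    )
  })
}

#' @noRd
time_bin <- function(timestamps, bin) {
  if (bin == "month") {
    format(timestamps, "%Y-%m", tz = "UTC")
  } else {
    format(timestamps, "%G-W%V", tz = "UTC")  # ISO week
  }
}

#' Topic frequency and weight per timestep
#'
#' Bins documents by calendar month (default) or ISO week.  Per
#' (topic, step): `frequency` is the document count and `weight` the
#' step-local term frequencies reweighted by the corpus-global IDF
#' from [ctfidf()], so per-step frequencies over topics sum to the
#' non-outlier document count of the step.  Outlier documents are
#' excluded.
#'
#' @param token_matrix An `nmu_token_matrix`.
#' @param labels Cluster labels aligned with the rows.
#' @param timestamps POSIXct vector aligned with the rows.
#' @param bin `"month"` or `"week"`.
#' @return Data frame `topic_id`, `step`, `frequency`, `weight`.
#' @export
topics_over_time <- function(token_matrix, labels, timestamps,
                             bin = c("month", "week")) {
  bin <- match.arg(bin)
  stopifnot(length(timestamps) == nrow(token_matrix$counts),
            length(labels) == nrow(token_matrix$counts))
  ct <- ctfidf(token_matrix, labels)
  idf <- ifelse(ct$f > 0, log(1 + ct$A / ct$f), 0)
  steps <- time_bin(timestamps, bin)
  rows <- list()
  for (step in sort(unique(steps))) {
    for (topic in ct$classes) {
      sel <- steps == step & labels == topic
      if (!any(sel)) next
      tf_step <- colSums(token_matrix$counts[sel, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        topic_id = topic, step = step, frequency = sum(sel),
        weight = sum(tf_step * idf), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Embedding-based topic coherence
#'
#' Per topic: the mean over all unordered pairs of its `top_k` words
#' of `max(0, cosine(v_i, v_j))` under the provider's vectors, so
#' scores land in [0, 1] by construction (1 when all words share one
#' vector, 0 when vectors are pairwise orthogonal).  Topics with fewer
#' than two embeddable words (nonzero vectors) are excluded with a
#' warning.
#'
#' @param topics Topic list from [extract_topics()].
#' @param provider An `nmu_embedding_provider`.
#' @param top_k Number of top words scored per topic (default 5).
#' @return List with `per_topic` (data frame `topic_id`, `coherence`)
#'   and `mean` (mean over scored topics).
#' @export
topic_coherence <- function(topics, provider, top_k = 5) {
  if (top_k < 2) stop_nmu("top_k must be >= 2", class = "nmutext_config_error")
  ids <- numeric(0); scores <- numeric(0)
  for (tp in topics) {
    words <- utils::head(tp$top_words$term, top_k)
    if (length(words) < 2) {
      warning("topic ", tp$topic_id, " has fewer than 2 top words; skipped")
      next
    }
    V <- provider$embed_tokens(words)
    norms <- sqrt(rowSums(V^2))
    ok <- norms > 0
    if (sum(ok) < 2) {
      warning("topic ", tp$topic_id, " has fewer than 2 embeddable words; ",
              "skipped")
      next
    }
    V <- V[ok, , drop = FALSE] / norms[ok]
    sim <- tcrossprod(V)
    sim <- pmin(pmax(sim, -1), 1)
    # identical vectors have cosine 1 by definition; guard rounding
    zero_gap <- as.matrix(stats::dist(V)) == 0
    sim[zero_gap] <- 1
    pair <- sim[upper.tri(sim)]
    scores <- c(scores, mean(pmax(pair, 0)))
    ids <- c(ids, tp$topic_id)
  }
  list(per_topic = data.frame(topic_id = ids, coherence = scores),
       mean = if (length(scores) > 0) mean(scores) else NA_real_)
}

#' Write topics as JSON
#'
#' @param topics Topic list from [extract_topics()].
#' @param path Output path.
#' @export
write_topics_json <- function(topics, path) {
  obj <- lapply(topics, function(tp) {
    list(topic_id = tp$topic_id, size = tp$size,
         top_words = lapply(seq_len(nrow(tp$top_words)), function(i) {
           list(term = tp$top_words$term[i],
                weight = tp$top_words$weight[i])
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
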