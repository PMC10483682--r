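# Entity-level evaluation: exact span+label matching, 70-15-15
# holdout, and k-fold cross-validation with mean +/- sample SD.

#' Entity-level precision, recall and F1
#'
#' A predicted span counts as a true positive iff its start, end AND
#' label all match a gold span of the same record; each gold span can
#' be matched at most once.  Zero-division follows the 0/0 -> 0
#' convention (with a warning).  Micro-averaged figures are the
#' headline; per-label figures are also reported.
#'
#' @param gold,pred Lists aligned by record; each element a data frame
#'   with columns `start`, `end`, `label` (possibly zero rows).
#' @return List of class `nmu_entity_eval` with `micro` (`precision`,
#'   `recall`, `f1`, `tp`, `fp`, `fn`) and `per_label` (data frame).
#' @export
entity_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop_nmu("gold and pred must align record by record",
             class = "nmutext_contract_error")
  }
  labels <- unique(c(
    unlist(lapply(gold, function(g) g$label)),
    unlist(lapply(pred, function(p) p$label))
  ))
  tp <- stats::setNames(integer(length(labels)), labels)
  fp <- tp; fn <- tp
  for (r in seq_along(gold)) {
    g <- gold[[r]]; p <- pred[[r]]
    matched <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(p))) {
      hit <- which(!matched & g$start == p$start[i] & g$end == p$end[i] &
                     g$label == p$label[i])
      if (length(hit) > 0) {
        matched[hit[1]] <- TRUE
        tp[p$label[i]] <- tp[p$label[i]] + 1L
      } else {
        fp[p$label[i]] <- fp[p$label[i]] + 1L
      }
    }
    for (i in which(!matched)) fn[g$label[i]] <- fn[g$label[i]] + 1L
  }
  safe_div <- function(num, den) {
    if (den == 0) {
      if (num != 0) stop("impossible count state")
      warning("0/0 in metric; reported as 0")
      return(0)
    }
    num / den
  }
  prf <- function(tp_, fp_, fn_) {
    p <- safe_div(tp_, tp_ + fp_)
    r <- safe_div(tp_, tp_ + fn_)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  }
  micro <- suppressWarnings(prf(sum(tp), sum(fp), sum(fn)))
  per_label <- do.call(rbind, lapply(labels, function(l) {
    m <- suppressWarnings(prf(tp[l], fp[l], fn[l]))
    data.frame(label = l, precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], tp = tp[l], fp = fp[l], fn = fn[l],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(
    list(micro = c(as.list(micro),
                   list(tp = sum(tp), fp = sum(fp), fn = sum(fn))),
         per_label = per_label),
    class = "nmu_entity_eval"
  )
}

#' Seeded train/dev/test holdout split
#'
#' Shuffles indices with the given seed, then slices contiguously into
#' the requested ratios with largest-remainder rounding, so the three
#' parts always partition the input exactly.
#'
#' @param n Number of items (or a list/corpus whose length is used).
#' @param ratios Three ratios summing to 1 (default `c(0.70, 0.15,
#'   0.15)`).
#' @param seed Shuffle seed.
#' @return List with integer index vectors `train`, `dev`, `test`.
#' @export
holdout_split <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1) {
  if (!is.numeric(n)) n <- if (is.data.frame(n)) nrow(n) else length(n)
  if (abs(sum(ratios) - 1) > 1e-9 || length(ratios) != 3) {
    stop_nmu("ratios must be three numbers summing to 1",
             class = "nmutext_config_error")
  }
  sizes <- floor(n * ratios)
  rem <- n * ratios - sizes
  leftover <- n - sum(sizes)
  if (leftover > 0) {
    ord <- order(-rem, seq_along(ratios))
    sizes[ord[seq_len(leftover)]] <- sizes[ord[seq_len(leftover)]] + 1
  }
  idx <- with_local_seed(seed, sample(n))
  list(
    train = sort(idx[seq_len(sizes[1])]),
    dev = sort(idx[sizes[1] + seq_len(sizes[2])]),
    test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
}

#' Seeded k-fold cross-validation
#'
#' Shuffles, forms k near-equal folds (sizes differ by at most one),
#' uses each fold once as the test set, and aggregates per-metric mean
#' and sample standard deviation (n - 1 denominator).
#'
#' @param corpus A list of items (or anything `train_fn`/`eval_fn`
#'   index into).
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @param train_fn Function(train_items) -> model.
#' @param eval_fn Function(model, test_items) -> named numeric vector
#'   of metrics (e.g. precision/recall/f1).
#' @return List of class `nmu_cv_report` with `folds` (data frame of
#'   per-fold metrics), `mean` and `sd` (named vectors).
#' @export
cross_validate <- function(corpus, k = 5, seed = 1, train_fn, eval_fn) {
  n <- length(corpus)
  if (k < 2 || n < k) {
    stop_nmu("need k >= 2 and at least k items", class = "nmutext_contract_error")
  }
  idx <- with_local_seed(seed, sample(n))
  fold_of <- rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
  scores <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- idx[fold_of == f]
    train_idx <- idx[fold_of != f]
    model <- train_fn(corpus[train_idx])
    scores[[f]] <- eval_fn(model, corpus[test_idx])
  }
  folds <- do.call(rbind, lapply(scores, function(s) as.data.frame(t(s))))
  structure(
    list(folds = folds,
         mean = colMeans(folds),
         sd = vapply(folds, stats::sd, numeric(1))),
    class = "nmu_cv_report"
  )
}

#' Render a cross-validation report as a mean +/- SD table
#'
#' @param report An `nmu_cv_report`.
#' @param digits Decimal places (default 3).
#' @return Character vector of table lines (also printed).
#' @export
format_cv_report <- function(report, digits = 3) {
  lines <- vapply(names(report$mean), function(m) {
    sprintf("%-12s %.*f ± %.*f", m, digits, report$mean[[m]],
            digits, report$sd[[m]])
  }, character(1))
  lines
}

#' Write an evaluation or CV report as JSON
#'
#' @param report An `nmu_entity_eval` or `nmu_cv_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
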