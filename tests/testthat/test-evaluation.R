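span_df <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      label = character()))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(start = r[[1]], end = r[[2]], label = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("exact span+label matching reproduces the worked examples", {
  same <- list(span_df(list(1, 3, "DRUG")))
  ev <- entity_prf(same, same)
  expect_equal(unlist(ev$micro[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))

  gold <- list(span_df(list(0, 1, "ADE"), list(2, 3, "DRUG")))
  pred <- list(span_df(list(0, 1, "ADE"), list(4, 5, "DRUG")))
  ev2 <- entity_prf(gold, pred)
  expect_equal(ev2$micro$precision, 0.5)
  expect_equal(ev2$micro$recall, 0.5)
  expect_equal(ev2$micro$f1, 0.5)

  ev3 <- suppressWarnings(entity_prf(gold, list(span_df())))
  expect_equal(unlist(ev3$micro[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_error(entity_prf(gold, list()), class = "nmutext_contract_error")
})

test_that("label mismatches at matching offsets are not true positives", {
  gold <- list(span_df(list(0, 2, "ADE")))
  pred <- list(span_df(list(0, 2, "DRUG")))
  ev <- entity_prf(gold, pred)
  expect_equal(ev$micro$tp, 0)
  expect_equal(ev$micro$fp, 1)
  expect_equal(ev$micro$fn, 1)
  # swapping gold and pred exchanges precision and recall
  g2 <- list(span_df(list(0, 1, "ADE"), list(2, 3, "ADE")))
  p2 <- list(span_df(list(0, 1, "ADE")))
  a <- entity_prf(g2, p2)
  b <- entity_prf(p2, g2)
  expect_equal(a$micro$precision, b$micro$recall)
  expect_equal(a$micro$recall, b$micro$precision)
})

test_that("each gold span matches at most one prediction", {
  gold <- list(span_df(list(0, 2, "DRUG")))
  pred <- list(span_df(list(0, 2, "DRUG"), list(0, 2, "DRUG")))
  ev <- entity_prf(gold, pred)
  expect_equal(ev$micro$tp, 1)
  expect_equal(ev$micro$fp, 1)
})

test_that("holdout split uses largest-remainder rounding and partitions", {
  s100 <- holdout_split(100, seed = 4)
  expect_equal(lengths(s100), c(train = 70, dev = 15, test = 15))
  s10 <- holdout_split(10, seed = 4)
  expect_equal(lengths(s10), c(train = 7, dev = 2, test = 1))
  all_idx <- sort(unname(unlist(s10)))
  expect_equal(all_idx, 1:10)
  expect_identical(holdout_split(10, seed = 4), s10)  # deterministic
  expect_false(identical(holdout_split(10, seed = 5)$train, s10$train))
})

test_that("cross-validation folds are near-equal and stats use n-1", {
  corpus <- as.list(1:23)
  seen <- new.env(); seen$sizes <- integer(); seen$items <- integer()
  cv <- cross_validate(
    corpus, k = 5, seed = 2,
    train_fn = function(train) length(train),
    eval_fn = function(model, test) {
      seen$sizes <- c(seen$sizes, length(test))
      seen$items <- c(seen$items, unlist(test))
      c(f1 = 0.8)
    }
  )
  expect_equal(sort(seen$items), 1:23)        # folds partition the corpus
  expect_lte(diff(range(seen$sizes)), 1)      # near-equal folds
  expect_equal(unname(cv$mean), 0.8)
  expect_equal(unname(cv$sd), 0)

  scores <- c(0.9, 1.0, 0.8, 1.0, 0.8)
  i <- 0
  cv2 <- cross_validate(as.list(1:10), k = 5, seed = 1,
                        train_fn = function(x) NULL,
                        eval_fn = function(m, t) {
                          i <<- i + 1
                          c(f1 = scores[i])
                        })
  expect_equal(unname(cv2$mean), 0.9)
  expect_equal(unname(cv2$sd), 0.1)
  expect_error(cross_validate(as.list(1:3), k = 5, seed = 1,
                              train_fn = identity, eval_fn = identity),
               class = "nmutext_contract_error")
})

test_that("cv report formats as mean +/- SD lines", {
  i <- 0
  cv <- cross_validate(as.list(1:10), k = 5, seed = 1,
                       train_fn = function(x) NULL,
                       eval_fn = function(m, t) {
                         i <<- i + 1
                         c(f1 = c(0.9, 1, 0.8, 1, 0.8)[i])
                       })
  line <- format_cv_report(cv)
  expect_match(line, "f1")
  expect_match(line, "0.900")
  expect_match(line, "0.100")
})
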