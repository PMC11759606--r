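test_that("PLH histogram obeys its closed-form cases", {
  # all likelihoods zero: the whole mass sits in the first bin
  h <- plh_features(rep(0, 7))
  expect_equal(h[1], 1)
  expect_equal(sum(h[-1]), 0)

  # one likelihood per bin centre: exactly uniform
  centres <- (0:100 + 0.5) / 101
  expect_equal(plh_features(centres), rep(1 / 101, 101))

  # normalization holds for arbitrary input
  h <- plh_features(withr::with_seed(1, runif(57)))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h >= 0))

  expect_error(plh_features(numeric(0)), "at least one")
  expect_error(plh_features(c(0.2, 1.3)), "0, 1")
})

test_that("the boundary likelihood 1 falls in the closed last bin", {
  h <- plh_features(c(1, 1))
  expect_equal(h[101], 1)
})

test_that("tf-idf matches its closed forms", {
  # one slide, every patch in a single word: tf = 1, idf = ln(2/2)+1 = 1
  b <- bow_tfidf(list(rep(0.5, 9)))
  w <- pathomil:::likelihood_bin(0.5)
  expect_equal(b[1, w], 1)
  expect_equal(sum(b[1, -w]), 0)

  # a word present in all N slides has idf exactly 1
  bags <- list(c(0.5, 0.1), c(0.5, 0.9), c(0.5, 0.3))
  idf <- bow_fit(bags)
  expect_equal(idf$idf[w], 1)
})

test_that("bow_tfidf equals the brute-force oracle on random toy cohorts", {
  for (s in 1:100) {
    bags <- withr::with_seed(s, {
      n_slides <- sample(1:5, 1)
      lapply(seq_len(n_slides), function(i) runif(sample(1:20, 1)))
    })
    expect_equal(unname(bow_tfidf(bags)), bf_tfidf(bags), tolerance = 1e-12)
  }
})

test_that("a frozen idf is applied unchanged to new slides", {
  train_bags <- list(c(0.1, 0.1, 0.9), c(0.2, 0.8))
  idf <- bow_fit(train_bags)
  test_bag <- list(c(0.1, 0.5))
  out <- bow_tfidf(test_bag, idf)
  w1 <- pathomil:::likelihood_bin(0.1)
  w5 <- pathomil:::likelihood_bin(0.5)
  expect_equal(out[1, w1], 0.5 * idf$idf[w1])
  expect_equal(out[1, w5], 0.5 * idf$idf[w5])
  expect_error(bow_tfidf(list(numeric(0)), idf), "non-empty")
})

test_that("label features implement the documented vote and tie rules", {
  mk <- function(lik) data.frame(likelihood = lik,
                                 pred_label = as.integer(lik >= 0.5))
  expect_equal(unname(label_features(mk(c(0.9, 0.8)))), c(1, 1))
  expect_equal(unname(label_features(mk(rep(0.2, 5)))), c(0, 0))
  # a 50/50 vote resolves to 1 even when the mean likelihood is below 0.5
  tie <- data.frame(likelihood = c(0.9, 0.05), pred_label = c(1, 0))
  expect_equal(unname(label_features(tie))[1], 1)
})

test_that("assemble_features yields the 206-feature contract", {
  v <- assemble_features(rep(1 / 101, 101), c(1, 0), rep(0, 101), c(0, 0))
  expect_length(v, 206)
  expect_identical(names(v), feature_names_206())
  expect_error(assemble_features(rep(0, 100), c(1, 0), rep(0, 101), c(0, 0)),
               "lengths")

  z <- assemble_features(rep(0, 101), c(0, 0), rep(0, 101), c(0, 0))
  expect_true(all(z == 0))
})

test_that("fusion is invariant to patch order and patch duplication", {
  lik <- withr::with_seed(8, runif(30))
  expect_equal(plh_features(lik), plh_features(rev(lik)))
  expect_equal(plh_features(lik), plh_features(rep(lik, 2)))
  idf <- bow_fit(list(lik))
  expect_equal(bow_tfidf(list(sample(lik)), idf), bow_tfidf(list(lik), idf))
  expect_equal(bow_tfidf(list(rep(lik, 3)), idf), bow_tfidf(list(lik), idf))
})

test_that("fuse_slides maps each slide independently given the frozen idf", {
  preds <- withr::with_seed(12, data.frame(
    slide_id = rep(c("A", "B", "C"), each = 10),
    likelihood = runif(30)
  ))
  preds$pred_label <- as.integer(preds$likelihood >= 0.5)
  f1 <- fuse_slides(preds, train_slide_ids = c("A", "B", "C"))
  expect_equal(ncol(f1$features), 207)
  expect_equal(nrow(f1$features), 3)
  # PLH block of every slide sums to one
  plh_cols <- sprintf("plh_%03d", 0:100)
  expect_equal(unname(rowSums(f1$features[, plh_cols])), rep(1, 3))

  # permuting the slide order permutes rows, nothing else
  perm <- preds[order(match(preds$slide_id, c("C", "A", "B"))), ]
  f2 <- fuse_slides(perm, train_slide_ids = c("A", "B", "C"))
  reord <- f2$features[match(f1$features$slide_id, f2$features$slide_id), ]
  rownames(reord) <- NULL
  expect_equal(reord, f1$features)
})
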