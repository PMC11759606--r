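#' The 206 slide-level feature names
#'
#' `plh_000..plh_100`, `plh_label_major`, `plh_label_meanprob`,
#' `bow_000..bow_100`, `bow_label_major`, `bow_label_meanprob`:
#' 2 procedures x (101 probability features + 2 predictive label features).
#'
#' @return character vector of length 206, stable across runs.
#' @export
feature_names_206 <- function() {
  c(sprintf("plh_%03d", 0:100), "plh_label_major", "plh_label_meanprob",
    sprintf("bow_%03d", 0:100), "bow_label_major", "bow_label_meanprob")
}

# quantize a likelihood in [0,1] to one of 101 equal-width bins
# (edges k/101, k = 0..101; the last bin is closed). 1-based bin index.
likelihood_bin <- function(likelihood) {
  assert_that(all(likelihood >= 0 & likelihood <= 1),
              "likelihoods must lie in [0, 1]")
  pmin(floor(likelihood * 101), 100) + 1L
}

#' Patch-likelihood histogram (PLH) features of one slide
#'
#' Histogram of the slide's patch likelihoods over 101 equal-width bins on
#' `[0, 1]`, normalized to sum to one so slides with different tile counts
#' are comparable.
#'
#' @param likelihoods numeric vector of patch likelihoods in `[0, 1]`.
#' @return numeric 101-vector summing to 1.
#' @export
plh_features <- function(likelihoods) {
  assert_that(length(likelihoods) >= 1, "need at least one likelihood")
  tabulate(likelihood_bin(likelihoods), nbins = 101) / length(likelihoods)
}

#' Fit the inverse-document-frequency vector of the BoW pipeline
#'
#' Each patch is quantized to one of 101 likelihood "words" (the PLH bin
#' rule). Over the `N` fitting slides,
#' `idf(w) = ln((1 + N) / (1 + df(w))) + 1` with `df(w)` the number of
#' slides containing word `w`. Fit on training slides and freeze for test
#' slides.
#'
#' @param bags list of per-slide likelihood vectors (each non-empty).
#' @return object of class `bow_idf` (fields `idf`, `n_slides`).
#' @export
bow_fit <- function(bags) {
  assert_that(length(bags) >= 1, "need at least one slide")
  assert_that(all(lengths(bags) >= 1), "every likelihood bag must be non-empty")
  df <- rowSums(vapply(bags, function(b) {
    tabulate(likelihood_bin(b), nbins = 101) > 0
  }, logical(101)))
  out <- list(idf = log((1 + length(bags)) / (1 + df)) + 1,
              n_slides = length(bags))
  class(out) <- "bow_idf"
  out
}

#' TF-IDF bag-of-words features
#'
#' Per slide, `tf(w) = count(w) / bag size` over the 101 likelihood words;
#' the feature vector is `tf * idf` with the idf frozen from [bow_fit()].
#' When `idf` is omitted it is fitted on `bags` themselves (training use).
#'
#' @param bags list of per-slide likelihood vectors.
#' @param idf a `bow_idf` from [bow_fit()], or `NULL` to fit on `bags`.
#' @return numeric matrix, one row per slide, 101 columns.
#' @export
bow_tfidf <- function(bags, idf = NULL) {
  if (is.null(idf)) idf <- bow_fit(bags)
  assert_that(inherits(idf, "bow_idf"), "idf must come from bow_fit()")
  assert_that(length(idf$idf) == 101, "idf vocabulary size mismatch")
  assert_that(all(lengths(bags) >= 1), "every likelihood bag must be non-empty")
  t(vapply(bags, function(b) {
    tf <- tabulate(likelihood_bin(b), nbins = 101) / length(b)
    tf * idf$idf
  }, numeric(101)))
}

#' The two predictive label features of one slide
#'
#' `(majority-vote predicted label, indicator that the mean likelihood is at
#' least 0.5)`; a tied majority vote resolves to 1.
#'
#' @param preds data frame of one slide's predictions with columns
#'   `likelihood` and `pred_label`.
#' @return integer 2-vector in `{0, 1}`.
#' @export
label_features <- function(preds) {
  assert_that(nrow(preds) >= 1, "need at least one prediction")
  c(major = as.integer(mean(preds$pred_label) >= 0.5),
    meanprob = as.integer(mean(preds$likelihood) >= 0.5))
}

#' Assemble the 206-feature slide vector
#'
#' Concatenates the PLH block, its label pair, the BoW block and its label
#' pair in the documented order and attaches the stable feature names.
#'
#' @param plh 101-vector from [plh_features()].
#' @param plh_labels 2-vector from [label_features()].
#' @param bow 101-vector row of [bow_tfidf()].
#' @param bow_labels 2-vector from [label_features()].
#' @return named numeric vector of length 206.
#' @export
assemble_features <- function(plh, plh_labels, bow, bow_labels) {
  assert_that(length(plh) == 101 && length(plh_labels) == 2 &&
                length(bow) == 101 && length(bow_labels) == 2,
              "blocks must have lengths 101, 2, 101, 2")
  stats::setNames(c(plh, plh_labels, bow, bow_labels), feature_names_206())
}

#' Fuse patch predictions into the slide feature matrix
#'
#' Runs both slide-level pipelines over a cohort of patch predictions: the
#' PLH histogram and the BoW TF-IDF encoding, each extended by the two
#' predictive label features. The idf is fitted on the training slides only
#' and frozen for the remaining slides.
#'
#' @param preds patch predictions (`slide_id`, `likelihood`, `pred_label`).
#' @param train_slide_ids slide ids of the training cohort (idf fitting
#'   set); default: all slides.
#' @return list with `features` (data frame `slide_id` + 206 named columns,
#'   one row per slide in first-appearance order) and `idf` (the frozen
#'   `bow_idf`).
#' @export
fuse_slides <- function(preds, train_slide_ids = NULL) {
  assert_that(nrow(preds) >= 1, "no predictions supplied")
  sids <- unique(preds$slide_id)
  bags <- lapply(sids, function(s) preds$likelihood[preds$slide_id == s])
  names(bags) <- sids
  if (is.null(train_slide_ids)) train_slide_ids <- sids
  train_slide_ids <- intersect(train_slide_ids, sids)
  assert_that(length(train_slide_ids) >= 1, "no training slides present")
  idf <- bow_fit(bags[train_slide_ids])
  bow <- bow_tfidf(bags, idf)
  rows <- t(vapply(seq_along(sids), function(i) {
    sub <- preds[preds$slide_id == sids[i], ]
    lab <- label_features(sub)
    assemble_features(plh_features(sub$likelihood), lab, bow[i, ], lab)
  }, numeric(206)))
  features <- data.frame(slide_id = sids, rows, stringsAsFactors = FALSE,
                         check.names = FALSE)
  list(features = features, idf = idf)
}
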