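#' Random train/test split
#'
#' The training set holds `floor(train_fraction * n)` samples, drawn
#' reproducibly from the seed. With `stratify_by`, the floor rule is applied
#' within each stratum.
#'
#' @param n cohort size (>= 2).
#' @param train_fraction training fraction in `(0, 1)` (default 0.7).
#' @param seed RNG seed.
#' @param stratify_by optional vector of length `n` (e.g. the outcome) to
#'   stratify the draw.
#' @return character vector of length `n` with values `"train"` / `"test"`.
#' @export
split_cohort <- function(n, train_fraction = 0.7, seed = 1L,
                         stratify_by = NULL) {
  assert_that(is_count(n) && n >= 2, "n must be an integer >= 2")
  assert_that(is.numeric(train_fraction) && train_fraction > 0 &&
                train_fraction < 1, "train_fraction must be in (0, 1)")
  withr::with_seed(seed, {
    split <- rep("test", n)
    if (is.null(stratify_by)) {
      split[sample.int(n, floor(train_fraction * n))] <- "train"
    } else {
      assert_that(length(stratify_by) == n, "stratify_by must have length n")
      for (lev in unique(stratify_by)) {
        idx <- which(stratify_by == lev)
        split[sample(idx, floor(train_fraction * length(idx)))] <- "train"
      }
    }
    split
  })
}

#' Train the metastasis classifiers
#'
#' Fits one model per requested algorithm on the selected slide features:
#' a random forest, gradient-boosted trees (XGBoost), and an L2-regularised
#' logistic model. Hyperparameters are fixed, recorded in the result, and
#' all fits are seeded and single-threaded for reproducibility.
#'
#' @param X numeric feature matrix or data frame (rows = slides).
#' @param y 0/1 outcome labels (both classes required).
#' @param algos subset of `c("random_forest", "xgboost", "ridge_logistic")`.
#' @param seed RNG seed.
#' @return named list of fitted classifiers (class `pathomil_classifier`),
#'   each carrying its algorithm name and hyperparameters.
#' @export
train_classifiers <- function(X, y,
                              algos = c("random_forest", "xgboost",
                                        "ridge_logistic"),
                              seed = 1L) {
  X <- as.matrix(X)
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  if (length(unique(y)) < 2) {
    stop("single-class labels; cannot train classifiers", call. = FALSE)
  }
  algos <- match.arg(algos, several.ok = TRUE)
  fits <- lapply(algos, function(algo) {
    fit <- withr::with_seed(seed, switch(
      algo,
      random_forest = {
        hp <- list(ntree = 500)
        list(fit = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                              ntree = hp$ntree),
             hyperparameters = hp)
      },
      xgboost = {
        hp <- list(nrounds = 100, max_depth = 3, learning_rate = 0.1)
        list(fit = xgboost::xgboost(
          X, factor(y, levels = c(0, 1)),
          objective = "binary:logistic", nrounds = hp$nrounds,
          max_depth = hp$max_depth, learning_rate = hp$learning_rate,
          nthreads = 1, seed = seed),
          hyperparameters = hp)
      },
      ridge_logistic = {
        hp <- list(alpha = 0, lambda = 0.1)
        list(fit = glmnet::glmnet(X, y, family = "binomial",
                                  alpha = hp$alpha, lambda = hp$lambda),
             hyperparameters = hp)
      }
    ))
    structure(list(algo = algo, fit = fit$fit,
                   hyperparameters = fit$hyperparameters,
                   seed = seed, feature_names = colnames(X)),
              class = "pathomil_classifier")
  })
  names(fits) <- algos
  fits
}

#' Predict positive-class scores from a fitted classifier
#'
#' @param model a `pathomil_classifier` from [train_classifiers()].
#' @param X feature matrix with the training columns.
#' @return numeric score vector (probability of class 1).
#' @export
predict_classifier <- function(model, X) {
  assert_that(inherits(model, "pathomil_classifier"), "not a pathomil_classifier")
  X <- as.matrix(X)
  assert_that(nrow(X) >= 1, "empty feature matrix")
  if (!is.null(model$feature_names)) {
    assert_that(all(model$feature_names %in% colnames(X)),
                "feature columns do not match the training matrix")
    X <- X[, model$feature_names, drop = FALSE]
  }
  switch(
    model$algo,
    random_forest = as.numeric(predict(model$fit, X, type = "prob")[, "1"]),
    xgboost = as.numeric(predict(model$fit, X)),
    ridge_logistic = as.numeric(predict(model$fit, X, type = "response"))
  )
}
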