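# Independent brute-force oracles used to cross-check the package's
# implementations. They are deliberately written in the most literal way
# possible (explicit loops over definitions) and share no code with R/.

# tf-idf over the 101 likelihood words, straight from the definitions
bf_tfidf <- function(bags) {
  word_of <- function(x) min(floor(x * 101), 100) + 1
  n <- length(bags)
  df <- numeric(101)
  for (w in 1:101) {
    for (b in bags) {
      if (any(sapply(b, word_of) == w)) df[w] <- df[w] + 1
    }
  }
  idf <- log((1 + n) / (1 + df)) + 1
  out <- matrix(0, n, 101)
  for (i in seq_len(n)) {
    words <- sapply(bags[[i]], word_of)
    for (w in 1:101) {
      out[i, w] <- sum(words == w) / length(words) * idf[w]
    }
  }
  out
}

# exhaustive pairwise greedy filter with the first-kept-wins order rule
bf_pearson_filter <- function(X, threshold = 0.9) {
  X <- as.matrix(X)
  keep <- character(0)
  for (nm in colnames(X)) {
    if (stats::sd(X[, nm]) == 0) next
    redundant <- FALSE
    for (k in keep) {
      if (abs(stats::cor(X[, nm], X[, k])) > threshold) redundant <- TRUE
    }
    if (!redundant) keep <- c(keep, nm)
  }
  keep
}

# exhaustive pair enumeration C-index (comparable iff t_i < t_j, event_i = 1)
bf_cindex <- function(risk, time, event) {
  num <- 0
  den <- 0
  for (i in seq_along(risk)) {
    for (j in seq_along(risk)) {
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# contingency metrics straight from the counting definitions
bf_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  div <- function(a, b) if (b == 0) 0 else a / b
  c(accuracy = (tp + tn) / length(pred),
    sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

# small planted cohort reused by several training tests
small_plant_cohort <- function(seed = 21, n_patients = 16, tiles_per_slide = 24) {
  generate_cohort(cohort_config(
    n_patients = n_patients, tiles_per_slide = tiles_per_slide,
    tile_size = 64, seed = seed
  ))
}

# all tissue tiles of a cohort plus their weak labels and latent truth
cohort_tissue_tiles <- function(cohort) {
  tiles <- unlist(lapply(cohort$manifest$slide_id, cohort_tiles,
                         cohort = cohort), recursive = FALSE)
  keep <- !cohort$patch_truth$background
  er <- stats::setNames(cohort$manifest$er_label, cohort$manifest$slide_id)
  split <- stats::setNames(cohort$manifest$split, cohort$manifest$slide_id)
  sid <- cohort$patch_truth$slide_id[keep]
  list(tiles = tiles[keep], slide_id = sid,
       weak_label = as.integer(er[sid]),
       latent = cohort$patch_truth$likelihood[keep],
       is_train = split[sid] == "train")
}

# flat random tissue-like tile
random_tile <- function(size = 32, seed = 1) {
  withr::with_seed(seed, {
    array(runif(size * size * 3, 40, 215), dim = c(size, size, 3))
  })
}
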