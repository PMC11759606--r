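#' Pearson-redundancy feature filter
#'
#' Greedy scan in canonical column order: a column is dropped iff its
#' absolute Pearson correlation with any already-kept column strictly
#' exceeds `threshold` (anti-correlated duplicates are as redundant as
#' correlated ones). Constant columns, whose correlation is undefined, are
#' dropped with a message. The result is independent of row order and
#' preserves column order.
#'
#' @param X numeric matrix or data frame of features (rows = slides).
#' @param threshold correlation cut in `(0, 1]` (default 0.9; a pair
#'   correlated above it keeps only its first member).
#' @return character vector of kept column names, in input order.
#' @export
pearson_filter <- function(X, threshold = 0.9) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 2, "need at least two rows to correlate")
  assert_that(is.numeric(threshold) && threshold > 0 && threshold <= 1,
              "threshold must be in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    message("pearson_filter: dropping ", sum(constant),
            " constant column(s): ",
            paste(utils::head(colnames(X)[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
  }
  candidates <- colnames(X)[!constant]
  kept <- character(0)
  for (nm in candidates) {
    if (length(kept) == 0) {
      kept <- nm
      next
    }
    r <- abs(cor(X[, nm], X[, kept, drop = FALSE]))
    if (all(r <= threshold)) kept <- c(kept, nm)
  }
  kept
}
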