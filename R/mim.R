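#' Plug-in mutual information between a feature and class labels
#'
#' Estimates `MI(Y, X) = H(Y) + H(X) - H(Y, X)` in bits with plug-in
#' (empirical frequency) entropies, using `0 * log 0 = 0`. Continuous
#' features are discretized by equal-frequency (quantile) binning; discrete
#' features with at most `n_bins` distinct values are used as-is.
#'
#' @param feature Numeric vector, one value per trial, or an already
#'   discretized integer vector when `bin_edges` is `NA`.
#' @param labels Class label per trial (any discrete vector); must not be
#'   constant.
#' @param n_bins Number of quantile bins (default 10, >= 2).
#' @param bin_edges Optional pre-computed bin edges (from training data) to
#'   reuse at test time.
#' @return Numeric scalar, MI in bits, with attribute `"bin_edges"`.
#' @export
mutual_information <- function(feature, labels, n_bins = 10,
                               bin_edges = NULL) {
  if (length(feature) != length(labels)) stop("feature and labels lengths differ")
  if (length(unique(labels)) < 2) {
    stop("labels are constant: H(Y) = 0 and ranking by MI is meaningless")
  }
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (is.null(bin_edges)) bin_edges <- quantile_edges(feature, n_bins)
  xd <- discretize_with_edges(feature, bin_edges)
  yd <- as.integer(factor(labels))
  joint <- table(yd, xd) / length(xd)
  mi <- entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
    entropy_bits(joint)
  structure(max(mi, 0), bin_edges = bin_edges)
}

# Interior quantile cut points (length n_bins - 1); duplicated quantiles of
# heavily tied features collapse to fewer effective bins.
quantile_edges <- function(x, n_bins) {
  probs <- seq_len(n_bins - 1) / n_bins
  unique(unname(stats::quantile(x, probs, type = 7)))
}

discretize_with_edges <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE) + 1L
}

# H(p) in bits for a vector/table of probabilities; 0 log 0 := 0.
entropy_bits <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank features by mutual information and select the top k
#'
#' Mutual-information maximization (MIM): every feature column is scored by
#' its plug-in MI with the labels, columns are ranked by decreasing MI (ties
#' broken by ascending original column index), and the first `k` are
#' selected. The returned bin edges let the same discretization be applied
#' at prediction time.
#'
#' @param features Numeric matrix `[n_trials x n_features]`.
#' @param labels Class label per trial.
#' @param k Number of features to keep (default 4).
#' @param n_bins Quantile bins per feature (default 10).
#' @return A list of class `feature_ranking`: `order` (full permutation,
#'   best first), `scores` (MI in bits, in `order`), `selected` (first `k`
#'   of `order`), `k_selected`, `bin_edges` (per original feature).
#' @export
rank_and_select <- function(features, labels, k = 4, n_bins = 10) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (k > p) stop("k (", k, ") exceeds number of features (", p, ")")
  edges <- vector("list", p)
  mi <- numeric(p)
  for (j in seq_len(p)) {
    v <- mutual_information(features[, j], labels, n_bins)
    mi[j] <- as.numeric(v)
    edges[[j]] <- attr(v, "bin_edges")
  }
  ord <- order(-mi, seq_len(p))
  structure(
    list(order = ord, scores = mi[ord], selected = ord[seq_len(k)],
         k_selected = as.integer(k), bin_edges = edges),
    class = "feature_ranking"
  )
}
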