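#' Kennard-Stone representative sample selection
#'
#' Deterministic max-min selection in score space. The first two selections
#' are the pair at maximum distance; each subsequent selection maximises the
#' minimum distance to the already-selected set. With `metric = "mahalanobis"`
#' distances are computed after whitening by the covariance of the scores
#' (the usual choice when selecting in PCA space). Ties are broken by the
#' lowest sample index.
#'
#' @param scores numeric matrix, one row per sample.
#' @param n_select number of samples to select (2 .. n).
#' @param metric `"mahalanobis"` (default) or `"euclidean"`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone_select <- function(scores, n_select,
                                 metric = c("mahalanobis", "euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(scores)
  n <- nrow(X)
  if (!is_count(n_select, min = 2L) || n_select > n) {
    stopf("n_select must lie in [2, %d]", n)
  }
  if (metric == "mahalanobis") {
    S <- stats::cov(X)
    ev <- eigen(S, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    if (!any(pos)) stopf("degenerate score covariance")
    W <- ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(ev$values[pos]), sum(pos))
    X <- X %*% W
  }
  D <- as.matrix(stats::dist(X))

  # seed pair at maximum distance, lexicographic lowest-index tie break
  mx <- max(D)
  hits <- which(D == mx, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])

  remaining <- setdiff(seq_len(n), sel)
  while (length(sel) < n_select) {
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    best <- remaining[which.max(mind)]  # which.max takes the first = lowest index
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
  }
  sel
}
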