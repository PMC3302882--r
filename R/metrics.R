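#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie): 1 for identical
#' partitions up to relabelling, expectation 0 under random labelling. The
#' degenerate comparisons in which both partitions are all singletons or
#' both are a single group are identical partitions and return 1.
#'
#' @param truth,estimate Group labels over the same elements (vectors of
#'   equal length; any atomic type).
#' @return A single number in (-1, 1].
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
#' @export
adjusted_rand <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("partitions cover different element sets", call. = FALSE)
  }
  if (anyNA(truth) || anyNA(estimate)) {
    stop("labels must not contain missing values", call. = FALSE)
  }
  t_id <- as.integer(factor(truth))
  e_id <- as.integer(factor(estimate))
  ari <- mclust::adjustedRandIndex(t_id, e_id)
  if (is.nan(ari)) {
    # both all-singletons or both one group: identical partitions
    same <- all(tabulate(t_id) == 1L) && all(tabulate(e_id) == 1L) ||
      (max(t_id) == 1L && max(e_id) == 1L)
    return(if (same) 1 else 0)
  }
  ari
}

#' Correlation gap of a partition
#'
#' The difference between the average intra-group and the average
#' inter-group correlation (diagonal excluded): the axis along which the
#' synthetic benchmarks become harder as noise grows. Groups of size one
#' contribute no intra pairs.
#'
#' @param x Symmetric correlation (or similarity) matrix.
#' @param labels Group label per element.
#' @return Mean intra-group entry minus mean inter-group entry.
#' @examples
#' C <- block_correlation(c(3, 3), rho = 0.5)
#' correlation_gap(C, rep(1:2, each = 3)) # 0.5
#' @export
correlation_gap <- function(x, labels) {
  x <- check_symmetric(x, "correlation matrix")
  n <- nrow(x)
  if (length(labels) != n) {
    stop("labels do not match the matrix size", call. = FALSE)
  }
  same <- outer(labels, labels, "==")
  off <- !diag(n)
  if (!any(same & off)) {
    stop("all groups are singletons; intra-group mean undefined", call. = FALSE)
  }
  mean(x[same & off]) - mean(x[!same])
}
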