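#' Pearson similarity and correlation distance from a data matrix
#'
#' Computes the pairwise Pearson correlation between the rows of `x` as the
#' similarity matrix and the correlation distance
#' \eqn{d_{ij} = \sqrt{2 (1 - w_{ij})}} as the dissimilarity matrix. The
#' correlation distance is the standard metric companion of the correlation
#' coefficient: it is 0 for perfectly correlated and 2 for perfectly
#' anti-correlated series.
#'
#' Missing values are handled with pairwise-complete correlations (with a
#' warning); rows with fewer than 3 complete pairs against any other row are
#' rejected, as are constant (zero-variance) rows.
#'
#' @param x Numeric matrix or data frame; rows are the elements to be
#'   clustered, columns are observations. At least 3 observations.
#' @return A list with components `similarity` and `dissimilarity`, both
#'   symmetric matrices with the row names of `x` as dimnames.
#' @examples
#' xy <- rbind(a = sin(1:50), b = sin(1:50 + 0.1), c = cos(1:50))
#' s <- pearson_similarity(xy)
#' s$similarity["a", "b"]
#' @export
pearson_similarity <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (ncol(x) < 3L) stop("need at least 3 observations (columns)", call. = FALSE)
  labels <- default_labels(nrow(x), rownames(x))
  has_na <- anyNA(x)
  if (has_na) {
    warning("missing values present; using pairwise-complete correlations")
    complete <- !is.na(x)
    pair_n <- complete %*% t(complete)
    if (any(pair_n < 3L)) {
      bad <- which(apply(pair_n < 3L, 1L, any))[1L]
      stop("row '", labels[bad], "' has fewer than 3 complete pairs",
        call. = FALSE
      )
    }
  }
  vars <- apply(x, 1L, stats::var, na.rm = TRUE)
  if (any(vars == 0 | is.na(vars))) {
    bad <- labels[which(vars == 0 | is.na(vars))[1L]]
    stop("row '", bad, "' has zero variance; correlation undefined",
      call. = FALSE
    )
  }
  w <- stats::cor(t(x), use = if (has_na) "pairwise.complete.obs" else "everything")
  w <- (w + t(w)) / 2
  diag(w) <- 1
  d <- sqrt(pmax(2 * (1 - w), 0))
  dimnames(w) <- dimnames(d) <- list(labels, labels)
  list(similarity = w, dissimilarity = d)
}

#' Gaussian-kernel similarity from Euclidean feature distances
#'
#' Computes the pairwise Euclidean distance between the rows of `x` as the
#' dissimilarity matrix and the Gaussian kernel
#' \eqn{w_{ij} = \exp(-d_{ij}^2 / (2\sigma^2))} as the similarity matrix,
#' with bandwidth \eqn{\sigma} equal to the standard deviation of the
#' pairwise distances over all element pairs. This is the recipe used for
#' feature-vector data such as the iris measurements, where a correlation
#' between four features would be meaningless.
#'
#' @param x Numeric matrix or data frame of features; rows are elements.
#' @return A list with components `similarity` and `dissimilarity`.
#' @examples
#' s <- gaussian_kernel_similarity(as.matrix(iris[1:10, 1:4]))
#' range(s$similarity)
#' @export
gaussian_kernel_similarity <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (anyNA(x)) stop("missing values are not supported here", call. = FALSE)
  labels <- default_labels(nrow(x), rownames(x))
  d <- as.matrix(stats::dist(x))
  sigma <- stats::sd(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate distances: zero spread across pairs", call. = FALSE)
  }
  w <- exp(-d^2 / (2 * sigma^2))
  dimnames(w) <- dimnames(d) <- list(labels, labels)
  list(similarity = w, dissimilarity = d, sigma = sigma)
}
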