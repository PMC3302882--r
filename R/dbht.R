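#' DBHT: deterministic clustering and hierarchy from a similarity structure
#'
#' Runs the full Directed Bubble Hierarchical Tree pipeline: build the PMFG
#' from the similarity matrix, decompose it into bubbles at separating
#' 3-cliques, direct the bubble tree by similarity flows, anchor discrete
#' clusters at the converging bubbles, and assemble the three-level
#' complete-linkage dendrogram. The method is deterministic and needs no
#' prior number of clusters, threshold, or supervision.
#'
#' @param x Either a numeric data matrix (rows = elements to cluster,
#'   columns = observations/features) or, with `similarity = "precomputed"`,
#'   a symmetric similarity matrix.
#' @param similarity Similarity recipe: `"pearson"` (correlation similarity
#'   with correlation distance; the default for series/expression data),
#'   `"gaussian_kernel"` (Euclidean distance with Gaussian-kernel
#'   similarity; for feature vectors), or `"precomputed"`.
#' @param dissimilarity Optional dissimilarity matrix, used with
#'   `"precomputed"`.
#' @param transpose If `TRUE`, cluster the columns of `x` instead.
#' @return An object of class `dbht` with components `pmfg`, `bubble_tree`,
#'   `directed_tree`, `clusters`, `hierarchy` (an [stats::hclust]-compatible
#'   merge tree), `distances`, and `recipe`.
#' @examples
#' x <- rbind(
#'   matrix(rnorm(5 * 60), 5) + rep(rnorm(60), each = 5),
#'   matrix(rnorm(5 * 60), 5) - rep(rnorm(60), each = 5)
#' )
#' fit <- dbht(x)
#' glance(fit)
#' head(tidy(fit))
#' @export
dbht <- function(x,
                 similarity = c("pearson", "gaussian_kernel", "precomputed"),
                 dissimilarity = NULL,
                 transpose = FALSE) {
  similarity <- match.arg(similarity)
  x <- as.matrix(x)
  if (transpose) x <- t(x)
  aff <- switch(similarity,
    pearson = pearson_similarity(x),
    gaussian_kernel = gaussian_kernel_similarity(x),
    precomputed = list(similarity = x, dissimilarity = dissimilarity)
  )
  g <- build_pmfg(aff$similarity, aff$dissimilarity)
  bt <- build_bubble_tree(g)
  dbt <- direct_bubble_tree(g, bt)
  D <- pmfg_distances(g)
  cl <- dbht_clusters(g, dbt, distances = D)
  hc <- build_full_dendrogram(g, dbt, cl, distances = D)
  structure(
    list(
      pmfg = g, bubble_tree = bt, directed_tree = dbt,
      clusters = cl, hierarchy = hc, distances = D,
      recipe = similarity, n = g$n, labels = g$labels
    ),
    class = "dbht"
  )
}

#' @export
print.dbht <- function(x, ...) {
  cat("DBHT fit:", x$n, "elements\n")
  cat("  PMFG edges:        ", nrow(x$pmfg$edges), "\n")
  cat("  bubbles:           ", length(x$directed_tree$bubbles), "\n")
  cat(
    "  converging bubbles:",
    sum(x$directed_tree$kind == "converging"), "\n"
  )
  cat("  discrete clusters: ", max(x$clusters$labels), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-element view of a DBHT fit
#'
#' @param x A `dbht` object.
#' @param ... Unused.
#' @return A tibble with one row per element: `element`, `cluster` (discrete
#'   DBHT cluster), and `bubble` (the bubble holding the element in the
#'   intra-cluster hierarchy).
#' @method tidy dbht
#' @export
tidy.dbht <- function(x, ...) {
  v2b <- assign_vertices_to_bubbles(x$pmfg, x$directed_tree, x$clusters)
  tibble::tibble(
    element = x$labels,
    cluster = as.integer(x$clusters$labels),
    bubble = as.integer(v2b)
  )
}

#' One-row summary of a DBHT fit
#'
#' @param x A `dbht` object.
#' @param ... Unused.
#' @return A one-row tibble: element count, PMFG edge count, bubble counts
#'   by kind, tie merges, and the discrete cluster count.
#' @method glance dbht
#' @export
glance.dbht <- function(x, ...) {
  kind <- x$directed_tree$kind
  tibble::tibble(
    n = x$n,
    n_edges = nrow(x$pmfg$edges),
    n_bubbles = length(x$directed_tree$bubbles),
    n_converging = sum(kind == "converging"),
    n_diverging = sum(kind == "diverging"),
    n_passage = sum(kind == "passage"),
    n_tie_merges = x$directed_tree$merged,
    n_clusters = max(x$clusters$labels)
  )
}
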