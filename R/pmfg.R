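#' Planarity test for an undirected edge list
#'
#' Decides whether a simple undirected graph admits a planar embedding, using
#' the left-right planarity criterion (linear-time class). The empty graph
#' and any graph with fewer than 9 edges are planar.
#'
#' @param edges Two-column matrix or data frame of vertex pairs (integers
#'   starting at 1).
#' @param n Number of vertices; defaults to the largest endpoint.
#' @return `TRUE` iff the graph is planar.
#' @examples
#' is_planar(t(combn(4, 2))) # K4
#' is_planar(t(combn(5, 2))) # K5
#' @export
is_planar <- function(edges, n = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    return(TRUE)
  }
  if (ncol(edges) < 2L) stop("edges must have two columns", call. = FALSE)
  edges <- cbind(
    as.integer(pmin(edges[, 1L], edges[, 2L])),
    as.integer(pmax(edges[, 1L], edges[, 2L]))
  )
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  edges <- unique(edges)
  if (is.null(n)) n <- max(edges)
  .lr_is_planar(as.integer(n), edges)
}

#' Build the Planar Maximally Filtered Graph
#'
#' Constructs the PMFG from a similarity matrix: candidate edges are ranked
#' by decreasing similarity (ties broken lexicographically by vertex pair)
#' and inserted greedily, keeping an edge if and only if the graph stays
#' planar, until the maximal planar count of \eqn{3(n-2)} edges is reached.
#' The result is a connected maximal planar graph -- a triangulation of the
#' topological sphere -- retaining the most relevant links without any
#' thresholding; negative similarities are allowed and simply rank last.
#'
#' @param similarity Symmetric n x n similarity matrix (n >= 3); larger
#'   values mean more similar. The diagonal is ignored.
#' @param dissimilarity Optional symmetric non-negative n x n dissimilarity
#'   matrix carried onto the edges (used downstream for shortest paths). If
#'   omitted and all similarities lie in \[-1, 1\], the correlation distance
#'   \eqn{\sqrt{2(1-w)}} is used.
#' @return An object of class `pmfg`: a list with `n`, `labels`, and
#'   `edges`, a tibble with columns `i`, `j`, `w`, `d`.
#' @examples
#' s <- pearson_similarity(matrix(rnorm(5 * 40), 5))
#' g <- build_pmfg(s$similarity, s$dissimilarity)
#' nrow(g$edges) # 3 * (5 - 2)
#' @export
build_pmfg <- function(similarity, dissimilarity = NULL) {
  w <- check_symmetric(similarity, "similarity")
  n <- nrow(w)
  if (n < 3L) stop("need at least 3 elements", call. = FALSE)
  labels <- default_labels(n, rownames(similarity))
  if (is.null(dissimilarity)) {
    if (max(w) > 1 + 1e-8 || min(w) < -1 - 1e-8) {
      stop(
        "cannot derive a correlation distance from similarities outside ",
        "[-1, 1]; supply `dissimilarity`",
        call. = FALSE
      )
    }
    d <- sqrt(pmax(2 * (1 - w), 0))
  } else {
    d <- check_symmetric(dissimilarity, "dissimilarity")
    if (nrow(d) != n) stop("similarity and dissimilarity sizes differ", call. = FALSE)
    if (min(d) < 0) stop("dissimilarity must be non-negative", call. = FALSE)
  }
  ij <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[ij], ij[, 1L], ij[, 2L])
  cand <- ij[ord, , drop = FALSE]
  sel <- .pmfg_select(n, cand)
  kept <- cand[sel, , drop = FALSE]
  edges <- tibble::tibble(
    i = as.integer(kept[, 1L]),
    j = as.integer(kept[, 2L]),
    w = w[kept],
    d = d[kept]
  )
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  structure(
    list(n = n, labels = labels, edges = edges),
    class = "pmfg"
  )
}

#' @export
print.pmfg <- function(x, ...) {
  cat(
    "Planar Maximally Filtered Graph:", x$n, "vertices,",
    nrow(x$edges), "edges\n"
  )
  invisible(x)
}

#' Convert a PMFG to an igraph object
#'
#' Edge attributes `weight` (similarity) and `distance` (dissimilarity) are
#' carried over.
#' @param g A `pmfg` object.
#' @return An [igraph::igraph] graph.
#' @export
pmfg_igraph <- function(g) {
  stopifnot(inherits(g, "pmfg"))
  ig <- igraph::graph_from_edgelist(cbind(g$edges$i, g$edges$j), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n - igraph::vcount(ig)))
  igraph::V(ig)$name <- g$labels
  igraph::E(ig)$weight <- g$edges$w
  igraph::E(ig)$distance <- g$edges$d
  ig
}

#' All-pairs shortest-path distances on the PMFG
#'
#' Shortest paths use the edge dissimilarities `d` as lengths (not hop
#' counts): the distance between two vertices is the smallest sum of edge
#' dissimilarities over any connecting path.
#' @param g A `pmfg` object.
#' @return A symmetric n x n matrix of path distances.
#' @export
pmfg_distances <- function(g) {
  stopifnot(inherits(g, "pmfg"))
  ig <- pmfg_igraph(g)
  D <- igraph::distances(ig, weights = igraph::E(ig)$distance, algorithm = "dijkstra")
  dimnames(D) <- list(g$labels, g$labels)
  D
}

#' Dense adjacency / similarity-weight matrices of a PMFG
#' @noRd
pmfg_adjacency <- function(g, values = c("indicator", "weight")) {
  values <- match.arg(values)
  A <- matrix(0, g$n, g$n)
  idx <- cbind(g$edges$i, g$edges$j)
  v <- if (values == "indicator") 1 else g$edges$w
  A[idx] <- v
  A[idx[, c(2L, 1L)]] <- v
  A
}
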