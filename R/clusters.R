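#' Attachment strength of a vertex to a bubble
#'
#' The strength used to resolve vertices shared by several bubbles: the sum
#' of PMFG similarity weights on the vertex's edges into the bubble,
#' normalized by the bubble's edge count, so large bubbles do not win merely
#' by offering more places to attach.
#' @noRd
chi_strength <- function(W, A, edge_count, v, bubble_vs, bubble_id) {
  vs <- setdiff(bubble_vs, v)
  s <- sum(W[v, vs] * A[v, vs])
  s / edge_count[bubble_id]
}

#' Per-bubble edge counts of the induced subgraphs
#' @noRd
bubble_edge_counts <- function(g, bubbles) {
  vapply(bubbles, function(vs) {
    sum(g$edges$i %in% vs & g$edges$j %in% vs)
  }, numeric(1))
}

#' Discrete DBHT clustering from a directed bubble tree
#'
#' Produces the unique partition of the vertex set anchored at the
#' converging bubbles, in two steps. First, vertices lying in converging
#' bubbles are assigned: a vertex in exactly one converging bubble goes to
#' it; a vertex in several goes to the one with the largest attachment
#' strength. Second, every remaining vertex is assigned to the converging
#' bubble (among those whose subtree contains one of the vertex's bubbles,
#' falling back to all non-empty anchors) with the minimum mean shortest-path
#' distance to the anchor's already-assigned vertex set, shortest paths being
#' measured on the PMFG with the edge dissimilarities as lengths. Converging
#' bubbles left with an empty vertex set spawn no cluster. Ties in either
#' step go to the smaller canonical bubble id.
#'
#' @param g A `pmfg` object.
#' @param dbt A `directed_bubble_tree` built from `g`.
#' @param distances Optional precomputed [pmfg_distances()] matrix.
#' @return An object of class `dbht_clusters`: `labels` (integer cluster id
#'   per vertex, named by element label), `anchors` (tibble mapping cluster
#'   id to its converging bubble), and `anchor_sets` (step-one vertex sets).
#' @export
dbht_clusters <- function(g, dbt, distances = NULL) {
  stopifnot(inherits(g, "pmfg"), inherits(dbt, "directed_bubble_tree"))
  n <- g$n
  W <- pmfg_adjacency(g, "weight")
  A <- pmfg_adjacency(g, "indicator")
  ec <- bubble_edge_counts(g, dbt$bubbles)
  conv <- which(dbt$kind == "converging")
  if (!length(conv)) stop("internal error: no converging bubble", call. = FALSE)

  # step 1: vertices inside converging bubbles
  assigned_bubble <- rep(NA_integer_, n) # converging bubble id per vertex
  in_conv <- lapply(conv, function(b) dbt$bubbles[[b]])
  count <- integer(n)
  for (s in seq_along(conv)) count[in_conv[[s]]] <- count[in_conv[[s]]] + 1L
  for (v in which(count == 1L)) {
    s <- which(vapply(in_conv, function(vs) v %in% vs, logical(1)))
    assigned_bubble[v] <- conv[s]
  }
  for (v in which(count > 1L)) {
    cand <- conv[vapply(in_conv, function(vs) v %in% vs, logical(1))]
    chi <- vapply(cand, function(b) {
      chi_strength(W, A, ec, v, dbt$bubbles[[b]], b)
    }, numeric(1))
    assigned_bubble[v] <- cand[which.max(chi)] # which.max: first (smallest id) on ties
  }

  # step 2: remaining vertices, by mean shortest-path distance to anchor sets
  if (is.null(distances)) distances <- pmfg_distances(g)
  subtrees <- converging_subtrees(dbt)
  vert_bubbles <- vector("list", n)
  for (b in seq_along(dbt$bubbles)) {
    for (v in dbt$bubbles[[b]]) vert_bubbles[[v]] <- c(vert_bubbles[[v]], b)
  }
  anchor_set <- lapply(conv, function(b) which(assigned_bubble == b))
  nonempty <- conv[vapply(anchor_set, length, integer(1)) > 0L]
  for (v in which(is.na(assigned_bubble))) {
    cand <- conv[vapply(seq_along(conv), function(s) {
      any(vert_bubbles[[v]] %in% subtrees[[s]])
    }, logical(1))]
    cand <- intersect(cand, nonempty)
    if (!length(cand)) cand <- nonempty
    # anchor sets are the step-one sets, frozen, so the result does not
    # depend on the order in which residual vertices are visited
    dbar <- vapply(cand, function(b) {
      mean(distances[v, anchor_set[[match(b, conv)]]])
    }, numeric(1))
    assigned_bubble[v] <- cand[which.min(dbar)]
  }

  anchors_used <- sort(unique(assigned_bubble))
  labels <- match(assigned_bubble, anchors_used)
  names(labels) <- g$labels
  structure(
    list(
      labels = as.integer(labels),
      anchors = tibble::tibble(
        cluster = seq_along(anchors_used),
        bubble = as.integer(anchors_used)
      ),
      anchor_bubble = as.integer(assigned_bubble),
      anchor_sets = anchor_set
    ),
    class = "dbht_clusters"
  )
}

#' @export
print.dbht_clusters <- function(x, ...) {
  cat(
    "DBHT discrete clustering:", max(x$labels), "clusters over",
    length(x$labels), "elements\n"
  )
  invisible(x)
}
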