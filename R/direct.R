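#' Direct the bubble tree and classify bubbles
#'
#' Each bubble-tree link, labelled by a separating 3-clique, is directed by
#' comparing the total PMFG similarity flowing from the clique into the two
#' sides of the tree: for a side with vertex set \eqn{V_s}, the side weight
#' is \eqn{\sum_{i \in k} \sum_{j \in V_s \setminus k} A_{ij} w_{ij}}
#' (clique-internal edges, common to both sides, are excluded). The link
#' points toward the heavier side. On an exact tie the two endpoint bubbles
#' are joined into a single larger bubble and the directions are re-derived
#' on the contracted tree until no ties remain.
#'
#' Bubbles are then classified: *converging* when all incident links point
#' inward (the sinks of the strongest-connection flow, taken as cluster
#' centres), *diverging* when all point outward, *passage* otherwise. An
#' isolated single bubble is classified converging.
#'
#' @param g A `pmfg` object.
#' @param bt The [build_bubble_tree()] result for `g`.
#' @return An object of class `directed_bubble_tree`: `bubbles`, `links`
#'   (with direction column `to` and side weights `w_a`, `w_b`), `kind`
#'   (per-bubble classification), and `merged` (number of tie merges
#'   performed).
#' @export
direct_bubble_tree <- function(g, bt) {
  stopifnot(inherits(g, "pmfg"), inherits(bt, "bubble_tree"))
  W <- pmfg_adjacency(g, "weight")
  A <- pmfg_adjacency(g, "indicator")

  bubbles <- bt$bubbles
  links <- bt$links
  merged <- 0L

  repeat {
    nb <- length(bubbles)
    if (nrow(links) == 0L) break
    # split the tree at each link and compute the two side weights
    nbrs <- vector("list", nb)
    for (r in seq_len(nrow(links))) {
      nbrs[[links$a[r]]] <- c(nbrs[[links$a[r]]], r)
      nbrs[[links$b[r]]] <- c(nbrs[[links$b[r]]], r)
    }
    side_bubbles <- function(start, banned_link) {
      seen <- logical(nb)
      seen[start] <- TRUE
      queue <- start
      while (length(queue)) {
        x <- queue[[1L]]
        queue <- queue[-1L]
        for (r in nbrs[[x]]) {
          if (r == banned_link) next
          y <- if (links$a[r] == x) links$b[r] else links$a[r]
          if (!seen[y]) {
            seen[y] <- TRUE
            queue <- c(queue, y)
          }
        }
      }
      which(seen)
    }
    w_a <- w_b <- numeric(nrow(links))
    for (r in seq_len(nrow(links))) {
      k <- links$clique[[r]]
      va <- unique(unlist(bubbles[side_bubbles(links$a[r], r)]))
      vb <- unique(unlist(bubbles[side_bubbles(links$b[r], r)]))
      w_a[r] <- sum(W[k, setdiff(va, k)] * A[k, setdiff(va, k)])
      w_b[r] <- sum(W[k, setdiff(vb, k)] * A[k, setdiff(vb, k)])
    }
    ties <- which(w_a == w_b)
    if (!length(ties)) {
      links$w_a <- w_a
      links$w_b <- w_b
      links$to <- ifelse(w_a > w_b, links$a, links$b)
      break
    }
    # merge the first tied link (canonical order) and re-derive
    r <- ties[[1L]]
    a <- links$a[r]
    b <- links$b[r]
    joined <- sort(union(bubbles[[a]], bubbles[[b]]))
    keep <- setdiff(seq_len(nb), c(a, b))
    new_ids <- integer(nb)
    new_ids[keep] <- seq_along(keep)
    new_ids[c(a, b)] <- length(keep) + 1L
    bubbles <- c(bubbles[keep], list(joined))
    links <- links[-r, , drop = FALSE]
    links$a <- new_ids[links$a]
    links$b <- new_ids[links$b]
    swap <- links$a > links$b
    tmp <- links$a[swap]
    links$a[swap] <- links$b[swap]
    links$b[swap] <- tmp
    # re-canonicalize bubble order
    keys <- vapply(bubbles, function(x) paste(x, collapse = ","), character(1))
    ord <- order(keys)
    rank <- match(seq_along(bubbles), ord)
    bubbles <- bubbles[ord]
    links$a0 <- rank[links$a]
    links$b0 <- rank[links$b]
    links$a <- pmin(links$a0, links$b0)
    links$b <- pmax(links$a0, links$b0)
    links$a0 <- links$b0 <- NULL
    links <- links[order(links$a, links$b), , drop = FALSE]
    merged <- merged + 1L
  }

  nb <- length(bubbles)
  kind <- character(nb)
  if (nrow(links) == 0L) {
    kind[] <- "converging"
    links$w_a <- links$w_b <- numeric(0)
    links$to <- integer(0)
  } else {
    for (x in seq_len(nb)) {
      inc <- which(links$a == x | links$b == x)
      if (!length(inc)) {
        kind[x] <- "converging" # isolated bubble: trivially a sink
      } else if (all(links$to[inc] == x)) {
        kind[x] <- "converging"
      } else if (all(links$to[inc] != x)) {
        kind[x] <- "diverging"
      } else {
        kind[x] <- "passage"
      }
    }
  }
  links$to <- as.integer(links$to)

  structure(
    list(
      n = bt$n, bubbles = bubbles, links = links, kind = kind,
      merged = merged
    ),
    class = "directed_bubble_tree"
  )
}

#' @export
print.directed_bubble_tree <- function(x, ...) {
  cat(
    "Directed bubble tree:", length(x$bubbles), "bubbles (",
    sum(x$kind == "converging"), "converging,",
    sum(x$kind == "diverging"), "diverging,",
    sum(x$kind == "passage"), "passage )\n"
  )
  invisible(x)
}

#' Converging subtrees of a directed bubble tree
#'
#' For each converging bubble, returns the set of bubbles with a directed
#' path toward it. Subtrees may overlap: this is the non-discrete stage of
#' the clustering, before vertices are uniquely assigned.
#'
#' @param dbt A `directed_bubble_tree`.
#' @return Named list mapping each converging bubble id to the integer ids
#'   of the bubbles in its subtree (the converging bubble included).
#' @export
converging_subtrees <- function(dbt) {
  stopifnot(inherits(dbt, "directed_bubble_tree"))
  nb <- length(dbt$bubbles)
  conv <- which(dbt$kind == "converging")
  links <- dbt$links
  nbrs <- vector("list", nb)
  for (r in seq_len(nrow(links))) {
    nbrs[[links$a[r]]] <- c(nbrs[[links$a[r]]], r)
    nbrs[[links$b[r]]] <- c(nbrs[[links$b[r]]], r)
  }
  out <- lapply(conv, function(cb) {
    seen <- logical(nb)
    seen[cb] <- TRUE
    queue <- cb
    while (length(queue)) {
      x <- queue[[1L]]
      queue <- queue[-1L]
      for (r in nbrs[[x]]) {
        y <- if (links$a[r] == x) links$b[r] else links$a[r]
        # expand to y only if the link is directed from y toward x's side
        if (!seen[y] && links$to[r] == x) {
          seen[y] <- TRUE
          queue <- c(queue, y)
        }
      }
    }
    which(seen)
  })
  names(out) <- as.character(conv)
  out
}
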