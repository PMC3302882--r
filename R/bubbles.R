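#' Enumerate the 3-cliques of a PMFG
#'
#' Lists every vertex triple inducing a triangle, in canonical sorted order,
#' and flags the separating ones. In a maximal planar graph triangles are the
#' faces plus any separating 3-cliques, so their number is close to
#' \eqn{2n - 4}.
#'
#' @param g A `pmfg` object.
#' @return A tibble with columns `v1 < v2 < v3` and `separating`.
#' @export
enumerate_3cliques <- function(g) {
  stopifnot(inherits(g, "pmfg"))
  adj <- adjacency_list(g$n, g$edges)
  tri <- list()
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$i[r]
    j <- g$edges$j[r]
    common <- intersect(adj[[i]], adj[[j]])
    common <- common[common > j] # canonical i < j < k, counted once
    for (k in common) tri[[length(tri) + 1L]] <- c(i, j, k)
  }
  if (!length(tri)) {
    return(tibble::tibble(
      v1 = integer(0), v2 = integer(0), v3 = integer(0),
      separating = logical(0)
    ))
  }
  m <- do.call(rbind, tri)
  m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  sep <- vapply(
    seq_len(nrow(m)),
    function(r) is_separating_clique(g, m[r, ], adj = adj),
    logical(1)
  )
  tibble::tibble(
    v1 = as.integer(m[, 1L]), v2 = as.integer(m[, 2L]),
    v3 = as.integer(m[, 3L]), separating = sep
  )
}

#' Is a triangle a separating 3-clique?
#'
#' A 3-clique separates the graph when deleting its three vertices (and
#' incident edges) leaves at least two connected components among the
#' remaining vertices.
#'
#' @param g A `pmfg` object.
#' @param members Integer vector of the 3 clique vertices.
#' @param adj Optional precomputed adjacency list.
#' @return `TRUE` iff the clique is separating.
#' @export
is_separating_clique <- function(g, members, adj = NULL) {
  stopifnot(inherits(g, "pmfg"))
  members <- sort(as.integer(members))
  if (length(members) != 3L) stop("a 3-clique has exactly 3 members", call. = FALSE)
  if (is.null(adj)) adj <- adjacency_list(g$n, g$edges)
  ok <- all(
    members[2L] %in% adj[[members[1L]]],
    members[3L] %in% adj[[members[1L]]],
    members[3L] %in% adj[[members[2L]]]
  )
  if (!ok) stop("members do not induce a triangle of the graph", call. = FALSE)
  rest <- setdiff(seq_len(g$n), members)
  if (!length(rest)) {
    return(FALSE)
  }
  length(induced_components(adj, rest)) >= 2L
}

#' Decompose a PMFG into its bubble tree
#'
#' Recursively subdivides the graph at every separating 3-clique: each such
#' clique splits its current part into the interior plus the clique and the
#' exterior plus the clique, both again maximal planar. The terminal parts
#' are the bubbles; two bubbles are linked when a separating 3-clique joins
#' them, and the links form a tree with (number of separating 3-cliques + 1)
#' nodes.
#'
#' @param g A `pmfg` object.
#' @return An object of class `bubble_tree`: a list with `n`, `bubbles`
#'   (list of sorted vertex-id vectors, canonically ordered), `links`
#'   (tibble `a`, `b`, `clique` list-column), and `sep_cliques`.
#' @export
build_bubble_tree <- function(g) {
  stopifnot(inherits(g, "pmfg"))
  adj <- adjacency_list(g$n, g$edges)
  cl <- enumerate_3cliques(g)
  sep <- cl[cl$separating, c("v1", "v2", "v3")]
  sep_cliques <- lapply(seq_len(nrow(sep)), function(r) {
    c(sep$v1[r], sep$v2[r], sep$v3[r])
  })

  bubbles <- list()
  links <- list() # list of list(a_set=, b_set=, clique=)

  # recursive subdivision; returns the vertex sets of the bubbles carved out
  split_part <- function(vs, clique_ids) {
    for (pos in seq_along(clique_ids)) {
      cid <- clique_ids[pos]
      k <- sep_cliques[[cid]]
      comps <- induced_components(adj, setdiff(vs, k))
      if (length(comps) < 2L) next # defensive: cannot split this part
      parts <- lapply(comps, function(cc) sort(union(cc, k)))
      remaining <- clique_ids[-seq_len(pos)]
      dropped <- clique_ids[seq_len(pos - 1L)]
      part_cliques <- lapply(parts, function(p) {
        keep <- vapply(
          c(dropped, remaining),
          function(id) all(sep_cliques[[id]] %in% p), logical(1)
        )
        c(dropped, remaining)[keep]
      })
      sub <- lapply(seq_along(parts), function(s) {
        split_part(parts[[s]], part_cliques[[s]])
      })
      # link: on each side, the bubble that contains the splitting clique
      hub <- NULL
      for (s in seq_along(sub)) {
        holder <- Filter(function(b) all(k %in% b), sub[[s]])
        holder <- holder[[1L]]
        if (is.null(hub)) {
          hub <- holder
        } else {
          links[[length(links) + 1L]] <<- list(
            a_set = hub, b_set = holder, clique = sort(k)
          )
        }
      }
      return(do.call(c, sub))
    }
    bubbles[[length(bubbles) + 1L]] <<- sort(vs)
    list(sort(vs))
  }

  split_part(seq_len(g$n), seq_along(sep_cliques))

  # canonical bubble order: by vertex set
  keys <- vapply(bubbles, function(b) paste(b, collapse = ","), character(1))
  ord <- order(keys)
  bubbles <- bubbles[ord]
  keys <- keys[ord]
  find_bubble <- function(set) match(paste(set, collapse = ","), keys)
  link_tbl <- tibble::tibble(
    a = vapply(links, function(l) find_bubble(l$a_set), numeric(1)),
    b = vapply(links, function(l) find_bubble(l$b_set), numeric(1)),
    clique = lapply(links, function(l) l$clique)
  )
  swap <- !is.na(link_tbl$a) & !is.na(link_tbl$b) & link_tbl$a > link_tbl$b
  tmp <- link_tbl$a[swap]
  link_tbl$a[swap] <- link_tbl$b[swap]
  link_tbl$b[swap] <- tmp
  link_tbl <- link_tbl[order(link_tbl$a, link_tbl$b), ]
  link_tbl$a <- as.integer(link_tbl$a)
  link_tbl$b <- as.integer(link_tbl$b)

  structure(
    list(
      n = g$n, bubbles = bubbles, links = link_tbl,
      sep_cliques = sep_cliques
    ),
    class = "bubble_tree"
  )
}

#' @export
print.bubble_tree <- function(x, ...) {
  cat(
    "Bubble tree:", length(x$bubbles), "bubbles,",
    nrow(x$links), "separating 3-clique links\n"
  )
  invisible(x)
}

#' Vertex-to-bubble membership matrix (vertices x bubbles, 0/1)
#' @noRd
bubble_membership <- function(bt) {
  M <- matrix(0L, bt$n, length(bt$bubbles))
  for (b in seq_along(bt$bubbles)) M[bt$bubbles[[b]], b] <- 1L
  M
}
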