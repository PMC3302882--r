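#' Assign every vertex to one bubble of its cluster's subtree
#'
#' Vertices in converging bubbles keep their discrete-clustering assignment;
#' vertices in exactly one bubble of the subtree keep that bubble; vertices
#' in several take the bubble with the largest attachment strength (ties to
#' the smaller canonical id).
#'
#' @param g A `pmfg` object.
#' @param dbt A `directed_bubble_tree`.
#' @param clusters A [dbht_clusters()] result.
#' @return Integer vector: bubble id per vertex.
#' @export
assign_vertices_to_bubbles <- function(g, dbt, clusters) {
  stopifnot(inherits(clusters, "dbht_clusters"))
  n <- g$n
  W <- pmfg_adjacency(g, "weight")
  A <- pmfg_adjacency(g, "indicator")
  ec <- bubble_edge_counts(g, dbt$bubbles)
  subtrees <- converging_subtrees(dbt)
  conv <- as.integer(names(subtrees))
  vert_bubbles <- vector("list", n)
  for (b in seq_along(dbt$bubbles)) {
    for (v in dbt$bubbles[[b]]) vert_bubbles[[v]] <- c(vert_bubbles[[v]], b)
  }
  out <- integer(n)
  for (v in seq_len(n)) {
    anchor <- clusters$anchor_bubble[v]
    if (v %in% dbt$bubbles[[anchor]]) {
      out[v] <- anchor # step-one vertices stay in their converging bubble
      next
    }
    st <- subtrees[[match(anchor, conv)]]
    cand <- intersect(vert_bubbles[[v]], st)
    if (!length(cand)) cand <- st # residual fallback vertex: nearest by strength
    if (length(cand) == 1L) {
      out[v] <- cand
    } else {
      chi <- vapply(cand, function(b) {
        chi_strength(W, A, ec, v, dbt$bubbles[[b]], b)
      }, numeric(1))
      out[v] <- cand[which.max(chi)]
    }
  }
  out
}

#' Complete-linkage merge events for one level
#'
#' Agglomerates `groups` (a list of leaf-id vectors) under the distance
#' matrix `dmat` (complete linkage) and returns merge events as lists with
#' the left/right leaf sets and the merge height.
#' @noRd
linkage_events <- function(dmat, groups, level) {
  k <- length(groups)
  if (k < 2L) {
    return(list())
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  members <- vector("list", k - 1L)
  events <- vector("list", k - 1L)
  side_members <- function(id) {
    if (id < 0L) groups[[-id]] else members[[id]]
  }
  for (r in seq_len(k - 1L)) {
    left <- side_members(hc$merge[r, 1L])
    right <- side_members(hc$merge[r, 2L])
    members[[r]] <- c(left, right)
    events[[r]] <- list(
      left = left, right = right,
      height = hc$height[r], level = level
    )
  }
  events
}

#' Build the full three-level DBHT dendrogram
#'
#' Assembles one monotone merge tree over all N elements from three
#' complete-linkage levels computed on PMFG shortest-path distances:
#' within each bubble's vertex set (intra-bubble), between the bubbles of
#' each cluster (intra-cluster, inter-bubble distance = maximum pairwise
#' shortest-path distance between the bubbles' vertex sets), and between
#' the clusters (inter-cluster, same complete-linkage distance between the
#' clusters' vertex sets). The three levels use different distance scales,
#' so each level's heights are affinely offset just enough that its smallest
#' merge strictly exceeds the previous level's largest; the offsets are
#' recorded in the result and cutting the tree at the discrete-cluster count
#' reproduces the discrete partition exactly.
#'
#' @param g A `pmfg` object.
#' @param dbt A `directed_bubble_tree`.
#' @param clusters A [dbht_clusters()] result.
#' @param distances Optional precomputed [pmfg_distances()] matrix.
#' @return An [stats::hclust]-compatible object with extra attributes
#'   `merge_level` (per-merge tag: `intra_bubble`, `intra_cluster`,
#'   `inter_cluster`) and `level_offsets`.
#' @export
build_full_dendrogram <- function(g, dbt, clusters, distances = NULL) {
  n <- g$n
  if (is.null(distances)) distances <- pmfg_distances(g)
  v2b <- assign_vertices_to_bubbles(g, dbt, clusters)

  cluster_ids <- sort(unique(clusters$labels))
  events <- list()

  # level 1: complete linkage inside each bubble's assigned vertex set;
  # the unit is the (cluster, bubble) pair, since a bubble shared by two
  # overlapping subtrees can host vertices of different clusters
  for (cl in cluster_ids) {
    vs_cl <- which(clusters$labels == cl)
    for (b in sort(unique(v2b[vs_cl]))) {
      vs <- intersect(which(v2b == b), vs_cl)
      if (length(vs) < 2L) next
      events <- c(
        events,
        linkage_events(distances[vs, vs, drop = FALSE],
          as.list(vs),
          level = "intra_bubble"
        )
      )
    }
  }

  # level 2: complete linkage between the bubbles of each cluster
  set_dist <- function(sets) {
    k <- length(sets)
    dm <- matrix(0, k, k)
    for (p in seq_len(k - 1L)) {
      for (q in (p + 1L):k) {
        dm[p, q] <- dm[q, p] <-
          max(distances[sets[[p]], sets[[q]], drop = FALSE])
      }
    }
    dm
  }
  for (cl in cluster_ids) {
    vs_cl <- which(clusters$labels == cl)
    bubs <- sort(unique(v2b[vs_cl]))
    sets <- lapply(bubs, function(b) intersect(which(v2b == b), vs_cl))
    if (length(sets) < 2L) next
    events <- c(
      events,
      linkage_events(set_dist(sets), sets, level = "intra_cluster")
    )
  }

  # level 3: complete linkage between the clusters
  csets <- lapply(cluster_ids, function(cl) which(clusters$labels == cl))
  if (length(csets) >= 2L) {
    events <- c(
      events,
      linkage_events(set_dist(csets), csets, level = "inter_cluster")
    )
  }

  stopifnot(length(events) == n - 1L)

  # stitch levels: offset so that each level starts strictly above the last
  lv <- vapply(events, function(e) e$level, character(1))
  ht <- vapply(events, function(e) e$height, numeric(1))
  eps <- 1e-8 * max(1, ht)
  offsets <- c(intra_bubble = 0, intra_cluster = 0, inter_cluster = 0)
  running_max <- if (any(lv == "intra_bubble")) max(ht[lv == "intra_bubble"]) else 0
  for (level in c("intra_cluster", "inter_cluster")) {
    idx <- which(lv == level)
    if (!length(idx)) next
    shift <- max(0, running_max - min(ht[idx])) + eps
    offsets[[level]] <- shift
    ht[idx] <- ht[idx] + shift
    running_max <- max(ht[idx])
  }

  # assemble an hclust merge table in non-decreasing height order
  lvrank <- match(lv, c("intra_bubble", "intra_cluster", "inter_cluster"))
  ord <- order(ht, lvrank)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node_of <- rep(NA_integer_, n) # current root (merge row) holding each leaf
  for (r in seq_along(ord)) {
    e <- events[[ord[r]]]
    lrep <- e$left[[1L]]
    rrep <- e$right[[1L]]
    lnode <- if (is.na(node_of[lrep])) -as.integer(lrep) else node_of[lrep]
    rnode <- if (is.na(node_of[rrep])) -as.integer(rrep) else node_of[rrep]
    merge[r, ] <- sort(c(lnode, rnode))
    height[r] <- ht[ord[r]]
    node_of[unlist(c(e$left, e$right))] <- r
  }
  if (is.unsorted(height)) {
    stop("internal error: dendrogram heights are not monotone", call. = FALSE)
  }

  hc <- structure(
    list(
      merge = merge, height = height,
      order = dendrogram_order(merge, n),
      labels = g$labels, method = "dbht",
      dist.method = "pmfg shortest path",
      call = match.call()
    ),
    class = "hclust"
  )
  attr(hc, "merge_level") <- lv[ord]
  attr(hc, "level_offsets") <- offsets
  hc
}

#' Leaf order for plotting, from a merge matrix
#' @noRd
dendrogram_order <- function(merge, n) {
  walk <- function(id) {
    if (id < 0L) {
      return(-id)
    }
    c(walk(merge[id, 1L]), walk(merge[id, 2L]))
  }
  as.integer(walk(n - 1L))
}

#' Cut a DBHT dendrogram into k groups
#'
#' The partition induced by removing the k - 1 highest merges. Cutting at
#' the number of discrete clusters reproduces the discrete DBHT partition
#' exactly; cutting above it walks the inter-cluster hierarchy, below it the
#' intra-cluster and intra-bubble structure.
#'
#' @param x A `dbht` fit or an `hclust` object.
#' @param k Number of groups, between 1 and N.
#' @return Integer vector of group memberships named by element label.
#' @export
dbht_cut <- function(x, k) {
  hc <- if (inherits(x, "dbht")) x$hierarchy else x
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n, call. = FALSE)
  stats::cutree(hc, k = k)
}
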