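# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately brute-force and shares no code with the
# package internals it checks.

# ---- graph fixtures ---------------------------------------------------------

edges_k <- function(n) t(utils::combn(n, 2))

# complete bipartite K_{a,b} on vertices 1..a and (a+1)..(a+b)
edges_k_bipartite <- function(a, b) {
  as.matrix(expand.grid(seq_len(a), a + seq_len(b)))
}

# chain of tetrahedra: K4 on 1..4, then each new vertex v is glued onto the
# triangle {v-3, v-2, v-1}; maximal planar with a path-shaped bubble tree
tetra_chain_edges <- function(n) {
  stopifnot(n >= 4)
  ed <- edges_k(4)
  for (v in seq(5, length.out = max(0, n - 4))) {
    ed <- rbind(ed, cbind(c(v - 3, v - 2, v - 1), v))
  }
  ed
}

# weight matrix that forces build_pmfg to reproduce a given maximal planar
# graph: its edges get weight 2, everything else 1 (planarity rejects all
# non-edges once the target graph is complete)
weights_for_graph <- function(n, ed) {
  w <- matrix(1, n, n)
  for (r in seq_len(nrow(ed))) {
    w[ed[r, 1], ed[r, 2]] <- w[ed[r, 2], ed[r, 1]] <- 2
  }
  diag(w) <- 0
  w
}

# random similarity/dissimilarity pair with distinct weights
random_affinity <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2)
  w <- w + t(w)
  list(w = w, d = sqrt(2 * (1 - w)) * (1 - diag(n)))
}

random_pmfg <- function(n, seed) {
  aff <- random_affinity(n, seed)
  build_pmfg(aff$w, aff$d)
}

# ---- Kuratowski-subdivision planarity oracle --------------------------------

# TRUE iff the graph contains a subdivision of the pattern whose branch
# vertices are `branch` and whose required connections are `pairs` (rows),
# realized by internally vertex-disjoint paths.
has_subdivision_at <- function(adj, branch, pairs) {
  connect <- function(idx, used) {
    if (idx > nrow(pairs)) {
      return(TRUE)
    }
    u <- pairs[idx, 1]
    v <- pairs[idx, 2]
    dfs <- function(cur, interior) {
      for (nb in adj[[cur]]) {
        if (nb == v) {
          if (connect(idx + 1, c(used, interior))) {
            return(TRUE)
          }
          break # only one way to finish at v from cur
        }
      }
      for (nb in adj[[cur]]) {
        if (nb %in% branch || nb %in% used || nb %in% interior) next
        if (dfs(nb, c(interior, nb))) {
          return(TRUE)
        }
      }
      FALSE
    }
    dfs(u, integer(0))
  }
  connect(1, integer(0))
}

oracle_is_planar <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]
    j <- edges[r, 2]
    adj[[i]] <- union(adj[[i]], j)
    adj[[j]] <- union(adj[[j]], i)
  }
  if (n >= 5) {
    for (branch in utils::combn(n, 5, simplify = FALSE)) {
      if (has_subdivision_at(adj, branch, t(utils::combn(branch, 2)))) {
        return(FALSE)
      }
    }
  }
  if (n >= 6) {
    for (six in utils::combn(n, 6, simplify = FALSE)) {
      for (apick in utils::combn(six, 3, simplify = FALSE)) {
        if (min(apick) != min(six)) next # each 3/3 split once
        bpick <- setdiff(six, apick)
        pairs <- as.matrix(expand.grid(apick, bpick))
        if (has_subdivision_at(adj, six, pairs)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# ---- brute-force agglomeration oracle ---------------------------------------

# complete-linkage agglomeration by direct scanning; returns the cophenetic
# distance matrix, which is invariant to the order in which ties are merged
oracle_complete_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (p in seq_len(length(groups) - 1L)) {
      for (q in (p + 1L):length(groups)) {
        d <- max(D[groups[[p]], groups[[q]]])
        if (d < best[1]) best <- c(d, p, q)
      }
    }
    p <- best[2]
    q <- best[3]
    coph[groups[[p]], groups[[q]]] <- best[1]
    coph[groups[[q]], groups[[p]]] <- best[1]
    groups[[p]] <- c(groups[[p]], groups[[q]])
    groups[[q]] <- NULL
  }
  coph
}

# ---- brute-force recursive bubble splitter ----------------------------------

# decomposition by local separation: split the current induced subgraph at
# its first separating triangle, recurse; returns the terminal vertex sets
oracle_bubbles <- function(g) {
  ed <- as.matrix(g$edges[, c("i", "j")])
  adj <- vector("list", g$n)
  for (r in seq_len(nrow(ed))) {
    adj[[ed[r, 1]]] <- union(adj[[ed[r, 1]]], ed[r, 2])
    adj[[ed[r, 2]]] <- union(adj[[ed[r, 2]]], ed[r, 1])
  }
  comps_within <- function(vs) {
    seen <- c()
    out <- list()
    for (s in vs) {
      if (s %in% seen) next
      comp <- s
      queue <- s
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- setdiff(intersect(adj[[v]], vs), comp)
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
      seen <- c(seen, comp)
      out[[length(out) + 1]] <- sort(comp)
    }
    out
  }
  split_rec <- function(vs) {
    if (length(vs) >= 4) {
      tris <- utils::combn(vs, 3, simplify = FALSE)
      for (k in tris) {
        if (!(k[2] %in% adj[[k[1]]] && k[3] %in% adj[[k[1]]] &&
          k[3] %in% adj[[k[2]]])) {
          next
        }
        parts <- comps_within(setdiff(vs, k))
        if (length(parts) >= 2) {
          return(do.call(c, lapply(parts, function(p) {
            split_rec(sort(union(p, k)))
          })))
        }
      }
    }
    list(sort(vs))
  }
  split_rec(seq_len(g$n))
}

set_of_sets <- function(x) {
  sort(vapply(x, function(s) paste(sort(s), collapse = ","), character(1)))
}

# ---- pair-counting adjusted Rand oracle -------------------------------------

oracle_ari <- function(a, b) {
  n <- length(a)
  together <- function(z) outer(z, z, "==")[upper.tri(diag(n))]
  ta <- together(a)
  tb <- together(b)
  n11 <- sum(ta & tb)
  sa <- sum(ta)
  sb <- sum(tb)
  tot <- n * (n - 1) / 2
  expected <- sa * sb / tot
  (n11 - expected) / ((sa + sb) / 2 - expected)
}
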