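fit_parts <- function(n, seed) {
  g <- random_pmfg(n, seed)
  bt <- build_bubble_tree(g)
  dbt <- direct_bubble_tree(g, bt)
  D <- pmfg_distances(g)
  cl <- dbht_clusters(g, dbt, distances = D)
  list(g = g, dbt = dbt, cl = cl, D = D)
}

test_that("the merge tree has N-1 monotone merges covering every leaf", {
  for (seed in c(3, 14, 25)) {
    n <- sample(10:24, 1)
    p <- fit_parts(n, seed)
    hc <- build_full_dendrogram(p$g, p$dbt, p$cl, p$D)
    expect_equal(nrow(hc$merge), n - 1)
    expect_false(is.unsorted(hc$height))
    expect_setequal(-hc$merge[hc$merge < 0], seq_len(n))
    expect_setequal(hc$order, seq_len(n))
    # every cut size is reachable
    for (k in c(1, 2, n - 1, n)) {
      expect_equal(length(unique(dbht_cut(hc, k))), k)
    }
    expect_error(dbht_cut(hc, n + 1), "between")
  }
})

test_that("level tags are ordered along the tree and offsets recorded", {
  p <- fit_parts(18, seed = 33)
  hc <- build_full_dendrogram(p$g, p$dbt, p$cl, p$D)
  lv <- attr(hc, "merge_level")
  ranks <- match(lv, c("intra_bubble", "intra_cluster", "inter_cluster"))
  expect_false(is.unsorted(ranks)) # heights sort the levels block-wise
  off <- attr(hc, "level_offsets")
  expect_named(off, c("intra_bubble", "intra_cluster", "inter_cluster"))
  if (any(lv == "inter_cluster") && any(lv != "inter_cluster")) {
    expect_gt(
      min(hc$height[lv == "inter_cluster"]),
      max(hc$height[lv != "inter_cluster"])
    )
  }
})

test_that("cutting at the discrete cluster count reproduces the discrete partition", {
  for (seed in c(7, 19, 42)) {
    n <- sample(12:24, 1)
    p <- fit_parts(n, seed)
    hc <- build_full_dendrogram(p$g, p$dbt, p$cl, p$D)
    k <- max(p$cl$labels)
    expect_equal(adjusted_rand(dbht_cut(hc, k), p$cl$labels), 1)
  }
})

test_that("each linkage level matches the brute-force agglomeration oracle", {
  # intra-bubble level: merge heights on a bubble's vertex set equal
  # complete linkage on the shortest-path submatrix
  p <- fit_parts(20, seed = 55)
  hc <- build_full_dendrogram(p$g, p$dbt, p$cl, p$D)
  v2b <- assign_vertices_to_bubbles(p$g, p$dbt, p$cl)
  for (b in unique(v2b)) {
    vs <- which(v2b == b)
    vs <- vs[p$cl$labels[vs] == p$cl$labels[vs[1]]]
    if (length(vs) < 3 || length(vs) > 12) next
    sub <- p$D[vs, vs]
    ref <- stats::hclust(stats::as.dist(sub), method = "complete")
    expect_equal(
      sort(stats::cophenetic(ref)),
      sort(stats::as.dist(oracle_complete_linkage_cophenetic(sub)))
    )
  }
  # generic check: hclust complete linkage (the engine behind every level)
  # agrees with the oracle on random matrices up to 12 items
  set.seed(77)
  for (trial in 1:5) {
    k <- sample(4:12, 1)
    D <- matrix(0, k, k)
    D[upper.tri(D)] <- runif(k * (k - 1) / 2)
    D <- D + t(D)
    ref <- stats::hclust(stats::as.dist(D), method = "complete")
    expect_equal(
      as.vector(as.matrix(stats::cophenetic(ref))),
      as.vector(oracle_complete_linkage_cophenetic(D))
    )
  }
})

test_that("three known points merge in the hand-computed order", {
  # distances: d(1,2)=1, d(1,3)=4, d(2,3)=2.5 -> 1+2 first at 1, then 3 at 4
  D <- matrix(c(0, 1, 4, 1, 0, 2.5, 4, 2.5, 0), 3, 3)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  expect_setequal(hc$merge[1, ], c(-2L, -1L))
  expect_equal(hc$height, c(1, 4))
})

test_that("the dendrogram exports to Newick and ape round-trips the leaves", {
  p <- fit_parts(12, seed = 66)
  hc <- build_full_dendrogram(p$g, p$dbt, p$cl, p$D)
  ph <- ape::as.phylo(hc)
  expect_setequal(ph$tip.label, p$g$labels)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(ph, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, p$g$labels)
})

test_that("a three-element single bubble gives two intra-bubble merges", {
  aff <- random_affinity(3, seed = 12)
  g <- build_pmfg(aff$w, aff$d)
  dbt <- direct_bubble_tree(g, build_bubble_tree(g))
  cl <- dbht_clusters(g, dbt)
  hc <- build_full_dendrogram(g, dbt, cl)
  expect_equal(nrow(hc$merge), 2)
  expect_equal(unique(attr(hc, "merge_level")), "intra_bubble")
})
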