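glued_tetrahedra <- function() {
  # two tetrahedra sharing the triangle {2,3,4}
  ed <- rbind(edges_k(4), cbind(c(2, 3, 4), 5))
  w <- weights_for_graph(5, ed)
  build_pmfg(w, max(w) - w)
}

test_that("triangle enumeration is exact on small fixtures", {
  g4 <- random_pmfg(4, seed = 2)
  expect_equal(nrow(enumerate_3cliques(g4)), 4) # K4 has 4 triangles

  g5 <- random_pmfg(5, seed = 2)
  tri <- enumerate_3cliques(g5)
  expect_equal(nrow(tri), 7) # brute force over C(5,3) triples of K5 minus an edge
  # canonical order, no duplicates
  expect_true(all(tri$v1 < tri$v2 & tri$v2 < tri$v3))
  expect_false(any(duplicated(tri[, 1:3])))
})

test_that("separating cliques are recognized", {
  g4 <- random_pmfg(4, seed = 5)
  tri <- enumerate_3cliques(g4)
  expect_false(any(tri$separating)) # removing any K4 triangle leaves 1 vertex

  g <- glued_tetrahedra()
  tri <- enumerate_3cliques(g)
  expect_equal(sum(tri$separating), 1)
  sep <- tri[tri$separating, ]
  expect_equal(c(sep$v1, sep$v2, sep$v3), c(2, 3, 4))
  expect_true(is_separating_clique(g, c(2, 3, 4)))
  expect_false(is_separating_clique(g, c(1, 2, 3)))
  expect_error(is_separating_clique(g, c(1, 2, 5)), "triangle")
})

test_that("glued tetrahedra decompose into two bubbles sharing the clique", {
  g <- glued_tetrahedra()
  bt <- build_bubble_tree(g)
  expect_equal(set_of_sets(bt$bubbles), c("1,2,3,4", "2,3,4,5"))
  expect_equal(nrow(bt$links), 1)
  expect_equal(bt$links$clique[[1]], c(2, 3, 4))
  expect_equal(
    sort(intersect(bt$bubbles[[bt$links$a[1]]], bt$bubbles[[bt$links$b[1]]])),
    c(2, 3, 4)
  )
})

test_that("a tetrahedron chain gives a path of tetrahedral bubbles", {
  n <- 9
  ed <- tetra_chain_edges(n)
  w <- weights_for_graph(n, ed)
  g <- build_pmfg(w, max(w) - w)
  bt <- build_bubble_tree(g)
  expect_equal(length(bt$bubbles), 6) # 5 separating cliques + 1
  expect_equal(nrow(bt$links), 5)
  expect_true(all(lengths(bt$bubbles) == 4))
})

test_that("bubble-tree invariants hold on random PMFGs", {
  for (seed in 21:28) {
    n <- sample(6:14, 1)
    g <- random_pmfg(n, seed)
    bt <- build_bubble_tree(g)
    n_sep <- sum(enumerate_3cliques(g)$separating)
    expect_equal(length(bt$bubbles), n_sep + 1)
    expect_equal(nrow(bt$links), n_sep)
    expect_setequal(unlist(bt$bubbles), seq_len(n)) # union covers all vertices
    # linked bubbles intersect exactly in their labelling clique
    for (r in seq_len(nrow(bt$links))) {
      expect_equal(
        sort(intersect(
          bt$bubbles[[bt$links$a[r]]],
          bt$bubbles[[bt$links$b[r]]]
        )),
        bt$links$clique[[r]]
      )
    }
  }
})

test_that("decomposition matches the brute-force recursive splitter", {
  for (seed in 31:38) {
    n <- sample(6:10, 1)
    g <- random_pmfg(n, seed)
    bt <- build_bubble_tree(g)
    expect_equal(set_of_sets(bt$bubbles), set_of_sets(oracle_bubbles(g)))
  }
})

test_that("bubbles are irreducible: re-decomposing one gives a single node", {
  g <- random_pmfg(12, seed = 44)
  bt <- build_bubble_tree(g)
  for (b in bt$bubbles) {
    if (length(b) < 4) next
    sub_w <- weights_for_graph(length(b), cbind(
      match(g$edges$i[g$edges$i %in% b & g$edges$j %in% b], b),
      match(g$edges$j[g$edges$i %in% b & g$edges$j %in% b], b)
    ))
    gb <- build_pmfg(sub_w, max(sub_w) - sub_w)
    btb <- build_bubble_tree(gb)
    expect_equal(length(btb$bubbles), 1)
  }
})
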