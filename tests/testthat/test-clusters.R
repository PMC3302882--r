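test_that("a single converging bubble yields one cluster", {
  g <- random_pmfg(6, seed = 70)
  dbt <- direct_bubble_tree(g, build_bubble_tree(g))
  cl <- dbht_clusters(g, dbt)
  if (sum(dbt$kind == "converging") == 1) {
    expect_equal(unique(cl$labels), 1L)
  }
  # degenerate single-bubble case always gives exactly one cluster
  g4 <- random_pmfg(4, seed = 71)
  cl4 <- dbht_clusters(g4, direct_bubble_tree(g4, build_bubble_tree(g4)))
  expect_equal(unname(cl4$labels), rep(1L, 4))
})

test_that("labels always form a partition anchored at converging bubbles", {
  for (seed in 81:90) {
    n <- sample(8:20, 1)
    g <- random_pmfg(n, seed)
    dbt <- direct_bubble_tree(g, build_bubble_tree(g))
    cl <- dbht_clusters(g, dbt)
    expect_length(cl$labels, n)
    expect_false(anyNA(cl$labels))
    k <- max(cl$labels)
    expect_setequal(unique(cl$labels), seq_len(k))
    expect_lte(k, sum(dbt$kind == "converging"))
    # anchors are distinct converging bubbles
    expect_false(any(duplicated(cl$anchors$bubble)))
    expect_true(all(dbt$kind[cl$anchors$bubble] == "converging"))
  }
})

test_that("step-one assignment maximizes the attachment strength", {
  # fixtures chosen so vertices shared between converging bubbles occur
  cases <- cbind(seed = c(17, 29, 33, 44, 50, 51), n = c(16, 20, 16, 16, 16, 20))
  n_shared <- 0
  for (row in seq_len(nrow(cases))) {
    seed <- cases[row, "seed"]
    n <- cases[row, "n"]
    g <- random_pmfg(n, seed)
    dbt <- direct_bubble_tree(g, build_bubble_tree(g))
    cl <- dbht_clusters(g, dbt)
    conv <- which(dbt$kind == "converging")
    W <- matrix(0, n, n)
    W[cbind(g$edges$i, g$edges$j)] <- g$edges$w
    W <- W + t(W)
    e_count <- vapply(dbt$bubbles, function(vs) {
      sum(g$edges$i %in% vs & g$edges$j %in% vs)
    }, numeric(1))
    for (v in seq_len(n)) {
      holding <- conv[vapply(conv, function(b) v %in% dbt$bubbles[[b]], logical(1))]
      if (length(holding) < 2) next
      chi <- vapply(holding, function(b) {
        sum(W[v, setdiff(dbt$bubbles[[b]], v)]) / e_count[b]
      }, numeric(1))
      expect_equal(
        cl$anchor_bubble[v], holding[which.max(chi)],
        info = sprintf("seed %d vertex %d", seed, v)
      )
      n_shared <- n_shared + 1
    }
  }
  expect_gt(n_shared, 0) # the fixtures do exercise the contested case
})

test_that("residual vertices go to the nearest anchor set by mean path distance", {
  for (seed in 97:99) {
    n <- 16
    g <- random_pmfg(n, seed)
    dbt <- direct_bubble_tree(g, build_bubble_tree(g))
    D <- pmfg_distances(g)
    cl <- dbht_clusters(g, dbt, distances = D)
    conv <- which(dbt$kind == "converging")
    in_conv <- unique(unlist(dbt$bubbles[conv]))
    step1 <- lapply(conv, function(b) {
      intersect(which(cl$anchor_bubble == b), in_conv)
    })
    st <- converging_subtrees(dbt)
    for (v in setdiff(seq_len(n), in_conv)) {
      vb <- which(vapply(dbt$bubbles, function(vs) v %in% vs, logical(1)))
      cand <- conv[vapply(seq_along(conv), function(s) any(vb %in% st[[s]]), logical(1))]
      cand <- cand[vapply(cand, function(b) length(step1[[match(b, conv)]]) > 0, logical(1))]
      if (!length(cand)) next
      dbar <- vapply(cand, function(b) mean(D[v, step1[[match(b, conv)]]]), numeric(1))
      expect_equal(cl$anchor_bubble[v], cand[which.min(dbar)])
    }
  }
})

test_that("well-separated two-block data is recovered exactly", {
  b <- flat_benchmark(
    seed = 5, sizes = c(12, 12), rho = 0.9,
    n_singletons = 0, t_len = 800
  )
  fit <- dbht(b$data)
  expect_equal(adjusted_rand(b$labels$block, fit$clusters$labels), 1)
  expect_equal(max(fit$clusters$labels), 2)
})

test_that("the pipeline is deterministic end to end", {
  b <- flat_benchmark(seed = 8, sizes = c(8, 8), rho = 0.7, n_singletons = 4, t_len = 300)
  f1 <- dbht(b$data)
  f2 <- dbht(b$data)
  expect_identical(
    serialize(f1$clusters$labels, NULL),
    serialize(f2$clusters$labels, NULL)
  ) # byte-for-byte
  expect_identical(f1$hierarchy$merge, f2$hierarchy$merge)
  expect_identical(f1$hierarchy$height, f2$hierarchy$height)
})
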