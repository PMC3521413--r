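# Feature space enumeration, subgraph vectorization, Fisher selection.

test_that("the feature space has 20 + 210 + 1540 = 1770 keys", {
  sp <- enumerate_feature_space()
  expect_length(sp$singles, 20)
  expect_length(sp$pairs, 210)
  expect_length(sp$triples, 1540)
  expect_length(sp$keys, 1770)
  expect_false(any(duplicated(sp$keys)))
  # every key is a sorted multiset
  expect_true(all(vapply(strsplit(sp$triples, ""), function(x)
    identical(x, sort(x)), logical(1))))
  toy <- enumerate_feature_space(c("A", "B"))
  expect_equal(toy$pairs, c("AA", "AB", "BB"))
  expect_equal(toy$triples, c("AAA", "AAB", "ABB", "BBB"))
})

test_that("an edgeless subgraph has zero pair and triple features", {
  g <- toy_graph(c("Q", "R"), rep("unknown", 2), matrix(numeric(), 0, 2))
  g$edges <- g$edges[0, ]
  v <- vectorize_subgraph(g$nodes$res_key, g)
  sp <- enumerate_feature_space()
  expect_equal(sum(v[c(sp$pairs, sp$triples)]), 0)
  expect_equal(v[["Q"]], 1)
  expect_equal(v[["R"]], 1)
})

test_that("a triangle's triple feature is the mean of its edge weights", {
  g <- toy_graph(c("Q", "Q", "R"), rep("unknown", 3),
                 rbind(c(1, 2), c(1, 3), c(2, 3)), c(0.3, 0.6, 0.9))
  v <- vectorize_subgraph(g$nodes$res_key, g)
  expect_equal(v[["QQR"]], 0.6)
  # the pair features sum edge weights per type
  expect_equal(v[["QQ"]], 0.3)
  expect_equal(v[["QR"]], 1.5)
})

test_that("repeated pair types accumulate by summation", {
  g <- toy_graph(c("A", "C", "A", "C"), rep("unknown", 4),
                 rbind(c(1, 2), c(3, 4)), c(0.2, 0.4))
  v <- vectorize_subgraph(g$nodes$res_key, g)
  expect_equal(v[["AC"]], 0.6)
})

test_that("vectors are additive over disconnected unions", {
  g <- toy_graph(c("Q", "Q", "R", "D", "E", "D"), rep("unknown", 6),
                 rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)),
                 c(0.3, 0.6, 0.9, 0.1, 0.5, 0.7))
  v_all <- vectorize_subgraph(g$nodes$res_key, g)
  v_1 <- vectorize_subgraph(g$nodes$res_key[1:3], g)
  v_2 <- vectorize_subgraph(g$nodes$res_key[4:6], g)
  expect_equal(v_all, v_1 + v_2)
  # and invariant to member enumeration order
  v_perm <- vectorize_subgraph(rev(g$nodes$res_key), g)
  expect_equal(v_perm, v_all)
})

test_that("single features scale with the supplied statistic", {
  g <- toy_graph(c("Q", "Q", "R"), rep("unknown", 3), rbind(c(1, 2)))
  singles <- setNames(rep(1, 20), amino_acids())
  singles[["Q"]] <- 0.5
  v <- vectorize_subgraph(g$nodes$res_key, g, singles)
  expect_equal(v[["Q"]], 2 * 0.5)
  expect_equal(v[["R"]], 1)
})

test_that("Fisher scoring ranks a perfectly separating feature first", {
  set.seed(2)
  n <- 40
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("epitope", "non-epitope"), each = n / 2)
  x[, 3] <- ifelse(y == "epitope", 5, -5) + rnorm(n, 0, 0.1)
  x[, 7] <- 1  # constant
  fs <- fisher_scores(x, y)
  expect_equal(which.max(fs), 3L)
  expect_equal(fs[7], 0)
  mask <- select_features(x, y, target_count = 8, seed = 1)
  expect_true("f3" %in% mask)
  expect_error(select_features(x, rep("epitope", n)), "two classes")
})

test_that("degenerate selection falls back with a warning", {
  x <- matrix(1, 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("epitope", "non-epitope"), each = 10)
  expect_warning(mask <- select_features(x, y, target_count = 4),
                 "no feature")
  expect_true(length(mask) >= 1)
})

test_that("a planted epitope triple ranks in the top decile", {
  set.seed(11)
  graphs <- lapply(1:12, function(i) {
    cx <- generate_complex(synthetic_spec(seed = 600 + i))
    antigen_surface_graph(parse_structure(cx$pdb_text, "A", "B"))
  })
  wt <- weight_table(graphs)
  sing <- singles_table(graphs)
  sv <- setNames(sing$weight, sing$aa)
  xs <- list(); ys <- character()
  for (g in graphs) {
    gw <- apply_weights(g, wt)
    labs <- setNames(g$nodes$label, g$nodes$res_key)
    for (cl in mcl_cluster(gw)) {
      lab <- assign_training_label(cl, labs)
      if (lab == "noise") next
      xs[[length(xs) + 1]] <- vectorize_subgraph(cl, gw, sv)
      ys <- c(ys, lab)
    }
  }
  x <- do.call(rbind, xs)
  fs <- fisher_scores(x, ys)
  ranks <- rank(-fs)
  # homogeneous enriched-type triples should rank among the top 177
  planted <- c("QQQ", "DDD", "YYY", "LLL")
  expect_lt(min(ranks[match(planted, colnames(x))]), 177)
})
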