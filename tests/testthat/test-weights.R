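# Edge-type counting, chi-squared / log-odds weights, contrast, boundary
# suppression.

test_that("there are exactly 210 pair types and 20 single types", {
  expect_length(betopr:::.all_pair_types(), 210)
  expect_length(amino_acids(), 20)
  g <- toy_graph(c("Q", "Q", "R"), rep("epitope", 3),
                 rbind(c(1, 2), c(1, 3), c(2, 3)))
  cnt <- count_edge_types(list(g), c("epitope", "non-epitope"))
  expect_equal(nrow(cnt), 210)
})

test_that("edge classes follow endpoint labels", {
  g <- toy_graph(c("Q", "Q", "R"), c("epitope", "epitope", "non-epitope"),
                 rbind(c(1, 2), c(1, 3), c(2, 3)))
  epi <- count_edge_types(list(g), c("epitope", "non-epitope"))
  expect_equal(epi$n1[epi$type == "QQ"], 1)
  expect_equal(sum(epi$n1), 1)
  expect_equal(sum(epi$n2), 0)
  bnd <- count_edge_types(list(g), c("boundary", "epitope"))
  expect_equal(bnd$n1[bnd$type == "QR"], 2)
  expect_equal(sum(bnd$n1), 2)
  expect_error(count_edge_types(list()), "no graphs")
  unl <- toy_graph(c("Q", "R"), c("unknown", "unknown"), rbind(c(1, 2)))
  expect_error(count_edge_types(list(unl)), "labelled")
})

test_that("the chi-squared statistic matches the hand contingency example", {
  expect_equal(chi2_stat(10, 10, 100, 300), 25 / 5 + 25 / 15)
  # observed equal to expected -> 0
  expect_equal(chi2_stat(10, 30, 100, 300), 0)
  expect_equal(chi2_stat(0, 0, 100, 300), 0)
  # symmetric under class swap
  expect_equal(chi2_stat(7, 3, 50, 80), chi2_stat(3, 7, 80, 50))
  expect_true(all(chi2_stat(0:20, 20:0, 100, 100) >= 0))
})

test_that("log-odds is the natural log of within-class frequencies", {
  # frequencies 0.02 vs 0.01 without smoothing
  expect_equal(log_odds(2, 1, 100, 100, pseudocount = 0), log(2))
  expect_equal(log_odds(5, 5, 80, 80), 0)
  # smoothing keeps zero counts finite and negative
  v <- log_odds(0, 30, 500, 500)
  expect_true(is.finite(v) && v < 0)
})

test_that("normalization and mixing behave at the endpoints", {
  chi2 <- c(0, 2, 8)
  lo <- c(-1, 0, 3)
  expect_equal(normalize_and_combine(chi2, lo, alpha = 1), c(0, 0.25, 1))
  expect_equal(normalize_and_combine(chi2, lo, alpha = 0), c(0, 0.25, 1))
  both_max <- normalize_and_combine(c(0, 8), c(-1, 3), alpha = 0.3)
  expect_equal(both_max[2], 1.0)
  expect_warning(out <- normalize_and_combine(c(1, 1), c(0, 1), alpha = 0.5),
                 "constant")
  expect_equal(out, c(0.25, 0.75))
  # convexity: result bounded by the two normalized tables
  set.seed(1)
  a <- runif(210); b <- runif(210)
  na <- (a - min(a)) / diff(range(a)); nb <- (b - min(b)) / diff(range(b))
  w <- normalize_and_combine(a, b, alpha = 0.3)
  expect_true(all(w >= pmin(na, nb) - 1e-12 & w <= pmax(na, nb) + 1e-12))
})

test_that("the contrast transform matches its closed form and is monotone", {
  expect_equal(contrast_weight(0.5, 3, 3), 0.25)
  expect_equal(contrast_weight(0.75, 3, 3), 0.9)
  expect_lt(contrast_weight(1e-9), 1e-6)
  expect_gt(contrast_weight(1 - 1e-9), 1 - 1e-6)
  grid <- seq(0.0005, 0.9995, length.out = 1000)
  expect_true(all(diff(contrast_weight(grid)) > 0))
})

test_that("boundary scores favour the larger contrast and set w0 by percentile", {
  set.seed(42)
  aa <- c(rep("Q", 4), rep("R", 4))
  lab <- c(rep("epitope", 4), rep("non-epitope", 4))
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)),
                 c(1, 5), c(2, 6), c(3, 7))
  g <- toy_graph(aa, lab, edges)
  bm <- boundary_model(list(g), w0_percentile = 90, combine = "max")
  expect_equal(bm$scores$score, pmax(bm$scores$w_epi, bm$scores$w_non))
  bmin <- boundary_model(list(g), w0_percentile = 90, combine = "min")
  expect_equal(bmin$scores$score, pmin(bmin$scores$w_epi, bmin$scores$w_non))
  expect_true(all(bm$scores$score >= 0 & bm$scores$score <= 1))
  # QR is the boundary type here and must carry the top score
  expect_equal(bm$scores$type[which.max(bm$scores$score)], "QR")
  bm100 <- boundary_model(list(g), w0_percentile = 100)
  expect_equal(sum(bm100$scores$score > bm100$w0), 0)
  pure <- toy_graph(c("Q", "Q"), rep("epitope", 2), rbind(c(1, 2)))
  expect_error(boundary_model(list(pure)), "boundary")
})

test_that("apply_weights populates weights and removes suppressed types", {
  g <- toy_graph(c("Q", "Q", "R"), rep("unknown", 3),
                 rbind(c(1, 2), c(1, 3), c(2, 3)))
  wt <- tibble::tibble(type = betopr:::.all_pair_types())
  wt$weight <- seq(0, 1, length.out = 210)
  gw <- apply_weights(g, wt)
  expect_false(anyNA(gw$edges$weight))
  expect_equal(gw$edges$weight,
               wt$weight[match(gw$edges$type, wt$type)])
  bm <- structure(list(
    scores = tibble::tibble(type = wt$type, w_epi = 0, w_non = 0,
                            score = ifelse(wt$type == "QR", 0.9, 0)),
    w0 = 0.5), class = "boundary_model")
  gs <- apply_weights(g, wt, bm)
  expect_false(any(gs$edges$type == "QR"))
  expect_equal(nrow(gs$edges), 1)
  # infinite w0 is equivalent to no suppression
  bm$w0 <- Inf
  expect_equal(apply_weights(g, wt, bm)$edges, gw$edges)
})

test_that("learned log-odds recovers planted enrichment directions", {
  set.seed(7)
  graphs <- lapply(1:20, function(i) {
    cx <- generate_complex(synthetic_spec(n_residues = 60, seed = 300 + i))
    antigen_surface_graph(parse_structure(cx$pdb_text, "A", "B"))
  })
  wt <- weight_table(graphs)
  enr <- c("Q", "D", "Y", "L")
  homo <- paste0(enr, enr)
  counted <- wt[wt$type %in% homo & (wt$n1 + wt$n2) >= 5, ]
  expect_gte(mean(counted$log_odds > 0), 0.95)
})

test_that("the singles table mirrors the pair machinery over 20 types", {
  g <- toy_graph(c("Q", "Q", "R", "K"),
                 c("epitope", "epitope", "non-epitope", "non-epitope"),
                 rbind(c(1, 2), c(3, 4)))
  s <- singles_table(list(g))
  expect_equal(nrow(s), 20)
  expect_equal(s$n1[s$aa == "Q"], 2)
  expect_equal(s$n2[s$aa == "R"], 1)
  expect_gt(s$log_odds[s$aa == "Q"], 0)
})
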