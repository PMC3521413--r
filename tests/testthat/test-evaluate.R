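# Metrics, non-planarity, multi-epitope truth and the G-test.

test_that("confusion metrics match their closed forms", {
  m <- confusion_metrics(tp = 16, tn = 100, fp = 1, fn = 3)
  expect_equal(m$fscore, 512 / 576, tolerance = 1e-9)   # ~0.889
  expect_equal(m$sen, 16 / 19)
  expect_equal(m$spe, 100 / 101)
  perfect <- confusion_metrics(10, 90, 0, 0)
  expect_equal(unlist(perfect), c(sen = 1, spe = 1, fscore = 1, acc = 1))
  none <- confusion_metrics(0, 90, 5, 5)
  expect_equal(none$fscore, 0)
  expect_equal(confusion_metrics(0, 0, 0, 0)$acc, 0)
})

test_that("the f-score obeys its harmonic bound", {
  set.seed(13)
  for (i in 1:1000) {
    cnt <- sample(0:50, 4, replace = TRUE)
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    pre <- if (cnt[1] + cnt[3] == 0) 0 else cnt[1] / (cnt[1] + cnt[3])
    lo <- min(pre, m$sen)
    expect_lte(m$fscore, 2 * lo / (1 + lo) + 1e-12)
  }
})

test_that("rank AUC behaves at the extremes and under randomness", {
  truth <- rep(c(TRUE, FALSE), c(20, 80))
  expect_equal(residue_auc(c(rep(2, 20), rep(1, 80)), truth), 1)
  expect_equal(residue_auc(c(rep(1, 20), rep(2, 80)), truth), 0)
  expect_error(residue_auc(1:5, rep(TRUE, 5)), "both classes")
  set.seed(21)
  n <- 4000
  truth_big <- sample(c(TRUE, FALSE), n, replace = TRUE)
  a <- residue_auc(runif(n), truth_big)
  n1 <- sum(truth_big); n0 <- n - n1
  se <- sqrt((n + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * se)
  # agrees with pROC on a mixed example
  sc <- c(rnorm(50, 1), rnorm(50))
  tr <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(residue_auc(sc, tr),
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE))))
})

test_that("non-planarity matches the symmetric four-point oracle", {
  pts <- rbind(c(1, 0, 0.5), c(-1, 0, 0.5), c(0, 1, -0.5), c(0, -1, -0.5))
  expect_equal(non_planarity(pts), 0.5, tolerance = 1e-12)
  # three non-collinear points are exactly planar
  expect_equal(non_planarity(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 3))), 0)
  expect_error(non_planarity(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  expect_warning(v <- non_planarity(cbind(1:5, 2 * (1:5), 0)), "collinear")
  expect_equal(v, 0)
})

test_that("non-planarity is rigid-motion invariant", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  base <- non_planarity(pts)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pts %*% rot + matrix(rep(c(3, -7, 2), each = 10), ncol = 3)
  expect_equal(non_planarity(moved), base, tolerance = 1e-9)
})

test_that("epitope similarity is overlap over the smaller epitope", {
  x <- paste0("r", 1:17)
  y <- c(paste0("r", 1:3), paste0("s", 1:12))
  expect_equal(epitope_similarity(x, y), 3 / 15)
  expect_equal(epitope_similarity(x, x), 1)
  expect_equal(epitope_similarity(x, paste0("q", 1:5)), 0)
  expect_equal(epitope_similarity(x, x[1:5]), 1)  # nested sets
  expect_error(epitope_similarity(x, character()), "empty")
})

test_that("multi-epitope truth clusters by single linkage on similarity", {
  e1 <- paste0("r", 1:17)
  e2 <- c(paste0("r", 1:3), paste0("s", 1:12))  # S = 0.2 with e1
  reps <- build_multi_epitope_truth(list(e1, e2), c(2.0, 1.5),
                                    link_threshold = 0.5)
  expect_length(reps, 2)
  # identical epitopes merge, the better-resolution complex represents
  reps2 <- build_multi_epitope_truth(list(e1, e1), c(2.5, 1.2))
  expect_length(reps2, 1)
  expect_equal(attr(reps2, "cluster"), c(1L, 1L))
  reps3 <- build_multi_epitope_truth(list(e1), 2.0)
  expect_equal(reps3[[1]], e1)
})

test_that("the G statistic matches the direct formula and is symmetric", {
  expect_equal(g_statistic(c(10, 10), c(5, 15)),
               2 * (10 * log(2) + 10 * log(2 / 3)))
  expect_equal(g_statistic(c(5, 15), c(5, 15)), 0)
  expect_equal(g_statistic(c(0, 10), c(5, 5)), 2 * 10 * log(2))
  present <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 15, 5, 70))
  labels <- rep(c("epitope", "non-epitope"), c(25, 75))
  g <- g_test(present, labels)
  expect_gt(g, 0)
  flipped <- g_test(present, ifelse(labels == "epitope", "b", "a"))
  expect_equal(g, flipped)
  expect_equal(g_test(rep(TRUE, 10), rep(c("a", "b"), 5)), 0)
})

test_that("prediction scoring follows the best-match convention", {
  universe <- paste0("r", 1:100)
  truth <- list(paste0("r", 1:10))
  good <- paste0("r", 1:9)
  noise <- paste0("r", 50:80)
  m <- score_prediction(list(noise, good), truth, universe)
  expect_equal(m$fscore, 2 * (9 / 9) * (9 / 10) / (1 + 9 / 10))
  # union convention scores the combined set instead
  mu <- score_prediction(list(noise, good), truth, universe,
                         best_match = FALSE)
  expect_lt(mu$fscore, m$fscore)
  # empty prediction scores zero
  expect_equal(score_prediction(list(), truth, universe)$fscore, 0)
})
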