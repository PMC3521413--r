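# Two-stage supervised learning: class-balanced RBF-SVM ensemble plus
# trust-reliable voting.

.default_grid <- function() {
  list(cost = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 3, by = 4))
}

# pack an e1071 svm into plain numeric parameters so the model bundle is a
# self-contained JSON; the decision-value orientation is verified against
# e1071's own predictions at pack time, and the probability map is a
# deterministic Platt sigmoid fitted on the training decision values
.svm_pack <- function(fit, x_train, y_train) {
  pack <- list(
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    gamma = as.numeric(fit$gamma),
    sign = 1
  )
  ref <- predict(fit, x_train, decision.values = TRUE)
  dv <- attr(ref, "decision.values")
  d_manual <- .svm_decision_raw(pack, x_train)
  if (sum((d_manual - as.numeric(dv[, 1]))^2) >
      sum((d_manual + as.numeric(dv[, 1]))^2)) {
    pack$sign <- -1
  }
  if (strsplit(colnames(dv)[1], "/")[[1]][1] != "epitope") {
    pack$sign <- -pack$sign
  }
  d <- pack$sign * d_manual
  platt <- .platt_fit(d, y_train == "epitope")
  pack$platt_a <- platt[1]
  pack$platt_b <- platt[2]
  pack
}

.svm_decision_raw <- function(pack, x) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x^2), rep(1, nrow(pack$sv))) +
    outer(rep(1, nrow(x)), rowSums(pack$sv^2)) - 2 * x %*% t(pack$sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-pack$gamma * d2) %*% pack$coefs - pack$rho)
}

# Platt sigmoid calibration p = 1/(1 + exp(a*d + b)) with the usual
# prior-corrected targets; deterministic (BFGS from a fixed start)
.platt_fit <- function(d, positive) {
  np <- sum(positive); nn <- sum(!positive)
  t <- ifelse(positive, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * d + par[2]
    # stable log(1 + exp(z)) and cross-entropy
    lp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    sum(t * lp + (1 - t) * (lp - z))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  fit$par
}

# decision value oriented so positive favours the epitope class, plus the
# calibrated probability of the epitope class
.svm_eval <- function(pack, x) {
  d <- pack$sign * .svm_decision_raw(pack, x)
  z <- pack$platt_a * d + pack$platt_b
  p_epi <- 1 / (1 + exp(pmin(pmax(z, -500), 500)))
  list(decision = d, p_epi = pmin(pmax(p_epi, 0), 1))
}

# grid-searched RBF SVM on one balanced set; returns pack + CV f-score
.train_one_svm <- function(x, y, grid, folds = 5, seed = 1, groups = NULL) {
  best <- list(f = -1, cost = grid$cost[1], gamma = grid$gamma[1])
  fold <- .stratified_folds(y, min(folds, min(table(y))), seed, groups)
  k <- max(fold)
  for (co in grid$cost) for (ga in grid$gamma) {
    tp <- fp <- fn <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "radial", cost = co, gamma = ga,
                        scale = FALSE)
      pred <- as.character(predict(fit, x[!tr, , drop = FALSE]))
      truth <- y[!tr]
      tp <- tp + sum(pred == "epitope" & truth == "epitope")
      fp <- fp + sum(pred == "epitope" & truth != "epitope")
      fn <- fn + sum(pred != "epitope" & truth == "epitope")
    }
    fsc <- .fscore(tp, fp, fn)
    if (fsc > best$f) best <- list(f = fsc, cost = co, gamma = ga)
  }
  set.seed(seed)
  fit <- e1071::svm(x, factor(y), kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  pack <- .svm_pack(fit, x, y)
  pack$cost <- best$cost
  pack$cv_fscore <- max(best$f, 0)
  pack
}

#' Train the balanced SVM ensemble
#'
#' The classifier count follows the class imbalance: `k = max(1,
#' round(n_non / n_epi))`. Non-epitope vectors are partitioned into `k`
#' disjoint groups by a seeded shuffle; classifier `i` is an RBF SVM trained
#' on group `i` plus all epitope vectors, with cost and kernel width chosen
#' by cross-validated f-score over a powers-of-two grid. Classifier weights
#' are the validation f-scores, normalized to sum 1 (uniform when all are
#' zero).
#'
#' @param x Feature matrix (rows = subgraphs, columns = selected features).
#' @param y Labels, `"epitope"` / `"non-epitope"`.
#' @param theta0 Vote threshold (default 0.3).
#' @param tau0 Dubiety band around 0.5 (default 0.05).
#' @param grid Hyperparameter grid, list with `cost` and `gamma`.
#' @param folds CV folds within each balanced set.
#' @param seed Seed for partitioning and CV.
#' @param groups Optional grouping ids (one per row, e.g. source antigen)
#'   kept together across CV folds, so the grid search measures
#'   generalization to unseen antigens.
#' @return A `betop_ensemble`: packed classifiers, normalized weights `w`,
#'   `theta0`, `tau0`, `k`, `seed` and the feature names.
#' @export
build_ensemble <- function(x, y, theta0 = 0.3, tau0 = 0.05,
                           grid = .default_grid(), folds = 5, seed = 1,
                           groups = NULL) {
  stopifnot(nrow(x) == length(y), tau0 >= 0, tau0 < 0.5)
  epi <- which(y == "epitope")
  non <- which(y == "non-epitope")
  if (length(epi) == 0 || length(non) == 0) {
    stop("both classes are required to train the ensemble")
  }
  k <- max(1L, round(length(non) / length(epi)))
  set.seed(seed)
  parts <- split(sample(non), rep_len(seq_len(k), length(non)))
  classifiers <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- c(epi, parts[[i]])
    classifiers[[i]] <- .train_one_svm(x[idx, , drop = FALSE], y[idx],
                                       grid, folds, seed + i,
                                       groups = groups[idx])
  }
  w <- vapply(classifiers, function(cl) cl$cv_fscore, numeric(1))
  w <- if (sum(w) == 0) rep(1 / k, k) else w / sum(w)
  structure(
    list(classifiers = classifiers, w = w, theta0 = theta0, tau0 = tau0,
         k = k, seed = seed, features = colnames(x)),
    class = "betop_ensemble"
  )
}

#' @export
print.betop_ensemble <- function(x, ...) {
  cat("<betop_ensemble> ", x$k, " RBF-SVM classifiers on ",
      length(x$features), " features; theta0 = ", x$theta0,
      ", tau0 = ", x$tau0, "\n", sep = "")
  invisible(x)
}

#' Trust-reliable ensemble vote
#'
#' Implements the voting rule `y = sgn(sum_i w_i f_i delta_i - theta0)`,
#' where `delta_i = 1 - g(tau0 - |p_i0 - 0.5|) * h(sum_i sgn(p_i0 - 0.5))`:
#' classifier `i`'s vote is dropped (`delta_i = 0`) when it is dubious (its
#' non-epitope probability `p_i0` within `tau0` of 0.5) while confident
#' classifiers lean one way (`h` nonzero). `g` is the strictly-positive
#' indicator, `h` the nonzero indicator, and `sgn(0)` contributes 0 to the
#' `h` sum.
#'
#' @param f Per-classifier labels, +1 (epitope) or -1 (non-epitope).
#' @param p0 Per-classifier probability of the non-epitope class, in
#'   `[0, 1]`.
#' @param w Classifier weights (sum 1).
#' @param theta0 Vote threshold.
#' @param tau0 Dubiety band.
#' @return Tibble (one row per classifier) with `f`, `p0`, `delta`, `w`,
#'   plus attributes `score` (`sum(w f delta)`) and `decision` (+1 iff
#'   `score > theta0`, else -1).
#' @export
trust_reliable_vote <- function(f, p0, w, theta0 = 0.3, tau0 = 0.05) {
  stopifnot(length(f) == length(p0), length(f) == length(w),
            all(f %in% c(-1, 1)))
  if (any(p0 < 0 | p0 > 1)) stop("probabilities must lie in [0, 1]")
  sgn <- sign(p0 - 0.5)                    # sgn(0) contributes 0
  h <- as.numeric(sum(sgn) != 0)
  g <- as.numeric((tau0 - abs(p0 - 0.5)) > 0)
  delta <- 1 - g * h
  score <- sum(w * f * delta)
  out <- tibble::tibble(f = f, p0 = p0, delta = delta, w = w)
  attr(out, "score") <- score
  attr(out, "decision") <- if (score > theta0) 1 else -1
  out
}

#' Classify one subgraph feature vector
#'
#' Evaluates every classifier of the ensemble on the masked vector and
#' combines them by [trust_reliable_vote()].
#'
#' @param v Named feature vector (full 1770-dimensional or already masked).
#' @param model A `betop_ensemble`.
#' @return List with `label` (`"epitope"` / `"non-epitope"`), `score` (the
#'   vote score) and the per-classifier `trace` tibble.
#' @export
predict_subgraph <- function(v, model) {
  if (is.null(names(v))) {
    if (length(v) != length(model$features)) stop("feature dimension mismatch")
    x <- matrix(v, nrow = 1)
  } else {
    if (!all(model$features %in% names(v))) stop("feature dimension mismatch")
    x <- matrix(v[model$features], nrow = 1)
  }
  f <- numeric(model$k)
  p0 <- numeric(model$k)
  for (i in seq_len(model$k)) {
    ev <- .svm_eval(model$classifiers[[i]], x)
    f[i] <- if (ev$decision > 0) 1 else -1
    p0[i] <- 1 - ev$p_epi
  }
  trace <- trust_reliable_vote(f, p0, model$w, model$theta0, model$tau0)
  list(label = if (attr(trace, "decision") > 0) "epitope" else "non-epitope",
       score = attr(trace, "score"),
       trace = trace)
}
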