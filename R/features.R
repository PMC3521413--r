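# 1770-dimensional subgraph feature vectors (residue composition, contact
# pairs, contact triangles) and Fisher-score feature selection.

#' Enumerate the subgraph feature space
#'
#' All multisets of sizes 1, 2 and 3 over the 20 amino acids, in
#' lexicographic order: 20 single-residue keys, 210 residue-pair keys and
#' 1540 residue-triangle keys, 1770 in total.
#'
#' @param alphabet Residue alphabet (default the 20 standard amino acids).
#' @return List with `singles`, `pairs`, `triples` and the concatenated
#'   `keys` vector.
#' @export
enumerate_feature_space <- function(alphabet = amino_acids()) {
  k <- length(alphabet)
  singles <- alphabet
  pairs <- unlist(lapply(seq_len(k), function(i)
    paste0(alphabet[i], alphabet[i:k])))
  triples <- unlist(lapply(seq_len(k), function(i)
    unlist(lapply(i:k, function(j)
      paste0(alphabet[i], alphabet[j], alphabet[j:k])))))
  list(singles = singles, pairs = pairs, triples = triples,
       keys = c(singles, pairs, triples))
}

# 3-cliques of the induced subgraph; returns tibble(type, mean_weight)
.subgraph_triangles <- function(members, edges) {
  e <- edges[edges$from %in% members & edges$to %in% members, , drop = FALSE]
  if (nrow(e) < 3) return(NULL)
  nb <- split(c(e$to, e$from), c(e$from, e$to))
  wkey <- paste(e$from, e$to, sep = "\r")
  w_of <- setNames(ifelse(is.na(e$weight), 1, e$weight), wkey)
  res <- list()
  for (r in seq_len(nrow(e))) {
    u <- e$from[r]; v <- e$to[r]
    common <- intersect(nb[[u]], nb[[v]])
    common <- common[common > v]  # each triangle counted once (u < v < w)
    for (wn in common) {
      w1 <- w_of[[paste(u, v, sep = "\r")]]
      w2 <- w_of[[paste(min(u, wn), max(u, wn), sep = "\r")]]
      w3 <- w_of[[paste(min(v, wn), max(v, wn), sep = "\r")]]
      res[[length(res) + 1]] <- list(nodes = c(u, v, wn),
                                     mw = (w1 + w2 + w3) / 3)
    }
  }
  res
}

#' Feature vector of one subgraph
#'
#' Single-residue features are the residue-type counts in the subgraph
#' scaled by the learned single-residue statistic; a residue-pair feature
#' sums the weights of the subgraph's edges of that type; a triangle feature
#' sums, over the subgraph's geometric 3-cliques matching the type multiset,
#' the mean of the clique's three edge weights. Patterns absent from the
#' subgraph are 0, so vectors are sparse and additive over disconnected
#' unions.
#'
#' @param members Character vector of residue keys in the subgraph.
#' @param graph The weighted `surface_graph` the subgraph came from.
#' @param singles Named numeric vector amino acid -> single-residue statistic
#'   (from [singles_table()]); defaults to all 1.
#' @param space Feature space from [enumerate_feature_space()].
#' @return Named numeric vector of length 1770.
#' @export
vectorize_subgraph <- function(members, graph, singles = NULL,
                               space = enumerate_feature_space()) {
  v <- setNames(numeric(length(space$keys)), space$keys)
  aa_of <- setNames(graph$nodes$aa, graph$nodes$res_key)
  if (is.null(singles)) singles <- setNames(rep(1, 20), amino_acids())

  cnt <- table(aa_of[members])
  v[names(cnt)] <- as.numeric(cnt) * singles[names(cnt)]

  e <- graph$edges[graph$edges$from %in% members &
                     graph$edges$to %in% members, , drop = FALSE]
  if (nrow(e) > 0) {
    w <- ifelse(is.na(e$weight), 1, e$weight)
    ps <- tapply(w, e$type, sum)
    v[names(ps)] <- v[names(ps)] + as.numeric(ps)
  }

  tri <- .subgraph_triangles(members, graph$edges)
  for (t in tri) {
    key <- paste(sort(unname(aa_of[t$nodes])), collapse = "")
    v[key] <- v[key] + t$mw
  }
  v
}

# f-score of the positive class; 0/0 conventions -> 0
.fscore <- function(tp, fp, fn) {
  if (tp == 0) return(0)
  pre <- tp / (tp + fp)
  sen <- tp / (tp + fn)
  2 * pre * sen / (pre + sen)
}

# stratified k-fold assignment; when `groups` is given (one id per row,
# e.g. the source antigen) all rows of a group share a fold, so
# cross-validation measures generalization to unseen antigens rather than
# to sibling subgraphs of an already-seen epitope
.stratified_folds <- function(y, k, seed, groups = NULL) {
  set.seed(seed)
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gs <- sample(unique(groups))
    gf <- setNames(rep_len(seq_len(k), length(gs)), gs)
    fold <- unname(gf[as.character(groups)])
  }
  fold
}

# cross-validated f-score of a class-weighted linear SVM restricted to
# `cols` (inverse-frequency weights so the minority epitope class is not
# drowned by the subgraph imbalance)
.cv_fscore <- function(x, y, cols, k = 3, seed = 1, groups = NULL) {
  fold <- .stratified_folds(y, k, seed, groups)
  tp <- fp <- fn <- 0
  cw <- length(y) / (2 * table(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    fit <- e1071::svm(x[tr, cols, drop = FALSE], factor(y[tr]),
                      kernel = "linear", scale = FALSE,
                      class.weights = cw)
    pred <- as.character(predict(fit, x[!tr, cols, drop = FALSE]))
    truth <- y[!tr]
    tp <- tp + sum(pred == "epitope" & truth == "epitope")
    fp <- fp + sum(pred == "epitope" & truth != "epitope")
    fn <- fn + sum(pred != "epitope" & truth == "epitope")
  }
  .fscore(tp, fp, fn)
}

#' Fisher discriminant score per feature
#'
#' `(mean1 - mean2)^2 / (var1 + var2)` between the two classes; constant
#' features score 0.
#'
#' @param x Feature matrix (rows = subgraphs).
#' @param y Character vector of labels (two classes).
#' @return Numeric vector of scores, one per column.
#' @export
fisher_scores <- function(x, y) {
  cls <- unique(y)
  stopifnot(length(cls) == 2)
  x1 <- x[y == cls[1], , drop = FALSE]
  x2 <- x[y == cls[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  num <- (m1 - m2)^2
  den <- v1 + v2
  out <- ifelse(num == 0, 0, num / (den + 1e-12))
  unname(out)
}

#' Select discriminative features
#'
#' Ranks features by Fisher score, then sweeps nested cut sizes and keeps
#' the prefix whose cross-validated classifier f-score is best. The sweep is
#' capped at `target_count` features.
#'
#' @param x Feature matrix (rows = subgraphs, columns named by feature key).
#' @param y Character labels (`"epitope"` / `"non-epitope"`).
#' @param target_count Largest mask size considered (default 144).
#' @param folds Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param groups Optional grouping ids (one per row, e.g. source antigen);
#'   rows of a group are never split across CV folds.
#' @return Character vector of selected feature keys (the mask), with the
#'   sweep table in attribute `"sweep"`.
#' @export
select_features <- function(x, y, target_count = 144, folds = 3, seed = 1,
                            groups = NULL) {
  if (length(unique(y)) < 2) stop("feature selection needs two classes")
  fs <- fisher_scores(x, y)
  ord <- order(fs, decreasing = TRUE)
  n_useful <- sum(fs > 0)
  sizes <- unique(pmin(c(8, 16, 32, 64, 96, target_count),
                       max(n_useful, 8)))
  sizes <- sizes[sizes <= target_count]
  if (n_useful == 0) {
    warning("no feature separates the classes; falling back to the smallest mask")
    return(colnames(x)[ord[seq_len(min(sizes))]])
  }
  sweep_f <- vapply(sizes, function(s) {
    .cv_fscore(x, y, ord[seq_len(s)], k = folds, seed = seed, groups = groups)
  }, numeric(1))
  best <- sizes[which.max(sweep_f)]
  mask <- colnames(x)[ord[seq_len(best)]]
  attr(mask, "sweep") <- tibble::tibble(size = sizes, cv_fscore = sweep_f)
  mask
}
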