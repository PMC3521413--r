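# Evaluation: confusion metrics, AUC, epitope non-planarity, multi-epitope
# ground truth, G-test feature analysis.

#' Residue-level confusion metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, f-score
#' `2*pre*sen/(pre+sen)` with precision `TP/(TP+FP)`, and accuracy
#' `(TP+TN)/total`; 0/0 cases are defined as 0.
#'
#' @param tp,tn,fp,fn Confusion counts over surface residues.
#' @return Tibble with one row: `sen`, `spe`, `fscore`, `acc`.
#' @examples
#' confusion_metrics(tp = 16, fp = 1, fn = 3, tn = 100)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  fsc <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  tibble::tibble(sen = sen, spe = spe, fscore = fsc, acc = acc)
}

#' Rank-based AUC of per-residue scores
#'
#' Mann-Whitney formulation: the probability that a random epitope residue
#' scores higher than a random non-epitope residue, ties counted half.
#'
#' @param scores Numeric vector of residue scores.
#' @param truth Logical vector (`TRUE` = epitope residue).
#' @return AUC in `[0, 1]`.
#' @export
residue_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Non-planarity of a residue patch
#'
#' Root-mean-square deviation of the patch's surface atoms from their
#' total-least-squares plane (the plane orthogonal to the smallest principal
#' axis of the centered coordinates). Flat epitopes score near 0; protrusive
#' ones score high.
#'
#' @param coords Matrix (n x 3) of surface-atom coordinates of the patch.
#' @return RMS perpendicular deviation in Angstrom.
#' @export
non_planarity <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("non-planarity needs at least 3 atoms")
  ctr <- sweep(coords, 2, colMeans(coords))
  sv <- svd(ctr, nu = 0)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    warning("collinear atoms; non-planarity is 0")
    return(0)
  }
  normal <- sv$v[, 3]
  sqrt(mean((ctr %*% normal)^2))
}

#' Overlap similarity of two epitopes
#'
#' `S_XY = |X intersect Y| / min(|X|, |Y|)`.
#'
#' @param x,y Character vectors of residue keys (non-empty).
#' @return Similarity in `[0, 1]`.
#' @export
epitope_similarity <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty epitope set")
  length(intersect(x, y)) / min(length(unique(x)), length(unique(y)))
}

#' Representative epitopes of a multi-complex antigen
#'
#' Epitopes of the same antigen observed in several complexes are clustered
#' by single linkage on the overlap similarity `S_XY` (epitopes with
#' `S_XY >= link_threshold` merge); each cluster is represented by the
#' epitope from the complex with the best (lowest) resolution.
#'
#' @param epitopes List of character vectors (residue keys), one per
#'   complex.
#' @param resolutions Numeric vector of the complexes' resolutions
#'   (Angstrom; `NA` treated as worst).
#' @param link_threshold Similarity at or above which two epitopes are the
#'   same (default 0.5).
#' @return List of representative epitopes (character vectors); attribute
#'   `"cluster"` holds the cluster index of each input epitope.
#' @export
build_multi_epitope_truth <- function(epitopes, resolutions = NULL,
                                      link_threshold = 0.5) {
  n <- length(epitopes)
  stopifnot(n >= 1)
  if (is.null(resolutions)) resolutions <- rep(NA_real_, n)
  if (n == 1) {
    out <- epitopes
    attr(out, "cluster") <- 1L
    return(out)
  }
  s <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s[i, j] <- s[j, i] <- epitope_similarity(epitopes[[i]], epitopes[[j]])
  }
  hc <- stats::hclust(stats::as.dist(1 - s), method = "single")
  cl <- stats::cutree(hc, h = 1 - link_threshold)
  res_rank <- ifelse(is.na(resolutions), Inf, resolutions)
  reps <- lapply(split(seq_len(n), cl), function(idx) {
    epitopes[[idx[which.min(res_rank[idx])]]]
  })
  out <- unname(reps)
  attr(out, "cluster") <- unname(cl)
  out
}

#' G statistic of observed vs expected counts
#'
#' `G = 2 * sum O * ln(O / E)`; zero-observation cells contribute 0.
#'
#' @param observed,expected Non-negative count vectors of equal length.
#' @return The G statistic.
#' @examples
#' g_statistic(c(10, 10), c(5, 15))  # ~5.75
#' @export
g_statistic <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), all(expected >= 0))
  terms <- ifelse(observed == 0, 0, observed * log(observed / expected))
  2 * sum(terms)
}

#' G-test of feature presence between two classes
#'
#' [g_statistic()] over the 2x2 presence/class contingency table, with
#' expected counts under independence; degenerate margins give 0.
#'
#' @param present Logical vector: the feature is present in each subgraph.
#' @param labels Character vector of class labels (two classes).
#' @return The G statistic.
#' @export
g_test <- function(present, labels) {
  tab <- table(factor(present, c(FALSE, TRUE)), labels)
  if (ncol(tab) != 2) stop("g_test needs two classes")
  o <- as.matrix(tab)
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) return(0)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  g_statistic(as.numeric(o), as.numeric(e))
}

#' Score a prediction against a truth epitope set
#'
#' Residue-level confusion metrics over the scored residues. With several
#' predicted candidate epitopes and `best_match = TRUE`, each truth epitope
#' is scored against its best-matching candidate and the results averaged
#' (the reporting convention for multi-candidate output).
#'
#' @param predicted List of predicted epitopes (character vectors), or a
#'   single character vector.
#' @param truth List of truth epitopes (or a single character vector).
#' @param universe Character vector of all scored (surface) residues.
#' @param best_match Use the best-candidate convention (default `TRUE`).
#' @return Tibble of metrics (one row per truth epitope plus their mean row
#'   is not added; use `dplyr::summarise`), columns `truth_id`, `sen`,
#'   `spe`, `fscore`, `acc`.
#' @export
score_prediction <- function(predicted, truth, universe, best_match = TRUE) {
  if (is.character(predicted)) predicted <- list(predicted)
  if (is.character(truth)) truth <- list(truth)
  if (length(predicted) == 0) predicted <- list(character())
  rows <- lapply(seq_along(truth), function(ti) {
    tr <- intersect(truth[[ti]], universe)
    one <- function(pred) {
      pred <- intersect(pred, universe)
      tp <- length(intersect(pred, tr))
      fp <- length(setdiff(pred, tr))
      fn <- length(setdiff(tr, pred))
      tn <- length(universe) - tp - fp - fn
      confusion_metrics(tp, tn, fp, fn)
    }
    cand <- lapply(predicted, one)
    if (best_match) {
      best <- which.max(vapply(cand, function(m) m$fscore, numeric(1)))
      m <- cand[[best]]
    } else {
      m <- one(unique(unlist(predicted)))
    }
    dplyr::mutate(m, truth_id = ti, .before = 1)
  })
  dplyr::bind_rows(rows)
}
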