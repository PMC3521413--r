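# Learning edge-type propensity weights: chi-squared + log-odds per
# residue-pair type, min-max normalization, alpha-mixing, contrast transform,
# and the boundary-edge suppression model.

.all_pair_types <- function() {
  aa <- amino_acids()
  unlist(lapply(seq_along(aa), function(i) paste0(aa[i], aa[i:length(aa)])))
}

# class of a labelled edge: both endpoints epitope -> "epitope", both
# non-epitope -> "non-epitope", mixed -> "boundary"
.edge_classes <- function(graph) {
  lab <- setNames(graph$nodes$label, graph$nodes$res_key)
  l1 <- unname(lab[graph$edges$from])
  l2 <- unname(lab[graph$edges$to])
  cls <- rep(NA_character_, length(l1))
  cls[l1 == "epitope" & l2 == "epitope"] <- "epitope"
  cls[l1 == "non-epitope" & l2 == "non-epitope"] <- "non-epitope"
  cls[(l1 == "epitope" & l2 == "non-epitope") |
        (l1 == "non-epitope" & l2 == "epitope")] <- "boundary"
  cls
}

#' Count edge types per class across labelled training graphs
#'
#' An edge's class follows its endpoint labels: epitope when both endpoints
#' are epitope residues, non-epitope when both are non-epitope, boundary
#' when mixed.
#'
#' @param graphs List of labelled `surface_graph` objects.
#' @param class_pair Length-2 character vector naming the two classes to
#'   count, from `"epitope"`, `"non-epitope"`, `"boundary"`.
#' @return Tibble with 210 rows: `type`, `n1` (count in `class_pair[1]`),
#'   `n2` (count in `class_pair[2]`).
#' @export
count_edge_types <- function(graphs, class_pair = c("epitope", "non-epitope")) {
  stopifnot(length(class_pair) == 2)
  if (length(graphs) == 0) stop("no graphs supplied")
  types <- .all_pair_types()
  n1 <- setNames(integer(length(types)), types)
  n2 <- n1
  any_labelled <- FALSE
  for (g in graphs) {
    if (nrow(g$edges) == 0) next
    cls <- .edge_classes(g)
    ok <- !is.na(cls)
    if (any(ok)) any_labelled <- TRUE
    t1 <- table(g$edges$type[cls == class_pair[1] & ok])
    t2 <- table(g$edges$type[cls == class_pair[2] & ok])
    n1[names(t1)] <- n1[names(t1)] + as.integer(t1)
    n2[names(t2)] <- n2[names(t2)] + as.integer(t2)
  }
  if (!any_labelled) stop("no labelled edges in the supplied graphs")
  tibble::tibble(type = types, n1 = unname(n1), n2 = unname(n2))
}

#' Chi-squared statistic for one edge type across two classes
#'
#' Expected counts under independence: `E_c = (n1 + n2) * total_c / (total1 +
#' total2)`. The statistic is `sum((N - E)^2 / E)` over the two class cells;
#' a type observed in neither class scores 0.
#'
#' @param n1,n2 Observed counts of the type in class 1 / class 2 (vectorized).
#' @param total1,total2 Total edge counts of each class.
#' @return Non-negative statistic (vector).
#' @export
chi2_stat <- function(n1, n2, total1, total2) {
  grand <- total1 + total2
  row_tot <- n1 + n2
  e1 <- row_tot * total1 / grand
  e2 <- row_tot * total2 / grand
  out <- rep(0, length(n1))
  pos <- row_tot > 0 & e1 > 0 & e2 > 0
  out[pos] <- (n1[pos] - e1[pos])^2 / e1[pos] + (n2[pos] - e2[pos])^2 / e2[pos]
  out
}

#' Smoothed log-odds ratio of within-class type frequencies
#'
#' `log(P/Q)` (natural log) where `P = (n1 + pseudocount) / (total1 + n_keys
#' * pseudocount)` is the smoothed frequency of the type within class 1 and
#' `Q` likewise for class 2.
#'
#' @param n1,n2 Observed counts (vectorized).
#' @param total1,total2 Class totals.
#' @param pseudocount Additive smoothing per cell (default 0.5).
#' @param n_keys Number of type keys sharing the class total (210 for pairs,
#'   20 for single residues).
#' @return Log-odds values (vector).
#' @export
log_odds <- function(n1, n2, total1, total2, pseudocount = 0.5, n_keys = 210) {
  p <- (n1 + pseudocount) / (total1 + n_keys * pseudocount)
  q <- (n2 + pseudocount) / (total2 + n_keys * pseudocount)
  log(p / q)
}

# min-max normalization to [0,1]; constant input -> all 0.5 with a warning
.minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant weight table; normalizing to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Normalize two weight tables and mix them
#'
#' Min-max normalizes the chi-squared and log-odds tables to `[0, 1]` across
#' their keys, then returns the convex combination
#' `alpha * chi2_norm + (1 - alpha) * log_odds_norm`.
#'
#' @param chi2 Numeric vector of chi-squared values.
#' @param lo Numeric vector of log-odds values (same length/order).
#' @param alpha Mixing weight on the chi-squared component (default 0.3).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_and_combine <- function(chi2, lo, alpha = 0.3) {
  stopifnot(length(chi2) == length(lo), alpha >= 0, alpha <= 1)
  alpha * .minmax(chi2) + (1 - alpha) * .minmax(lo)
}

#' Contrast transform for normalized weights
#'
#' `f(W) = 1 / (1 + theta * (W / (1 - W))^(-gamma))`: a strictly increasing
#' sigmoid on `(0, 1)` that amplifies large weights and suppresses small
#' ones; inputs are clamped to `[1e-9, 1 - 1e-9]`.
#'
#' @param w Normalized weights in `[0, 1]`.
#' @param theta,gamma Contrast parameters (both default 3).
#' @return Contrasted weights in `(0, 1)`.
#' @export
contrast_weight <- function(w, theta = 3, gamma = 3) {
  stopifnot(theta > 0, gamma > 0)
  w <- pmin(pmax(w, 1e-9), 1 - 1e-9)
  1 / (1 + theta * (w / (1 - w))^(-gamma))
}

#' Learn the weight table for one class contrast
#'
#' Full pipeline over the 210 residue-pair types: class counts, chi-squared
#' and smoothed log-odds, min-max normalization, alpha-mixing and contrast.
#'
#' @param graphs List of labelled `surface_graph` objects.
#' @param class_pair The two edge classes contrasted (default epitope vs
#'   non-epitope).
#' @param alpha Mixing weight (default 0.3).
#' @param theta,gamma Contrast parameters (default 3, 3).
#' @param pseudocount Log-odds smoothing.
#' @return Tibble with 210 rows: `type`, `n1`, `n2`, `chi2`, `log_odds`,
#'   `combined` (normalized mix) and `weight` (contrasted), plus attributes
#'   `alpha`, `theta`, `gamma`, `class_pair`.
#' @export
weight_table <- function(graphs, class_pair = c("epitope", "non-epitope"),
                         alpha = 0.3, theta = 3, gamma = 3, pseudocount = 0.5) {
  cnt <- count_edge_types(graphs, class_pair)
  t1 <- sum(cnt$n1); t2 <- sum(cnt$n2)
  cnt$chi2 <- chi2_stat(cnt$n1, cnt$n2, t1, t2)
  cnt$log_odds <- log_odds(cnt$n1, cnt$n2, t1, t2, pseudocount, n_keys = 210)
  cnt$combined <- normalize_and_combine(cnt$chi2, cnt$log_odds, alpha)
  cnt$weight <- contrast_weight(cnt$combined, theta, gamma)
  attr(cnt, "alpha") <- alpha
  attr(cnt, "theta") <- theta
  attr(cnt, "gamma") <- gamma
  attr(cnt, "class_pair") <- class_pair
  cnt
}

#' Single-residue statistics
#'
#' The same chi-squared + log-odds machinery applied to node-type frequencies
#' (epitope residues vs non-epitope residues) over the 20 amino acids.
#'
#' @inheritParams weight_table
#' @return Tibble with 20 rows: `aa`, `n1`, `n2`, `chi2`, `log_odds`,
#'   `combined`, `weight`.
#' @export
singles_table <- function(graphs, alpha = 0.3, theta = 3, gamma = 3,
                          pseudocount = 0.5) {
  aa <- amino_acids()
  n1 <- setNames(integer(20), aa); n2 <- n1
  for (g in graphs) {
    t1 <- table(g$nodes$aa[g$nodes$label == "epitope"])
    t2 <- table(g$nodes$aa[g$nodes$label == "non-epitope"])
    n1[names(t1)] <- n1[names(t1)] + as.integer(t1)
    n2[names(t2)] <- n2[names(t2)] + as.integer(t2)
  }
  if (sum(n1) + sum(n2) == 0) stop("no labelled residues in the supplied graphs")
  out <- tibble::tibble(aa = aa, n1 = unname(n1), n2 = unname(n2))
  out$chi2 <- chi2_stat(out$n1, out$n2, sum(out$n1), sum(out$n2))
  out$log_odds <- log_odds(out$n1, out$n2, sum(out$n1), sum(out$n2),
                           pseudocount, n_keys = 20)
  out$combined <- normalize_and_combine(out$chi2, out$log_odds, alpha)
  out$weight <- contrast_weight(out$combined, theta, gamma)
  out
}

#' Boundary-edge suppression model
#'
#' Boundary edges (epitope endpoint + non-epitope endpoint) are contrasted
#' against epitope edges (weights W') and against non-epitope edges (W''),
#' each through the full normalize/mix/contrast pipeline; a type's boundary
#' score combines the two. A contrast only counts for types actually
#' overrepresented among boundary edges (positive boundary log-odds): the
#' chi-squared component is direction-blind, and a type enriched *inside*
#' epitopes would otherwise be flagged and its cohesive edges destroyed.
#' With `combine = "min"` (the default) a type must moreover stand out from
#' *both* flanking classes to count as definitely boundary; `combine =
#' "max"` takes the larger of the two contrasts instead, which is more
#' aggressive and can still sacrifice epitope-internal types sitting next
#' to same-type neighbours. Types scoring above the `w0_percentile`
#' percentile of the 210 scores are treated as definite boundary types and
#' removed from graphs before clustering.
#'
#' @inheritParams weight_table
#' @param w0_percentile Percentile (0-100) of scores that sets the
#'   suppression threshold `w0`.
#' @param combine `"min"` (boundary-enriched against both classes) or
#'   `"max"` (against either).
#' @return A `boundary_model`: list with `scores` (tibble: `type`, `w_epi`,
#'   `w_non`, `score`), `w0`, and the parameters used.
#' @export
boundary_model <- function(graphs, alpha = 0.3, theta = 3, gamma = 3,
                           pseudocount = 0.5, w0_percentile = 75,
                           combine = c("min", "max")) {
  combine <- match.arg(combine)
  n_boundary <- sum(vapply(graphs, function(g) {
    sum(.edge_classes(g) == "boundary", na.rm = TRUE)
  }, numeric(1)))
  if (n_boundary == 0) stop("no boundary edges in the training graphs")
  w_epi <- weight_table(graphs, c("boundary", "epitope"),
                        alpha, theta, gamma, pseudocount)
  w_non <- weight_table(graphs, c("boundary", "non-epitope"),
                        alpha, theta, gamma, pseudocount)
  s_epi <- ifelse(w_epi$log_odds > 0, w_epi$weight, 0)
  s_non <- ifelse(w_non$log_odds > 0, w_non$weight, 0)
  score <- if (combine == "min") pmin(s_epi, s_non) else pmax(s_epi, s_non)
  scores <- tibble::tibble(type = w_epi$type, w_epi = s_epi,
                           w_non = s_non, score = score)
  structure(
    list(scores = scores,
         w0 = unname(quantile(scores$score, w0_percentile / 100)),
         w0_percentile = w0_percentile, combine = combine,
         alpha = alpha, theta = theta, gamma = gamma),
    class = "boundary_model"
  )
}

#' @export
print.boundary_model <- function(x, ...) {
  cat("<boundary_model> w0 =", format(x$w0, digits = 4),
      sprintf("(%g%% percentile); %d/210 types suppressed\n",
              x$w0_percentile, sum(x$scores$score > x$w0)))
  invisible(x)
}

#' Apply learned weights (and boundary suppression) to a surface graph
#'
#' Sets every edge's weight to the contrasted combined weight of its type
#' and, unless `suppress = FALSE`, removes edges whose type's boundary score
#' exceeds `w0`.
#'
#' @param graph A `surface_graph`.
#' @param wt Weight table from [weight_table()].
#' @param boundary Optional `boundary_model`; `NULL` skips suppression.
#' @param suppress `"remove"` deletes edges of suppressed types;
#'   `"downweight"` keeps them but multiplies their weight by
#'   `downweight_factor`, preserving graph topology for the clustering;
#'   `"none"` only populates weights. `TRUE`/`FALSE` are accepted as
#'   `"remove"`/`"none"`.
#' @param downweight_factor Multiplier for suppressed types under
#'   `"downweight"`.
#' @return The weighted (possibly pruned) `surface_graph`.
#' @export
apply_weights <- function(graph, wt, boundary = NULL, suppress = "remove",
                          downweight_factor = 0.1) {
  if (isTRUE(suppress)) suppress <- "remove"
  if (isFALSE(suppress)) suppress <- "none"
  suppress <- match.arg(suppress, c("remove", "downweight", "none"))
  w_of <- setNames(wt$weight, wt$type)
  unknown <- !(graph$edges$type %in% wt$type)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " edges with unknown residue types")
    graph$edges <- graph$edges[!unknown, , drop = FALSE]
  }
  graph$edges$weight <- unname(w_of[graph$edges$type])
  if (!is.null(boundary) && suppress != "none") {
    bad <- graph$edges$type %in%
      boundary$scores$type[boundary$scores$score > boundary$w0]
    if (suppress == "remove") {
      graph$edges <- graph$edges[!bad, , drop = FALSE]
    } else {
      graph$edges$weight[bad] <- graph$edges$weight[bad] * downweight_factor
    }
  }
  graph
}
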