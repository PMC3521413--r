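# Markov Clustering of weighted surface graphs.

# column-normalize a non-negative matrix; all-zero columns get a 1 on the
# diagonal (isolated node keeps its own flow)
.col_normalize <- function(m) {
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    m[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(m, 2, cs, "/")
}

#' Markov Clustering of a weighted surface graph
#'
#' Simulates flow on the graph: the column-stochastic matrix is alternately
#' expanded (matrix power, spreading flow) and inflated (entrywise Hadamard
#' power with coefficient `inflation` followed by column renormalization,
#' sharpening flow) until the matrix stops changing. Clusters are read from
#' the attractor rows of the equilibrium matrix; each node joins the
#' attractor with the largest support on its column (ties to the
#' lowest-indexed attractor), so the clusters always partition the node set.
#'
#' Self-loops are added before normalization with loop weight equal to the
#' node's maximum incident edge weight (1 for isolated nodes).
#'
#' @param graph A weighted `surface_graph` (edges with `NA` weight count
#'   as 1).
#' @param inflation Hadamard-power coefficient r (default 1.8).
#' @param expansion Matrix-power exponent (default 2).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max entrywise change.
#' @param prune Entries below this are zeroed each iteration.
#' @return List of clusters (character vectors of residue keys), with
#'   attributes `iterations` and `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 1.8, expansion = 2,
                        max_iter = 200, tol = 1e-8, prune = 1e-6) {
  keys <- graph$nodes$res_key
  n <- length(keys)
  if (n == 0) stop("empty graph")
  a <- matrix(0, n, n, dimnames = list(keys, keys))
  if (nrow(graph$edges) > 0) {
    w <- graph$edges$weight
    w[is.na(w)] <- 1
    if (any(w < 0)) stop("negative edge weights")
    i <- match(graph$edges$from, keys)
    j <- match(graph$edges$to, keys)
    a[cbind(i, j)] <- w
    a[cbind(j, i)] <- w
  }
  loop <- apply(a, 1, max)
  loop[loop == 0] <- 1
  diag(a) <- loop
  m <- .col_normalize(a)

  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    mx <- m
    for (e in seq_len(expansion - 1)) mx <- mx %*% m  # expansion
    mx <- mx^inflation                                 # inflation
    mx[mx < prune] <- 0
    mx <- .col_normalize(mx)
    delta <- max(abs(mx - m))
    m <- mx
    if (delta < tol) { converged <- TRUE; break }
  }

  attractors <- which(diag(m) > prune)
  if (length(attractors) == 0) attractors <- seq_len(n)
  support <- m[attractors, , drop = FALSE]
  owner <- apply(support, 2, which.max)       # ties -> lowest attractor index
  covered <- apply(support, 2, max) > 0
  owner[!covered] <- NA
  cluster_id <- attractors[owner]
  # nodes unsupported by any attractor become singletons
  if (anyNA(cluster_id)) cluster_id[is.na(cluster_id)] <- -which(is.na(cluster_id))
  groups <- split(keys, cluster_id)
  groups <- unname(groups[order(vapply(groups, function(g) min(match(g, keys)),
                                       numeric(1)))])
  attr(groups, "iterations") <- iter
  attr(groups, "converged") <- converged
  groups
}

#' Training label of a subgraph cluster
#'
#' A subgraph with no or very few (at most `max_epi_in_negative`) epitope
#' residues is a non-epitope subgraph; otherwise it is an epitope subgraph
#' when its epitope residues outnumber its non-epitope residues; any other
#' mixture is noise and is excluded from model training. The few-epitope
#' rule is applied first, so tiny all-epitope fragments (one edge, two
#' residues) do not become epitope prototypes: a lone strong residue pair
#' also arises by chance on non-epitope surface and must not define the
#' class.
#'
#' @param members Character vector of residue keys in the cluster.
#' @param node_labels Named character vector residue key -> label
#'   (`"epitope"` / `"non-epitope"`).
#' @param max_epi_in_negative Largest epitope count tolerated in a
#'   non-epitope subgraph (default 2).
#' @return One of `"epitope"`, `"non-epitope"`, `"noise"`.
#' @export
assign_training_label <- function(members, node_labels, max_epi_in_negative = 2) {
  lab <- node_labels[members]
  if (anyNA(lab) || any(!lab %in% c("epitope", "non-epitope"))) {
    stop("all cluster members must be labelled epitope or non-epitope")
  }
  n_epi <- sum(lab == "epitope")
  n_non <- sum(lab == "non-epitope")
  if (n_epi <= max_epi_in_negative) "non-epitope"
  else if (n_epi > n_non) "epitope"
  else "noise"
}

#' Cluster assignments as a tibble
#'
#' @param clusters List of clusters from [mcl_cluster()].
#' @param node_labels Optional named label vector; adds a `training_label`
#'   column via [assign_training_label()].
#' @return Tibble: `res_key`, `cluster_id` and optionally `training_label`.
#' @export
cluster_assignments <- function(clusters, node_labels = NULL) {
  out <- tibble::tibble(
    res_key = unlist(clusters),
    cluster_id = rep(seq_along(clusters),
                     vapply(clusters, length, integer(1)))
  )
  if (!is.null(node_labels)) {
    labs <- vapply(clusters, assign_training_label, character(1),
                   node_labels = node_labels)
    out$training_label <- labs[out$cluster_id]
  }
  out
}
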