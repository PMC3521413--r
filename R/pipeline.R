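# End-to-end orchestration: training on labelled complexes, prediction for
# unbound antigens, model bundle (de)serialization.

#' Train an epitope prediction model
#'
#' Runs the full training pipeline: optional curation, 4 A epitope
#' labelling, surface-graph construction, edge-weight learning (epitope vs
#' non-epitope contrast, boundary suppression, single-residue statistics),
#' Markov Clustering of the weighted graphs, subgraph labelling (noise
#' subgraphs are excluded), vectorization, feature selection and the
#' balanced SVM ensemble.
#'
#' @param complexes List of `complex_record` objects with antibody chains,
#'   or of [generate_complex()] outputs.
#' @param alpha Chi-squared / log-odds mixing weight (default 0.3).
#' @param theta,gamma Contrast parameters (default 3, 3).
#' @param inflation MCL inflation coefficient (default 1.8).
#' @param theta0,tau0 Voting threshold and dubiety band (defaults 0.3,
#'   0.05).
#' @param w0_percentile Boundary-suppression percentile (default 75).
#' @param target_count Feature-selection cap (default 144).
#' @param curate_input Apply [curate()] first (default `TRUE`).
#' @param seed Seed for all stochastic steps.
#' @param verbose Log per-stage counts.
#' @return A `betop_model` bundle (serializable with [write_model()]).
#' @export
betop_train <- function(complexes, alpha = 0.3, theta = 3, gamma = 3,
                        inflation = 1.8, theta0 = 0.3, tau0 = 0.05,
                        w0_percentile = 75, target_count = 144,
                        curate_input = TRUE, seed = 1, verbose = FALSE) {
  complexes <- lapply(complexes, .as_complex_record)
  if (length(complexes) < 2) {
    stop("training needs at least 2 labelled complexes")
  }
  if (curate_input) {
    complexes <- curate(complexes)
    if (length(complexes) < 2) stop("fewer than 2 complexes survive curation")
  }
  say <- function(...) if (verbose) message(...)

  graphs <- lapply(complexes, antigen_surface_graph)
  say("built ", length(graphs), " labelled surface graphs (",
      sum(vapply(graphs, function(g) nrow(g$nodes), numeric(1))), " residues, ",
      sum(vapply(graphs, function(g) nrow(g$edges), numeric(1))), " edges)")

  wt <- weight_table(graphs, c("epitope", "non-epitope"), alpha, theta, gamma)
  singles <- singles_table(graphs, alpha, theta, gamma)
  boundary <- boundary_model(graphs, alpha, theta, gamma,
                             w0_percentile = w0_percentile)

  space <- enumerate_feature_space()
  singles_vec <- setNames(singles$weight, singles$aa)
  xs <- list(); ys <- character(); antigen_of <- integer()
  n_noise <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    gw <- apply_weights(g, wt, boundary)
    clusters <- mcl_cluster(gw, inflation = inflation)
    labs <- setNames(g$nodes$label, g$nodes$res_key)
    for (cl in clusters) {
      lab <- assign_training_label(cl, labs)
      if (lab == "noise") { n_noise <- n_noise + 1L; next }
      xs[[length(xs) + 1]] <- vectorize_subgraph(cl, gw, singles_vec, space)
      ys <- c(ys, lab)
      antigen_of <- c(antigen_of, gi)
    }
  }
  if (length(xs) == 0 || length(unique(ys)) < 2) {
    stop("clustering produced no usable training subgraphs (",
         n_noise, " noise clusters); check labelling and weights")
  }
  x <- do.call(rbind, xs)
  say("training subgraphs: ", sum(ys == "epitope"), " epitope, ",
      sum(ys == "non-epitope"), " non-epitope, ", n_noise, " noise (dropped)")

  mask <- select_features(x, ys, target_count = target_count, seed = seed,
                          groups = antigen_of)
  ensemble <- build_ensemble(x[, mask, drop = FALSE], ys,
                             theta0 = theta0, tau0 = tau0, seed = seed,
                             groups = antigen_of)
  say("selected ", length(mask), " features; ensemble of ", ensemble$k,
      " classifiers")

  structure(
    list(weights = wt, singles = singles, boundary = boundary,
         mask = as.character(mask), ensemble = ensemble,
         params = list(alpha = alpha, theta = theta, gamma = gamma,
                       inflation = inflation, theta0 = theta0, tau0 = tau0,
                       w0_percentile = w0_percentile, seed = seed)),
    class = "betop_model"
  )
}

.as_complex_record <- function(x) {
  if (inherits(x, "complex_record")) return(x)
  if (is.list(x) && !is.null(x$pdb_text)) {
    return(parse_structure(x$pdb_text, x$antigen_chains, x$antibody_chains))
  }
  stop("cannot interpret input as a complex record")
}

#' @export
print.betop_model <- function(x, ...) {
  cat("<betop_model> ", length(x$mask), " selected features; ensemble of ",
      x$ensemble$k, " SVMs; alpha = ", x$params$alpha,
      ", inflation = ", x$params$inflation, "\n", sep = "")
  invisible(x)
}

#' @method glance betop_model
#' @export
glance.betop_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$mask),
    n_classifiers = x$ensemble$k,
    alpha = x$params$alpha,
    inflation = x$params$inflation,
    theta0 = x$params$theta0,
    tau0 = x$params$tau0,
    w0 = x$boundary$w0
  )
}

#' @method tidy betop_model
#' @export
tidy.betop_model <- function(x, ...) {
  x$weights
}

#' Predict epitopes for an unbound antigen
#'
#' Builds the antigen's surface graph, assigns the trained edge weights and
#' removes definite-boundary edge types, clusters by MCL, classifies every
#' subgraph with the SVM ensemble, and merges predicted epitope subgraphs
#' that are connected in the surface graph. Merging uses the
#' suppression-filtered graph: an edge of a definite-boundary type is, by
#' the model's own learning, evidence of an epitope/non-epitope frontier
#' and must not act as a conduit that fuses two distinct epitopes.
#'
#' @param antigen A `complex_record` (antibody role may be empty) or a
#'   [generate_complex()] output.
#' @param model A `betop_model`.
#' @return A `betop_prediction`: list with `epitopes` (list of residue-key
#'   vectors, merged), `scores` (mean subgraph vote score per epitope),
#'   `residues` (per-residue tibble: `res_key`, `aa`, `score`, `predicted`,
#'   `epitope_id`) and `graph` (the weighted surface graph).
#' @export
betop_predict <- function(antigen, model) {
  antigen <- .as_complex_record(antigen)
  graph <- antigen_surface_graph(antigen, label = FALSE)
  if (nrow(graph$nodes) < 1) stop("antigen has no surface residues")
  gw <- apply_weights(graph, model$weights, model$boundary)
  clusters <- mcl_cluster(gw, inflation = model$params$inflation)
  singles_vec <- setNames(model$singles$weight, model$singles$aa)
  space <- enumerate_feature_space()

  labels <- character(length(clusters))
  scores <- numeric(length(clusters))
  for (i in seq_along(clusters)) {
    v <- vectorize_subgraph(clusters[[i]], gw, singles_vec, space)
    pr <- predict_subgraph(v[model$mask], model$ensemble)
    labels[i] <- pr$label
    scores[i] <- pr$score
  }

  epi_idx <- which(labels == "epitope")
  merged <- .merge_connected_clusters(clusters[epi_idx], gw)
  epi_scores <- vapply(attr(merged, "members"), function(ids) {
    mean(scores[epi_idx][ids])
  }, numeric(1))

  res <- graph$nodes[, c("res_key", "aa")]
  res$score <- NA_real_
  for (i in seq_along(clusters)) res$score[res$res_key %in% clusters[[i]]] <- scores[i]
  res$predicted <- FALSE
  res$epitope_id <- NA_integer_
  for (e in seq_along(merged)) {
    hit <- res$res_key %in% merged[[e]]
    res$predicted[hit] <- TRUE
    res$epitope_id[hit] <- e
  }

  structure(
    list(epitopes = lapply(merged, identity), scores = epi_scores,
         residues = tibble::as_tibble(res), graph = gw),
    class = "betop_prediction"
  )
}

# merge predicted epitope subgraphs joined by any edge of the original
# surface graph (connected components, so merging is transitive and
# order-independent)
.merge_connected_clusters <- function(clusters, graph) {
  k <- length(clusters)
  if (k == 0) {
    out <- list()
    attr(out, "members") <- list()
    return(out)
  }
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- integer(0)
  key_owner <- setNames(rep(seq_len(k), lengths(clusters)), unlist(clusters))
  o1 <- key_owner[graph$edges$from]
  o2 <- key_owner[graph$edges$to]
  link <- which(!is.na(o1) & !is.na(o2) & o1 != o2)
  for (e in link) {
    r1 <- find(o1[[e]]); r2 <- find(o2[[e]])
    if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
  }
  root <- vapply(seq_len(k), find, integer(1))
  comp <- split(seq_len(k), root)
  out <- lapply(comp, function(ids) sort(unique(unlist(clusters[ids]))))
  members <- lapply(comp, identity)
  out <- unname(out)
  attr(out, "members") <- unname(members)
  out
}

#' @export
print.betop_prediction <- function(x, ...) {
  cat("<betop_prediction> ", length(x$epitopes), " predicted epitope(s); ",
      sum(x$residues$predicted), "/", nrow(x$residues),
      " surface residues predicted epitope\n", sep = "")
  invisible(x)
}

#' @method tidy betop_prediction
#' @export
tidy.betop_prediction <- function(x, ...) {
  x$residues
}

#' @method glance betop_prediction
#' @export
glance.betop_prediction <- function(x, ...) {
  tibble::tibble(
    n_epitopes = length(x$epitopes),
    n_predicted_residues = sum(x$residues$predicted),
    n_surface_residues = nrow(x$residues),
    top_score = if (length(x$scores) > 0) max(x$scores) else NA_real_
  )
}

#' Serialize a trained model to a single JSON bundle
#'
#' @param model A `betop_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "betop_model",
    version = 1L,
    params = model$params,
    weights = as.data.frame(model$weights),
    singles = as.data.frame(model$singles),
    boundary = list(scores = as.data.frame(model$boundary$scores),
                    w0 = model$boundary$w0,
                    combine = model$boundary$combine,
                    w0_percentile = model$boundary$w0_percentile,
                    alpha = model$boundary$alpha,
                    theta = model$boundary$theta,
                    gamma = model$boundary$gamma),
    mask = model$mask,
    ensemble = list(
      k = model$ensemble$k, w = model$ensemble$w,
      theta0 = model$ensemble$theta0, tau0 = model$ensemble$tau0,
      seed = model$ensemble$seed, features = model$ensemble$features,
      classifiers = lapply(model$ensemble$classifiers, function(cl) {
        list(sv = cl$sv, coefs = cl$coefs, rho = cl$rho, gamma = cl$gamma,
             sign = cl$sign, platt_a = cl$platt_a, platt_b = cl$platt_b,
             cost = cl$cost, cv_fscore = cl$cv_fscore)
      })
    )
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           dataframe = "columns")
  writeLines(as.character(json), path)
  invisible(path)
}

#' Read a model bundle written by [write_model()]
#'
#' @param path JSON bundle path.
#' @return A `betop_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  if (is.null(obj$format) || obj$format != "betop_model") {
    stop("not a betop model bundle: ", path)
  }
  boundary <- structure(
    list(scores = tibble::as_tibble(obj$boundary$scores),
         w0 = obj$boundary$w0, w0_percentile = obj$boundary$w0_percentile,
         combine = obj$boundary$combine,
         alpha = obj$boundary$alpha, theta = obj$boundary$theta,
         gamma = obj$boundary$gamma),
    class = "boundary_model"
  )
  classifiers <- lapply(seq_len(obj$ensemble$k), function(i) {
    cl <- if (is.data.frame(obj$ensemble$classifiers)) {
      lapply(obj$ensemble$classifiers, `[[`, i)
    } else obj$ensemble$classifiers[[i]]
    cl$coefs <- as.numeric(cl$coefs)
    cl$sv <- if (is.matrix(cl$sv)) cl$sv else
      matrix(unlist(cl$sv), nrow = length(cl$coefs), byrow = TRUE)
    cl
  })
  ensemble <- structure(
    list(classifiers = classifiers, w = as.numeric(obj$ensemble$w),
         theta0 = obj$ensemble$theta0, tau0 = obj$ensemble$tau0,
         k = obj$ensemble$k, seed = obj$ensemble$seed,
         features = as.character(obj$ensemble$features)),
    class = "betop_ensemble"
  )
  structure(
    list(weights = tibble::as_tibble(obj$weights),
         singles = tibble::as_tibble(obj$singles),
         boundary = boundary, mask = as.character(obj$mask),
         ensemble = ensemble, params = obj$params),
    class = "betop_model"
  )
}
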