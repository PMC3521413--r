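# Residue-level antigen surface graphs from Delaunay tessellation of
# surface atoms.

#' Delaunay edges of a set of surface atoms
#'
#' 3D Delaunay tessellation of the atom positions (incremental
#' Bowyer-Watson); the edge set of the tessellation defines spatial
#' neighbourhood between atoms. Near-degenerate inputs are retried once with
#' a deterministic symmetric jitter of 1e-6 Angstrom; truly degenerate inputs
#' (fewer than 4 atoms, or coplanar/collinear points) raise an error.
#'
#' @param surface_atoms Tibble of atoms (needs `serial`, `x`, `y`, `z`).
#' @return Two-column integer matrix of atom serial pairs (each edge once).
#' @export
delaunay_atom_graph <- function(surface_atoms) {
  n <- nrow(surface_atoms)
  if (n < 4) stop("Delaunay tessellation needs at least 4 atoms, got ", n)
  coords <- as.matrix(surface_atoms[, c("x", "y", "z")])
  ctr <- sweep(coords, 2, colMeans(coords))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate input: surface atoms are coplanar or collinear")
  }
  idx <- tryCatch(
    .delaunay_edges_cpp(coords),
    error = function(e) {
      set.seed(20120)
      jit <- matrix(runif(3 * n, -1, 1) * 1e-6, ncol = 3)
      .delaunay_edges_cpp(coords + jit)
    }
  )
  cbind(surface_atoms$serial[idx[, 1]], surface_atoms$serial[idx[, 2]])
}

#' Upgrade an atom-level contact graph to a residue-level surface graph
#'
#' Drops atom contacts within a single residue, removes atom contacts longer
#' than `max_dist` (strictly greater), and merges the surviving atom contacts
#' between each residue pair into one undirected residue edge. Every residue
#' with at least one surface atom becomes a node (isolated residues are
#' kept); a node's position is the centroid of its surface atoms.
#'
#' @param atom_edges Matrix of atom-serial pairs from [delaunay_atom_graph()].
#' @param atoms Tibble of the same surface atoms (needs `serial`, `res_key`,
#'   `aa`, `x`, `y`, `z`; an optional logical `epitope` column sets node
#'   labels).
#' @param max_dist Atom-contact length cutoff in Angstrom (default 6.0).
#' @return A `surface_graph`: list with `nodes` (tibble: `res_key`, `aa`,
#'   `x`, `y`, `z`, `label`) and `edges` (tibble: `from`, `to`, `type`,
#'   `weight`, with `from` < `to` and `weight` initially `NA`).
#' @export
upgrade_to_residue_graph <- function(atom_edges, atoms, max_dist = 6.0) {
  stopifnot(ncol(atom_edges) == 2)
  pos <- match(atom_edges[, 1], atoms$serial)
  qos <- match(atom_edges[, 2], atoms$serial)
  if (anyNA(pos) || anyNA(qos)) stop("atom_edges reference unknown serials")

  d <- sqrt((atoms$x[pos] - atoms$x[qos])^2 +
              (atoms$y[pos] - atoms$y[qos])^2 +
              (atoms$z[pos] - atoms$z[qos])^2)
  rk1 <- atoms$res_key[pos]
  rk2 <- atoms$res_key[qos]
  keep <- rk1 != rk2 & d <= max_dist
  rk1 <- rk1[keep]; rk2 <- rk2[keep]

  swap <- rk1 > rk2
  from <- ifelse(swap, rk2, rk1)
  to <- ifelse(swap, rk1, rk2)
  ek <- paste(from, to, sep = "\r")
  first <- !duplicated(ek)
  from <- from[first]; to <- to[first]

  nodes <- atoms %>%
    dplyr::group_by(.data$res_key) %>%
    dplyr::summarise(aa = .data$aa[1], x = mean(.data$x), y = mean(.data$y),
                     z = mean(.data$z),
                     label = if ("epitope" %in% names(atoms)) {
                       if (.data$epitope[1]) "epitope" else "non-epitope"
                     } else "unknown",
                     .groups = "drop") %>%
    dplyr::arrange(.data$res_key)

  aa_of <- setNames(nodes$aa, nodes$res_key)
  edges <- tibble::tibble(
    from = from, to = to,
    type = .pair_type(unname(aa_of[from]), unname(aa_of[to])),
    weight = NA_real_
  ) %>% dplyr::arrange(.data$from, .data$to)

  structure(list(nodes = nodes, edges = edges), class = "surface_graph")
}

#' Build the surface graph of the antigen in a complex
#'
#' Convenience wrapper: ASA, surface-atom selection, Delaunay tessellation
#' and residue-graph upgrade in one call. If the complex has antibody chains
#' and `label = TRUE`, nodes are labelled epitope / non-epitope by the
#' distance rule of [label_epitope_residues()].
#'
#' @param complex A `complex_record`.
#' @param asa_threshold Surface-atom ASA cutoff (Angstrom^2).
#' @param max_dist Residue-contact length cutoff (Angstrom).
#' @param label Label nodes from the antibody contacts when available.
#' @param contact_cutoff Epitope labelling distance (Angstrom).
#' @return A `surface_graph`.
#' @export
antigen_surface_graph <- function(complex, asa_threshold = 10, max_dist = 6.0,
                                  label = TRUE, contact_cutoff = 4.0) {
  # accessibility of the unbound antigen: antibody atoms must not occlude
  # the epitope surface
  ag_all <- complex$atoms[complex$atoms$role == "antigen", , drop = FALSE]
  asa <- compute_asa(ag_all)
  surf <- surface_atoms(asa, asa_threshold)
  ag <- ag_all[ag_all$serial %in% surf, , drop = FALSE]
  if (nrow(ag) < 4) stop("antigen has fewer than 4 surface atoms")
  if (label && length(complex$antibody_chains) > 0) {
    epi <- label_epitope_residues(complex, contact_cutoff)
    ag$epitope <- ag$res_key %in% epi
  }
  edges <- delaunay_atom_graph(ag)
  upgrade_to_residue_graph(edges, ag, max_dist = max_dist)
}

#' @export
print.surface_graph <- function(x, ...) {
  nl <- table(factor(x$nodes$label, c("epitope", "non-epitope", "unknown")))
  cat("<surface_graph> ", nrow(x$nodes), " residues, ", nrow(x$edges),
      " edges (", nl[["epitope"]], " epitope / ", nl[["non-epitope"]],
      " non-epitope / ", nl[["unknown"]], " unlabelled residues)\n", sep = "")
  invisible(x)
}

#' @method tidy surface_graph
#' @export
tidy.surface_graph <- function(x, ...) {
  x$edges
}

#' @method glance surface_graph
#' @export
glance.surface_graph <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_epitope = sum(x$nodes$label == "epitope"),
    n_non_epitope = sum(x$nodes$label == "non-epitope")
  )
}

#' Serialize a surface graph to JSON
#' @param graph A `surface_graph`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_surface_graph <- function(graph, path = NULL) {
  js <- jsonlite::toJSON(list(nodes = graph$nodes, edges = graph$edges),
                         digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a surface graph from JSON
#' @param path File path or JSON string from [write_surface_graph()].
#' @return A `surface_graph`.
#' @export
read_surface_graph <- function(path) {
  obj <- jsonlite::fromJSON(path)
  nodes <- tibble::as_tibble(obj$nodes)
  edges <- tibble::as_tibble(obj$edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            type = character(), weight = numeric())
  }
  edges$weight <- as.numeric(edges$weight)
  structure(list(nodes = nodes, edges = edges), class = "surface_graph")
}
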