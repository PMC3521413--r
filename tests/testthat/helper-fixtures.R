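# Shared fixtures, built in code.

# vertices of a regular tetrahedron with unit edge
tetrahedron_atoms <- function() {
  tibble::tibble(
    serial = 1:4,
    element = "C",
    x = c(0, 1, 0.5, 0.5),
    y = c(0, 0, sqrt(3) / 2, sqrt(3) / 6),
    z = c(0, 0, 0, sqrt(2 / 3))
  )
}

# hand-built surface graph: nodes with chosen amino acids and labels,
# edges with chosen weights
toy_graph <- function(aa, label, edges, weights = NULL) {
  n <- length(aa)
  keys <- sprintf("T:%03d:_", seq_len(n))
  nodes <- tibble::tibble(res_key = keys, aa = aa,
                          x = seq_len(n), y = 0, z = 0, label = label)
  from <- keys[edges[, 1]]
  to <- keys[edges[, 2]]
  sw <- from > to
  tmp <- from[sw]; from[sw] <- to[sw]; to[sw] <- tmp
  e <- tibble::tibble(
    from = from, to = to,
    type = betopr:::.pair_type(aa[edges[, 1]], aa[edges[, 2]]),
    weight = if (is.null(weights)) NA_real_ else weights
  )
  structure(list(nodes = nodes, edges = e), class = "surface_graph")
}

# two k-cliques (uniform weight 1) joined by a single weak edge
two_clique_graph <- function(k = 4, bridge_weight = 0.01) {
  n <- 2 * k
  edges <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    edges <- rbind(edges, c(i, j), c(k + i, k + j))
  }
  w <- rep(1, nrow(edges))
  edges <- rbind(edges, c(k, k + 1))
  w <- c(w, bridge_weight)
  toy_graph(rep("A", n), rep("unknown", n), edges, w)
}

# brute-force 3D Delaunay edge oracle: a pair is an edge iff some
# circumsphere through the pair and two other points is empty
brute_delaunay_edges <- function(coords) {
  n <- nrow(coords)
  circumcenter <- function(p) {
    a <- 2 * rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
    b <- c(sum(p[2, ]^2) - sum(p[1, ]^2),
           sum(p[3, ]^2) - sum(p[1, ]^2),
           sum(p[4, ]^2) - sum(p[1, ]^2))
    tryCatch(solve(a, b), error = function(e) NULL)
  }
  tets <- utils::combn(n, 4)
  edges <- matrix(nrow = 0, ncol = 2)
  for (t in seq_len(ncol(tets))) {
    idx <- tets[, t]
    cc <- circumcenter(coords[idx, , drop = FALSE])
    if (is.null(cc)) next
    r2 <- sum((coords[idx[1], ] - cc)^2)
    d2 <- rowSums(sweep(coords, 2, cc)^2)
    if (all(d2[-idx] > r2 + 1e-9)) {
      edges <- rbind(edges, t(utils::combn(idx, 2)))
    }
  }
  unique(as.data.frame(t(apply(edges, 1, sort))))
}

# residue-key helper matching the package's internal format
rk <- function(chain, resno) sprintf("%s:%d:_", chain, resno)
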