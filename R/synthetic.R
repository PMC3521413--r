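# Seeded synthetic antibody-antigen complexes and planted-partition graphs
# with known ground truth, so every pipeline stage is testable without
# structure downloads.

#' Specification of a synthetic antigen-antibody complex
#'
#' The generator emulates the geometry and composition the pipeline relies
#' on: pseudo-residues (3-5 dummy heavy atoms each) on a jittered sphere
#' shell, one or two contiguous geodesic caps planted as epitopes with a
#' residue-type composition enriched for characteristic polar patterns, and
#' a dummy antibody chain placed within 4 Angstrom of every epitope residue
#' and beyond 4 Angstrom of every non-epitope residue, so the distance
#' labelling rule recovers the planted truth exactly.
#'
#' @param n_residues Number of antigen pseudo-residues.
#' @param epitope_fraction Fraction of residues planted as epitope (default
#'   0.12, mirroring the roughly 15:120 epitope:surface imbalance of real
#'   antigen surfaces).
#' @param n_patches 1 or 2 planted epitope patches.
#' @param enriched_types Residue types over-represented in epitopes
#'   (default Q, D, Y, L).
#' @param enrichment_odds Multiplicative odds of an enriched type inside an
#'   epitope relative to the uniform background.
#' @param pattern_strength Probability that an epitope residue copies the
#'   type of a spatially adjacent epitope residue instead of drawing a fresh
#'   type, planting homogeneous residue pairs (QQ, NN, ...) and XXY
#'   triangles inside epitopes while the background stays independent.
#' @param radius Sphere radius in Angstrom; `NULL` (default) scales with
#'   the residue count to keep a residue spacing of about 5.3 Angstrom, a
#'   realistic surface packing (17 Angstrom at 130 residues).
#' @param noise_sd Radial jitter of residue centers (Angstrom).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_residues = 130, epitope_fraction = 0.12,
                           n_patches = 1,
                           enriched_types = c("Q", "D", "Y", "L"),
                           enrichment_odds = 8, pattern_strength = 0.6,
                           radius = NULL, noise_sd = 0.3, seed = 1) {
  if (is.null(radius)) radius <- 17 * sqrt(n_residues / 130)
  stopifnot(epitope_fraction > 0, epitope_fraction < 1,
            n_patches %in% c(1L, 2L), enrichment_odds > 0, radius > 0,
            pattern_strength >= 0, pattern_strength <= 1)
  structure(list(n_residues = n_residues, epitope_fraction = epitope_fraction,
                 n_patches = as.integer(n_patches),
                 enriched_types = enriched_types,
                 enrichment_odds = enrichment_odds,
                 pattern_strength = pattern_strength, radius = radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic Fibonacci-lattice directions on the unit sphere
.fib_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate one synthetic antibody-antigen complex
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pdb_text` (standard PDB text), `truth` (list of
#'   epitope residue-key vectors, one per patch), `antigen_chains`,
#'   `antibody_chains`, and the `spec`.
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  dirs <- .fib_sphere(n)
  centers <- dirs * (spec$radius + rnorm(n, 0, spec$noise_sd))

  # each patch is a full-size epitope (multi-epitope antigens carry several
  # complete epitopes, not fragments of one)
  per_patch <- rep(max(3L, round(spec$epitope_fraction * n)), spec$n_patches)
  axes <- if (spec$n_patches == 1) rbind(c(0, 0, 1)) else
    rbind(c(0, 0, 1), c(0, 0, -1))
  patches <- vector("list", spec$n_patches)
  taken <- integer()
  for (p in seq_len(spec$n_patches)) {
    ang <- dirs %*% axes[p, ]
    ord <- order(-ang)
    ord <- setdiff(ord, taken)
    patches[[p]] <- sort(ord[seq_len(per_patch[p])])
    taken <- c(taken, patches[[p]])
  }
  if (length(unique(taken)) < length(taken)) {
    stop("epitope patches overlap; reduce epitope_fraction or patch count")
  }
  is_epi <- seq_len(n) %in% taken

  aa <- amino_acids()
  w_bg <- rep(1, 20)
  w_epi <- ifelse(aa %in% spec$enriched_types, spec$enrichment_odds, 1)
  types <- character(n)
  types[!is_epi] <- sample(aa, sum(!is_epi), replace = TRUE, prob = w_bg)
  # epitope types: enriched marginal composition with spatial correlation --
  # a residue copies an adjacent enriched-type patch residue with
  # probability pattern_strength, planting homogeneous pairs and XXY
  # triangles; only enriched types propagate, so the patch keeps its
  # declared marginal enrichment
  for (p in patches) {
    assigned <- integer()
    for (i in p) {
      nb <- assigned[sqrt(rowSums(sweep(centers[assigned, , drop = FALSE],
                                        2, centers[i, ])^2)) < 7]
      nb <- nb[types[nb] %in% spec$enriched_types]
      if (length(nb) > 0 && runif(1) < spec$pattern_strength) {
        types[i] <- types[nb[sample.int(length(nb), 1)]]
      } else {
        types[i] <- sample(aa, 1, prob = w_epi)
      }
      assigned <- c(assigned, i)
    }
  }

  # 3-5 dummy heavy atoms per residue around its center
  atom_names <- c("N", "CA", "C", "O", "CB")
  atom_elems <- c("N", "C", "C", "O", "C")
  offsets <- rbind(c(0.7, 0, 0), c(-0.35, 0.6, 0), c(-0.35, -0.6, 0),
                   c(0, 0, 0.7), c(0, 0, -0.7))
  rows <- list()
  for (i in seq_len(n)) {
    m <- sample(3:5, 1)
    off <- offsets[seq_len(m), , drop = FALSE] +
      matrix(rnorm(3 * m, 0, 0.15), ncol = 3)
    rows[[i]] <- tibble::tibble(
      chain = "A", resno = i, aa = types[i],
      atom_name = atom_names[seq_len(m)], element = atom_elems[seq_len(m)],
      x = centers[i, 1] + off[, 1], y = centers[i, 2] + off[, 2],
      z = centers[i, 3] + off[, 3]
    )
  }
  antigen <- dplyr::bind_rows(rows)

  # dummy antibody: one atom radially above each epitope residue, within
  # 4 A of that residue and > 4 A from every non-epitope residue
  ab_rows <- list()
  for (j in seq_along(taken)) {
    i <- taken[j]
    u <- dirs[i, ]
    own <- as.matrix(antigen[antigen$resno == i, c("x", "y", "z")])
    # anchor on the residue's most radially distal atom: the contact sits
    # 3.2 A above it, inside the 4 A rule for this residue and well clear
    # of every other residue on the shell
    anchor <- own[which.max(own %*% u), ]
    p <- anchor + 3.2 * u
    ab_rows[[j]] <- tibble::tibble(
      chain = "B", resno = j, aa = "G", atom_name = "CA", element = "C",
      x = p[1], y = p[2], z = p[3])
  }
  # pad the dummy antibody to a realistic chain length (>= 30 modelled
  # residues) with far-field framework atoms at least 10 A above the shell,
  # well outside the labelling cutoff
  n_pad <- max(0L, 30L - length(taken))
  for (j in seq_len(n_pad)) {
    i <- taken[(j - 1L) %% length(taken) + 1L]
    u <- dirs[i, ]
    lift <- 10 + 2 * ((j - 1L) %/% length(taken))
    p <- centers[i, ] + lift * u
    ab_rows[[length(ab_rows) + 1]] <- tibble::tibble(
      chain = "B", resno = length(taken) + j, aa = "G", atom_name = "CA",
      element = "C", x = p[1], y = p[2], z = p[3])
  }
  antibody <- dplyr::bind_rows(ab_rows)

  # safety: the 4 A rule must label exactly the planted residues
  non_epi_atoms <- antigen[!(antigen$resno %in% taken), c("x", "y", "z")]
  abm <- as.matrix(antibody[, c("x", "y", "z")])
  nem <- as.matrix(non_epi_atoms)
  d2 <- outer(rowSums(nem^2), rep(1, nrow(abm))) +
    outer(rep(1, nrow(nem)), rowSums(abm^2)) - 2 * nem %*% t(abm)
  if (min(d2) <= 16) {
    stop("antibody placement infeasible: a non-epitope residue falls ",
         "within the labelling cutoff")
  }

  all_atoms <- dplyr::bind_rows(antigen, antibody)
  pdb_text <- .write_pdb_text(all_atoms)
  truth <- lapply(patches, function(idx) .residue_key("A", idx, ""))
  list(pdb_text = pdb_text, truth = truth,
       antigen_chains = "A", antibody_chains = "B", spec = spec)
}

# minimal fixed-column ATOM record writer (PDB v3.3 layout)
.write_pdb_text <- function(atoms) {
  res3 <- .aa1to3[atoms$aa]
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom_name) < 4, paste0(" ", atoms$atom_name),
           atoms$atom_name),
    " ", res3, atoms$chain, atoms$resno, " ",
    atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a planted-partition weighted graph
#'
#' A surface-graph-shaped test harness for the clustering stage: complete
#' blocks of `block_size` nodes with edge weight `intra_weight`, sparse
#' cross-block edges with weight `inter_weight`.
#'
#' @param n_blocks Number of planted blocks.
#' @param block_size Nodes per block.
#' @param intra_weight Within-block edge weight (> `inter_weight`).
#' @param inter_weight Cross-block edge weight.
#' @param p_inter Probability of each cross-block edge.
#' @param seed Seed.
#' @return A `surface_graph` with attribute `"blocks"` (list of planted
#'   memberships).
#' @export
generate_weighted_graph <- function(n_blocks = 2, block_size = 6,
                                    intra_weight = 1.0, inter_weight = 0.01,
                                    p_inter = 0.2, seed = 1) {
  stopifnot(intra_weight > inter_weight, inter_weight > 0)
  set.seed(seed)
  n <- n_blocks * block_size
  keys <- sprintf("G:%03d:_", seq_len(n))
  block <- rep(seq_len(n_blocks), each = block_size)
  nodes <- tibble::tibble(
    res_key = keys, aa = sample(amino_acids(), n, replace = TRUE),
    x = rnorm(n), y = rnorm(n), z = rnorm(n), label = "unknown"
  )
  pairs <- t(combn(n, 2))
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  keep_inter <- !same & runif(nrow(pairs)) < p_inter
  sel <- same | keep_inter
  a <- keys[pairs[sel, 1]]
  b <- keys[pairs[sel, 2]]
  from <- pmin(a, b)
  to <- pmax(a, b)
  edges <- tibble::tibble(
    from = from, to = to,
    type = .pair_type(nodes$aa[match(from, keys)], nodes$aa[match(to, keys)]),
    weight = ifelse(same[sel], intra_weight, inter_weight)
  ) %>% dplyr::arrange(.data$from, .data$to)
  g <- structure(list(nodes = nodes, edges = edges), class = "surface_graph")
  attr(g, "blocks") <- split(keys, block)
  g
}

#' Simulate a set of synthetic complexes
#'
#' @param n Number of complexes.
#' @param seed Base seed; complex `i` uses `seed * 1000 + i`.
#' @param n_patches Patches per complex (recycled).
#' @param ... Further arguments to [synthetic_spec()].
#' @return List of [generate_complex()] outputs.
#' @export
simulate_complexes <- function(n, seed = 1, n_patches = 1, ...) {
  n_patches <- rep_len(n_patches, n)
  lapply(seq_len(n), function(i) {
    generate_complex(synthetic_spec(n_patches = n_patches[i],
                                    seed = seed * 1000 + i, ...))
  })
}
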