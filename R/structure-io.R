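# Reading antibody-antigen structures, solvent accessibility, 4 A epitope
# labelling and data-set curation.

#' Parse a PDB structure into a complex record
#'
#' Reads the ATOM records of a PDB file, keeps heavy atoms of standard
#' residues, resolves alternate locations (highest occupancy wins, ties by
#' altloc letter), and tags every atom with its role: `"antigen"` or
#' `"antibody"`. Only the first model of a multi-model file is used.
#'
#' @param pdb_text Character scalar (or vector of lines) with PDB-format text.
#' @param antigen_chains Character vector of antigen chain identifiers.
#' @param antibody_chains Character vector of antibody chain identifiers
#'   (may be empty for an unbound antigen).
#' @return An object of class `complex_record`: a list with `atoms` (a tibble
#'   with one row per heavy atom: `serial`, `atom_name`, `element`, `chain`,
#'   `resno`, `ins`, `aa`, `x`, `y`, `z`, `role`, `res_key`), the chain role
#'   vectors and `resolution` (Angstrom, `NA` if the header has none).
#' @examples
#' spec <- synthetic_spec(n_residues = 40, seed = 1)
#' cx <- generate_complex(spec)
#' rec <- parse_structure(cx$pdb_text, antigen_chains = "A",
#'                        antibody_chains = "B")
#' nrow(rec$atoms)
#' @export
parse_structure <- function(pdb_text, antigen_chains, antibody_chains = character()) {
  stopifnot(is.character(pdb_text), length(antigen_chains) >= 1)
  if (length(pdb_text) == 1) pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  if (!any(startsWith(pdb_text, "ATOM"))) {
    stop("no ATOM records found in PDB text")
  }
  overlap <- intersect(antigen_chains, antibody_chains)
  if (length(overlap) > 0) {
    stop("chains assigned to both roles: ", paste(overlap, collapse = ", "))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)

  at <- at[at$type == "ATOM", , drop = FALSE]
  at$elesy <- toupper(trimws(at$elesy))
  no_el <- is.na(at$elesy) | at$elesy == ""
  if (any(no_el)) {
    # fall back to the first letter of the atom name that is not a digit
    guess <- gsub("[0-9' ]", "", at$elety[no_el])
    at$elesy[no_el] <- substr(guess, 1, 1)
  }
  at <- at[at$elesy != "H" & at$elesy != "D", , drop = FALSE]

  known <- at$resid %in% names(.aa3to1)
  if (any(!known)) {
    warning("dropping ", sum(!known), " atoms of non-standard residues: ",
            paste(unique(at$resid[!known]), collapse = ", "))
    at <- at[known, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no standard-residue heavy atoms in PDB text")

  roles <- c(setNames(rep("antigen", length(antigen_chains)), antigen_chains),
             setNames(rep("antibody", length(antibody_chains)), antibody_chains))
  missing_chain <- setdiff(names(roles), unique(at$chain))
  if (length(missing_chain) > 0) {
    stop("requested chain(s) absent from structure: ",
         paste(missing_chain, collapse = ", "))
  }
  at <- at[at$chain %in% names(roles), , drop = FALSE]

  # alternate locations: keep highest occupancy, ties by altloc letter order
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    atom_name = at$elety,
    element = at$elesy,
    chain = at$chain,
    resno = as.integer(at$resno),
    ins = at$insert,
    aa = unname(.aa3to1[at$resid]),
    x = at$x, y = at$y, z = at$z,
    role = unname(roles[at$chain])
  )
  atoms$res_key <- .residue_key(atoms$chain, atoms$resno, atoms$ins)
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite atom coordinates")
  }

  structure(
    list(atoms = atoms,
         antigen_chains = antigen_chains,
         antibody_chains = antibody_chains,
         resolution = .parse_resolution(pdb_text)),
    class = "complex_record"
  )
}

.parse_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl) == 0) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

#' @export
print.complex_record <- function(x, ...) {
  cat("<complex_record> ", nrow(x$atoms), " heavy atoms; antigen chains: ",
      paste(x$antigen_chains, collapse = ","),
      if (length(x$antibody_chains) > 0)
        paste0("; antibody chains: ", paste(x$antibody_chains, collapse = ",")),
      if (!is.na(x$resolution)) sprintf("; resolution %.2f A", x$resolution),
      "\n", sep = "")
  invisible(x)
}

#' Per-atom accessible surface area (Shrake-Rupley)
#'
#' Computes each atom's solvent-accessible surface area by rolling a probe
#' sphere over van der Waals spheres, using a deterministic golden-spiral
#' point set. Radii follow a NACCESS-like element table (C 1.87, N 1.65,
#' O 1.40, S 1.85 Angstrom).
#'
#' @param atoms Tibble of atoms as in a `complex_record` (needs `serial`,
#'   `element`, `x`, `y`, `z`), or a `complex_record` itself.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Number of test points per atom sphere.
#' @return Tibble with columns `serial` and `asa` (Angstrom^2); the probe
#'   radius is stored in attribute `"probe_radius"`.
#' @examples
#' one_c <- tibble::tibble(serial = 1L, element = "C", x = 0, y = 0, z = 0)
#' compute_asa(one_c)$asa  # full sphere: 4*pi*(1.87+1.4)^2
#' @export
compute_asa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  if (inherits(atoms, "complex_record")) atoms <- atoms$atoms
  if (nrow(atoms) == 0) stop("compute_asa needs at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- .vdw_radius(atoms$element)
  asa <- .shrake_rupley_cpp(coords, radii, probe_radius, as.integer(n_points))
  out <- tibble::tibble(serial = atoms$serial, asa = asa)
  attr(out, "probe_radius") <- probe_radius
  out
}

#' Select surface atoms by an ASA threshold
#'
#' @param asa Tibble from [compute_asa()].
#' @param threshold Inclusive lower bound in Angstrom^2; atoms with
#'   ASA >= threshold are surface atoms.
#' @return Integer vector of atom serials.
#' @export
surface_atoms <- function(asa, threshold = 10) {
  asa$serial[asa$asa >= threshold]
}

#' Label epitope residues by atom-distance to the antibody
#'
#' An antigen residue is an epitope residue when any of its heavy atoms lies
#' within `cutoff` (inclusive) of any antibody heavy atom.
#'
#' @param complex A `complex_record` with a non-empty antibody role.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return Character vector of epitope residue keys (`chain:resno:ins`).
#' @export
label_epitope_residues <- function(complex, cutoff = 4.0) {
  at <- complex$atoms
  ag <- at[at$role == "antigen", , drop = FALSE]
  ab <- at[at$role == "antibody", , drop = FALSE]
  if (nrow(ab) == 0) stop("cannot label epitopes: antibody role is empty")
  if (nrow(ag) == 0) stop("cannot label epitopes: antigen role is empty")
  agm <- as.matrix(ag[, c("x", "y", "z")])
  abm <- as.matrix(ab[, c("x", "y", "z")])
  # squared cross-distances antigen x antibody
  d2 <- outer(rowSums(agm^2), rep(1, nrow(abm))) +
    outer(rep(1, nrow(agm)), rowSums(abm^2)) - 2 * agm %*% t(abm)
  hit <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
  sort(unique(ag$res_key[hit]))
}

# per-chain one-letter sequence of the modelled residues, in residue order
.chain_sequences <- function(complex, role = "antigen") {
  at <- complex$atoms[complex$atoms$role == role, , drop = FALSE]
  res <- unique(at[, c("chain", "resno", "ins", "aa")])
  res <- res[order(res$chain, res$resno, res$ins), , drop = FALSE]
  split_aa <- split(res$aa, res$chain)
  vapply(split_aa, paste, collapse = "", FUN.VALUE = character(1))
}

# global-alignment identity = matches / min(length); match +1, mismatch 0,
# linear gap -1
.pairwise_identity <- function(s1, s2) {
  aas <- c(amino_acids(), "X")
  sub <- diag(1, length(aas))
  dimnames(sub) <- list(aas, aas)
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(s1), nchar(s2))
}

#' Curate a set of antibody-antigen complexes
#'
#' Applies the training-set filters: every modelled chain at least
#' `min_chain_len` residues long, X-ray resolution strictly below
#' `max_resolution`, and removal of duplicate antigen chains whose global
#' pairwise sequence identity with an already retained antigen chain exceeds
#' `identity_threshold` (identity = matched positions / shorter length;
#' first-seen chain retained). A complex whose antigen chains are all removed
#' as duplicates is dropped.
#'
#' @param complexes List of `complex_record` objects.
#' @param min_chain_len Minimum modelled-residue count per chain.
#' @param max_resolution Exclusive resolution bound (Angstrom); complexes with
#'   unknown resolution are kept.
#' @param identity_threshold Identity above which an antigen chain is a
#'   duplicate.
#' @return Filtered list of `complex_record` objects.
#' @export
curate <- function(complexes, min_chain_len = 30, max_resolution = 3.0,
                   identity_threshold = 0.80) {
  keep <- list()
  retained_seqs <- character()
  for (cx in complexes) {
    at <- cx$atoms
    res <- unique(at[, c("chain", "resno", "ins")])
    len_by_chain <- table(res$chain)
    if (any(len_by_chain < min_chain_len)) next
    if (!is.na(cx$resolution) && cx$resolution >= max_resolution) next

    seqs <- .chain_sequences(cx, "antigen")
    dup <- vapply(seqs, function(s) {
      length(retained_seqs) > 0 &&
        any(vapply(retained_seqs, .pairwise_identity, numeric(1), s2 = s) >
              identity_threshold)
    }, logical(1))
    if (all(dup)) next
    if (any(dup)) {
      drop_chains <- names(seqs)[dup]
      cx$atoms <- cx$atoms[!(cx$atoms$chain %in% drop_chains), , drop = FALSE]
      cx$antigen_chains <- setdiff(cx$antigen_chains, drop_chains)
    }
    retained_seqs <- c(retained_seqs, seqs[!dup])
    keep[[length(keep) + 1]] <- cx
  }
  keep
}
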