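# Residue and atom-level constants shared across the package.

#' The 20 standard amino acids
#'
#' One-letter codes in lexicographic order; this ordering fixes the layout of
#' every weight table and feature space in the package.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter lookup for the standard residues
.aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))

# NACCESS-like van der Waals radii by element (Angstrom); heavy atoms only
.vdw_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)
.vdw_default <- 1.80

.vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

# canonical residue key "chain:resno:ins"
.residue_key <- function(chain, resno, ins) {
  ins <- ifelse(is.na(ins) | ins == "", "_", ins)
  paste(chain, resno, ins, sep = ":")
}

# unordered residue-pair type, e.g. "AQ"
.pair_type <- function(a, b) {
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

# unordered residue-triple type, e.g. "AQQ"
.triple_type <- function(a, b, c) {
  m <- rbind(a, b, c)
  apply(m, 2, function(x) paste(sort(x), collapse = ""))
}
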