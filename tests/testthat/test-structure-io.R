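# PDB parsing, accessibility, epitope labelling and curation.

test_that("a generated complex round-trips through the parser", {
  cx <- generate_complex(synthetic_spec(n_residues = 40, seed = 5))
  rec <- parse_structure(cx$pdb_text, "A", "B")
  expect_s3_class(rec, "complex_record")
  expect_setequal(unique(rec$atoms$chain), c("A", "B"))
  expect_true(all(rec$atoms$aa %in% amino_acids()))
  expect_equal(sort(unique(rec$atoms$role)), c("antibody", "antigen"))
  # residues present for every antigen position
  ag <- rec$atoms[rec$atoms$role == "antigen", ]
  expect_equal(sort(unique(ag$resno)), 1:40)
})

pdb_line <- function(serial, name, alt, res3, chain, resno, x, y, z,
                     occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, res3, chain, resno, " ",
          x, y, z, occ, 0, substr(name, 1, 1))
}

test_that("alternate locations collapse to the highest-occupancy atom", {
  lines <- c(
    pdb_line(1, "CA", "A", "ALA", "A", 1, 11, 11, 11, occ = 0.40),
    pdb_line(2, "CA", "B", "ALA", "A", 1, 12, 11, 11, occ = 0.60),
    pdb_line(3, "CA", " ", "GLY", "A", 2, 15, 11, 11),
    "END")
  rec <- parse_structure(paste(lines, collapse = "\n"), "A")
  ala <- rec$atoms[rec$atoms$resno == 1, ]
  expect_equal(nrow(ala), 1)
  expect_equal(ala$x, 12.0)  # altloc B has the higher occupancy
})

test_that("requesting an absent chain is an explicit error", {
  cx <- generate_complex(synthetic_spec(n_residues = 40, seed = 5))
  expect_error(parse_structure(cx$pdb_text, "Z", "B"), "Z")
  expect_error(parse_structure("REMARK nothing\nEND", "A"), "ATOM")
})

test_that("an isolated atom exposes its full solvent-expanded sphere", {
  one <- tibble::tibble(serial = 1L, element = "C", x = 0, y = 0, z = 0)
  asa <- compute_asa(one, probe_radius = 1.4)
  expect_equal(asa$asa, 4 * pi * (1.87 + 1.4)^2, tolerance = 1e-6)
  # occlusion: two coincident-ish atoms each lose area
  two <- tibble::tibble(serial = 1:2, element = "C",
                        x = c(0, 0.5), y = 0, z = 0)
  asa2 <- compute_asa(two)
  expect_true(all(asa2$asa < 4 * pi * 3.27^2))
})

test_that("a caged atom is effectively buried", {
  # 26-point shell of carbons around a central carbon
  g <- expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5),
                   z = c(-2.5, 0, 2.5))
  atoms <- tibble::tibble(serial = seq_len(nrow(g)), element = "C",
                          x = g$x, y = g$y, z = g$z)
  asa <- compute_asa(atoms)
  centre <- which(g$x == 0 & g$y == 0 & g$z == 0)
  expect_lt(asa$asa[centre], 1)
})

test_that("ASA is invariant under rigid motion", {
  cx <- generate_complex(synthetic_spec(n_residues = 30, seed = 2))
  rec <- parse_structure(cx$pdb_text, "A", "B")
  at <- rec$atoms[1:50, ]
  asa1 <- compute_asa(at)$asa
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% rot
  at2 <- at
  at2$x <- xyz[, 1] + 5; at2$y <- xyz[, 2] - 3; at2$z <- xyz[, 3] + 11
  asa2 <- compute_asa(at2)$asa
  # the fixed golden-spiral point set leaves ~1% orientational
  # discretization error; totals agree much more closely
  expect_equal(asa1, asa2, tolerance = 0.02)
  expect_equal(sum(asa1), sum(asa2), tolerance = 0.005)
})

test_that("the surface-atom threshold is inclusive and monotone", {
  asa <- tibble::tibble(serial = 1:3, asa = c(10.0, 9.99, 55))
  expect_setequal(surface_atoms(asa, 10), c(1L, 3L))
  expect_length(surface_atoms(tibble::tibble(serial = integer(),
                                             asa = numeric())), 0)
  # monotone: higher threshold selects a subset
  cx <- generate_complex(synthetic_spec(n_residues = 30, seed = 9))
  rec <- parse_structure(cx$pdb_text, "A", "B")
  full <- compute_asa(rec)
  s10 <- surface_atoms(full, 10)
  s20 <- surface_atoms(full, 20)
  expect_true(all(s20 %in% s10))
  expect_setequal(surface_atoms(full, 0), full$serial[full$asa >= 0])
})

test_that("the 4 A rule is inclusive at the boundary", {
  mk <- function(d) {
    lines <- c(pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", " ", "GLY", "B", 1, d, 0, 0),
               "END")
    parse_structure(paste(lines, collapse = "\n"), "A", "B")
  }
  expect_equal(label_epitope_residues(mk(3.99)), "A:1:_")
  expect_length(label_epitope_residues(mk(4.01)), 0)
  expect_equal(label_epitope_residues(mk(0)), "A:1:_")
  rec <- mk(3.99); rec$atoms <- rec$atoms[rec$atoms$role == "antigen", ]
  expect_error(label_epitope_residues(rec), "antibody")
})

test_that("labelling a synthetic complex recovers the planted truth", {
  for (seed in c(1, 7, 23)) {
    cx <- generate_complex(synthetic_spec(seed = seed))
    rec <- parse_structure(cx$pdb_text, "A", "B")
    expect_setequal(label_epitope_residues(rec), unlist(cx$truth))
  }
})

test_that("curation drops short chains and duplicate antigens", {
  base <- generate_complex(synthetic_spec(n_residues = 40, seed = 3))
  rec <- parse_structure(base$pdb_text, "A", "B")
  short <- rec
  short$atoms <- short$atoms[!(short$atoms$role == "antigen" &
                                 short$atoms$resno > 25), ]
  expect_length(curate(list(short)), 0)           # antigen chain length 25 < 30
  # an identical antigen chain is a duplicate (identity 1 > 0.8)
  dup <- rec
  kept <- curate(list(rec, dup))
  expect_length(kept, 1)
  # a clearly different antigen survives
  other <- parse_structure(generate_complex(
    synthetic_spec(n_residues = 40, seed = 99))$pdb_text, "A", "B")
  expect_length(curate(list(rec, other)), 2)
  # the resolution filter is strict at 3 A
  poor <- rec; poor$resolution <- 3.0
  good <- other; good$resolution <- 2.99
  expect_length(curate(list(poor, good)), 1)
})

test_that("resolution is read from the header when present", {
  cx <- generate_complex(synthetic_spec(n_residues = 35, seed = 4))
  txt <- paste0("REMARK   2 RESOLUTION.    2.41 ANGSTROMS.\n", cx$pdb_text)
  expect_equal(parse_structure(txt, "A", "B")$resolution, 2.41)
})

test_that("pairwise identity follows matches over the shorter length", {
  s <- paste(rep("ACDEFGHIKL", 4), collapse = "")
  expect_equal(betopr:::.pairwise_identity(s, s), 1)
  s2 <- paste0(substr(s, 1, 32), "WWWWWWWW")   # 32/40 identical
  expect_equal(betopr:::.pairwise_identity(s, s2), 0.8, tolerance = 1e-9)
})
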