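eligible_fixture <- function() {
  # 3 eligible ALA residues; residue "2A" carries an insertion code, a
  # water HETATM and a hydrogen are present, CB of residue 1 has two
  # alternate locations (A at z=1.5 with occupancy 0.6, B at z=1.7
  # with 0.4)
  paste(c(
    "HEADER    SYNTHETIC FIXTURE",
    "SEQRES   1 A    3  ALA ALA ALA",
    "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.000   0.000   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       0.000   0.000   1.500  0.60  0.00           C",
    "ATOM      6  CB BALA A   1       0.000   0.000   1.700  0.40  0.00           C",
    "ATOM      7  HB1 ALA A   1       0.000   0.500   1.500  1.00  0.00           H",
    "ATOM      8  N   ALA A   2       3.800   1.000   0.000  1.00  0.00           N",
    "ATOM      9  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM     10  CB  ALA A   2       3.800   0.000   1.500  1.00  0.00           C",
    "ATOM     11  N   ALA A   2A      7.600   1.000   0.000  1.00  0.00           N",
    "ATOM     12  CA  ALA A   2A      7.600   0.000   0.000  1.00  0.00           C",
    "ATOM     13  N   ALA A   3      11.400   1.000   0.000  1.00  0.00           N",
    "ATOM     14  CA  ALA A   3      11.400   0.000   0.000  1.00  0.00           C",
    "ATOM     15  CB  ALA A   3      11.400   0.000   1.500  1.00  0.00           C",
    "TER",
    "HETATM   16  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), collapse = "\n")
}

test_that("parser keeps only eligible residues and picks one altloc", {
  m <- parse_structure(eligible_fixture(), "A", pdb_id = "FIX1")
  expect_s3_class(m, "structure_model")
  # inserted residue and water dropped, 3 residues remain
  expect_identical(nrow(m$residues), 3L)
  expect_identical(m$residues$resno, c(1L, 2L, 3L))
  # hydrogens gone
  expect_false(any(grepl("^H", m$atoms$name)))
  # altloc: highest occupancy retained, exactly one CB for residue 1
  cb1 <- m$atoms[m$atoms$res_idx == 1 & m$atoms$name == "CB", ]
  expect_identical(nrow(cb1), 1L)
  expect_equal(cb1$z, 1.5)
  # SEQRES captured and every residue matched to a position
  expect_identical(m$seqres, c("ALA", "ALA", "ALA"))
  expect_identical(m$residues$seqres_pos, 1:3)
})

test_that("altloc occupancy tie is broken by altloc identifier", {
  txt <- sub("0.60", "0.40", eligible_fixture(), fixed = TRUE)
  m <- parse_structure(txt, "A")
  cb1 <- m$atoms[m$atoms$res_idx == 1 & m$atoms$name == "CB", ]
  expect_equal(cb1$z, 1.5)  # altloc A wins the 0.40/0.40 tie
})

test_that("parse failures are informative", {
  expect_error(parse_structure(eligible_fixture(), "Q"),
               "available chains.*A")
  bad <- sub("   0.000   0.000   0.000", "     bad     bad     bad",
             eligible_fixture(), fixed = TRUE)
  expect_error(parse_structure(bad, "A"), "malformed ATOM record at line 4")
  expect_error(align_sequences("", "MK"), "non-empty")
})

test_that("parse/write round-trips eligible content exactly", {
  m <- parse_structure(eligible_fixture(), "A", pdb_id = "FIX1")
  m2 <- parse_structure(write_structure(m), "A", pdb_id = "FIX1")
  expect_identical(m2$residues, m$residues)
  expect_identical(m2$seqres, m$seqres)
  expect_identical(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms[, c("x", "y", "z")], m$atoms[, c("x", "y", "z")],
               tolerance = 1e-9)
})

test_that("round-trip holds on randomized generated models", {
  for (seed in 1:4) {
    fx <- make_pair(fixture_spec(20, motion = "hinge", hinge_position = 9,
                                 hinge_angle = 45, gly_positions = c(2L, 11L),
                                 seed = seed))
    m <- parse_structure(fx$pdb_a, "A")
    m2 <- parse_structure(write_structure(m), "A")
    expect_identical(m2$residues, m$residues)
    expect_identical(tapply(m2$atoms$res_idx, m2$atoms$res_idx, length),
                     tapply(m$atoms$res_idx, m$atoms$res_idx, length))
    expect_equal(m2$atoms[, c("x", "y", "z")], m$atoms[, c("x", "y", "z")],
                 tolerance = 1e-9)
  }
})

test_that("writer refuses residues without atoms, keeps Gly backbone-only", {
  m <- pseudo_model(rbind(c(0, 0, 0), c(10, 0, 0)), c("GLY", "ALA"))
  out <- write_structure(m)
  gly_atoms <- grep("GLY", strsplit(out, "\n")[[1]], value = TRUE)
  gly_atoms <- gly_atoms[startsWith(gly_atoms, "ATOM")]
  expect_identical(sort(trimws(substr(gly_atoms, 13, 16))),
                   sort(c("N", "CA", "C", "O")))
  m$atoms <- m$atoms[m$atoms$res_idx != 2, ]
  expect_error(write_structure(m), "zero atoms")
})

test_that("missing SEQRES warns and derives the sequence", {
  txt <- paste(grep("^SEQRES", strsplit(eligible_fixture(), "\n")[[1]],
                    value = TRUE, invert = TRUE), collapse = "\n")
  expect_warning(m <- parse_structure(txt, "A"), "no SEQRES")
  expect_true(m$seqres_derived)
  expect_identical(m$seqres, m$residues$resname)
})

test_that("multi-model files: MODEL 1 by default, others selectable", {
  rec <- function(serial, x, model) sprintf(
    "ATOM  %5d  CA  ALA A   1    %8.3f   0.000   0.000  1.00  0.00           C",
    serial, x)
  txt <- paste(c(
    "MODEL        1", rec(1, 1.0), "ENDMDL",
    "MODEL        2", rec(1, 9.0), "ENDMDL", "END"), collapse = "\n")
  expect_warning(m1 <- parse_structure(txt, "A"), "no SEQRES")
  expect_warning(m2 <- parse_structure(txt, "A", model = 2), "no SEQRES")
  expect_equal(m1$atoms$x, 1.0)
  expect_equal(m2$atoms$x, 9.0)
  expect_error(suppressWarnings(parse_structure(txt, "A", model = 3)),
               "2 model")
})
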