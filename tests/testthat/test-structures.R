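test_that("PDB parsing preserves residue and atom counts and the sequence", {
  st <- parse_tiny_pdb()
  expect_s3_class(st, "spatwin_structure")
  expect_equal(nrow(st$residues), 3L)
  expect_equal(nrow(st$atoms), 15L)
  expect_false(any(st$residues$is_hetero))
  ps <- polymer_sequence(st)
  expect_equal(ps$sequence, "AGS")
  expect_equal(ps$index$key, c("A:1", "A:2", "A:3"))
})

test_that("mmCIF parse equals the PDB parse of the same model", {
  st_pdb <- parse_tiny_pdb()
  st_cif <- parse_structure(write_tmp_lines(tiny_cif_lines(), ".cif"))
  expect_equal(st_cif$source_format, "mmcif")
  expect_equal(st_cif$residues$key, st_pdb$residues$key)
  expect_equal(st_cif$residues$resname, st_pdb$residues$resname)
  expect_equal(st_cif$atoms$name, st_pdb$atoms$name)
  expect_equal(st_cif$atoms$key, st_pdb$atoms$key)
  expect_equal(st_cif$atoms$x, st_pdb$atoms$x, tolerance = 1e-3)
  expect_equal(st_cif$atoms$y, st_pdb$atoms$y, tolerance = 1e-3)
  expect_equal(st_cif$atoms$z, st_pdb$atoms$z, tolerance = 1e-3)
})

test_that("format auto-detection reads extensionless files by content", {
  st <- parse_structure(write_tmp_lines(tiny_cif_lines(), ""))
  expect_equal(st$source_format, "mmcif")
  st2 <- parse_structure(write_tmp_lines(tiny_pdb_lines(), ""))
  expect_equal(st2$source_format, "pdb")
})

test_that("altloc resolution keeps the highest occupancy, first on ties", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N  ",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.60 11.00           C  ",
    "ATOM      3  CA BALA A   1      99.000  99.000  99.000  0.40 12.00           C  ",
    "ATOM      4  CB AALA A   1      55.000  55.000  55.000  0.50 13.00           C  ",
    "ATOM      5  CB BALA A   1      56.000  56.000  56.000  0.50 14.00           C  ",
    "END")
  st <- parse_structure(write_tmp_lines(lines, ".pdb"))
  ca <- st$atoms[st$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 11.639)        # occupancy 0.6 conformer A wins
  cb <- st$atoms[st$atoms$name == "CB", ]
  expect_equal(cb$x, 55)            # tie -> first encountered
})

test_that("modified residues map through the common table, hetero is flagged", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C  ",
    "HETATM    2  CA  MSE A   2       3.800   0.000   0.000  1.00 11.00           C  ",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00 12.00           C  ",
    "HETATM    4  O   HOH A 101      20.000  20.000  20.000  1.00 20.00           O  ",
    "END")
  st <- parse_structure(write_tmp_lines(lines, ".pdb"))
  expect_equal(polymer_sequence(st)$sequence, "AMS")   # MSE -> M, water excluded
  expect_true(st$residues$is_hetero[st$residues$resname == "HOH"])
})

test_that("chain selection validates names and 'all' concatenates in order", {
  lines <- c(
    "ATOM      1  CA  ALA B   1       0.000   0.000   0.000  1.00 10.00           C  ",
    "ATOM      2  CA  GLY B   2       3.800   0.000   0.000  1.00 11.00           C  ",
    "ATOM      3  CA  ALA A   1      20.000   0.000   0.000  1.00 10.00           C  ",
    "ATOM      4  CA  GLY A   2      23.800   0.000   0.000  1.00 11.00           C  ",
    "END")
  st <- parse_structure(write_tmp_lines(lines, ".pdb"))
  expect_equal(polymer_sequence(st)$sequence, "AGAG")  # chain A then chain B
  expect_equal(polymer_sequence(st)$index$chain, c("A", "A", "B", "B"))
  expect_equal(polymer_sequence(st, "B")$sequence, "AG")
  expect_error(polymer_sequence(st, "Z"), "available chains.*A")
})

test_that("unreadable, empty, and malformed inputs raise distinct errors", {
  expect_error(parse_structure(tempfile()), "cannot read")
  wat <- "HETATM    1  O   HOH A 101      20.000  20.000  20.000  1.00 20.00           O  "
  expect_error(parse_structure(write_tmp_lines(c(wat, "END"), ".pdb")),
               "no polymer residues")
  bad <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C  ",
    "ATOM      2  CA  GLY A   2       3.8xx   0.000   0.000  1.00 11.00           C  ",
    "END")
  expect_error(parse_structure(write_tmp_lines(bad, ".pdb")),
               "malformed coordinate record at line 2")
})

test_that("only the first model of a multi-model file is used", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C  ",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00 10.00           C  ",
    "ENDMDL",
    "END")
  st <- parse_structure(write_tmp_lines(lines, ".pdb"))
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 0)
})

test_that("B-factor writing sets scored residues and missing_value elsewhere", {
  st <- parse_tiny_pdb()
  out <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(st, c("A:1" = 1.5), out, missing_value = 0)
  lines <- readLines(out)
  atom <- lines[startsWith(lines, "ATOM")]
  expect_equal(substr(atom[1:5], 61, 66), rep("  1.50", 5))
  expect_equal(substr(atom[6:15], 61, 66), rep("  0.00", 10))
  # all-null scores -> every B-factor is missing_value
  write_bfactor_pdb(st, c("A:1" = NA_real_), out, missing_value = -1)
  atom <- readLines(out)[startsWith(readLines(out), "ATOM")]
  expect_equal(unique(substr(atom, 61, 66)), " -1.00")
})

test_that("B-factor writing alters nothing but columns 61-66", {
  st <- parse_tiny_pdb()
  out <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(st, c("A:1" = 7.25, "A:2" = NA_real_, "A:3" = -2.5), out)
  orig <- pdb_lines(st)
  new <- readLines(out)
  expect_equal(length(new), length(orig))
  strip_b <- function(l) paste0(substr(l, 1, 60), substring(l, 67))
  expect_identical(strip_b(new), strip_b(orig))
})

test_that("writing back each residue's own B-factor reproduces the file", {
  st <- parse_tiny_pdb()
  first_b <- tapply(st$atoms$bfactor, st$atoms$key, `[`, 1L)
  scores <- stats::setNames(as.numeric(first_b), names(first_b))
  out <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(st, scores, out)
  new <- readLines(out)
  orig <- pdb_lines(st)
  atom_i <- which(startsWith(orig, "ATOM"))
  firsts <- atom_i[c(1, 6, 11)]     # first atom of each residue
  expect_identical(substr(new[firsts], 61, 66), substr(orig[firsts], 61, 66))
})

test_that("unrepresentable scores and unknown residues are rejected", {
  st <- parse_tiny_pdb()
  out <- tempfile(fileext = ".pdb")
  expect_error(write_bfactor_pdb(st, c("A:1" = 1000), out), "rescale")
  expect_error(write_bfactor_pdb(st, c("A:1" = -100), out), "rescale")
  expect_error(write_bfactor_pdb(st, c("Z:9" = 1), out), "absent from the structure")
})
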