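# Small literal structure fixtures, written by hand so parser tests do not
# depend on the package's own serializer.

# 3 residues (ALA, GLY, SER) x 5 atoms on a rough helix, plus nothing else
tiny_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1       1.100   0.800  -0.500  1.00 10.00           N  ",
  "ATOM      2  CA  ALA A   1       2.300   0.000   0.000  1.00 11.00           C  ",
  "ATOM      3  C   ALA A   1       3.550   0.600   0.400  1.00 12.00           C  ",
  "ATOM      4  O   ALA A   1       4.400   1.400   0.200  1.00 13.00           O  ",
  "ATOM      5  CB  ALA A   1       2.600  -1.400   0.900  1.00 14.00           C  ",
  "ATOM      6  N   GLY A   2       0.301   3.066   1.000  1.00 15.00           N  ",
  "ATOM      7  CA  GLY A   2      -0.399   2.266   1.500  1.00 16.00           C  ",
  "ATOM      8  C   GLY A   2       0.851   2.866   1.900  1.00 17.00           C  ",
  "ATOM      9  O   GLY A   2       1.701   3.666   1.700  1.00 18.00           O  ",
  "ATOM     10  CB  GLY A   2      -0.099   0.866   2.400  1.00 19.00           C  ",
  "ATOM     11  N   SER A   3      -3.165   0.411   2.500  1.00 20.00           N  ",
  "ATOM     12  CA  SER A   3      -1.965  -0.389   3.000  1.00 21.00           C  ",
  "ATOM     13  C   SER A   3      -0.715   0.211   3.400  1.00 22.00           C  ",
  "ATOM     14  O   SER A   3       0.135   1.011   3.200  1.00 23.00           O  ",
  "ATOM     15  CB  SER A   3      -1.665  -1.789   3.900  1.00 24.00           C  ",
  "END"
)

# the same model as an mmCIF atom_site loop (independent hand conversion)
tiny_cif_lines <- function() {
  pdb <- tiny_pdb_lines()
  pdb <- pdb[startsWith(pdb, "ATOM")]
  hdr <- c(
    "data_tiny", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- vapply(pdb, function(l) {
    paste("ATOM",
          trimws(substr(l, 7, 11)), trimws(substr(l, 77, 78)),
          trimws(substr(l, 13, 16)), ".",
          trimws(substr(l, 18, 20)), trimws(substr(l, 22, 22)),
          trimws(substr(l, 23, 26)), "?",
          trimws(substr(l, 31, 38)), trimws(substr(l, 39, 46)),
          trimws(substr(l, 47, 54)), trimws(substr(l, 55, 60)),
          trimws(substr(l, 61, 66)),
          trimws(substr(l, 23, 26)), trimws(substr(l, 18, 20)),
          trimws(substr(l, 22, 22)), trimws(substr(l, 13, 16)), "1")
  }, "", USE.NAMES = FALSE)
  c(hdr, rows, "#")
}

write_tmp_lines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

parse_tiny_pdb <- function() {
  parse_structure(write_tmp_lines(tiny_pdb_lines(), ".pdb"))
}

# random small alignment for popgen property tests
random_alignment <- function(n, L, states = c("A", "C", "G", "T")) {
  mat <- matrix(sample(states, n * L, replace = TRUE,
                       prob = c(0.7, 0.1, 0.1, 0.1)), nrow = n)
  alignment_data(paste0("s", seq_len(n)),
                 apply(mat, 1L, paste, collapse = ""), "dna")
}
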