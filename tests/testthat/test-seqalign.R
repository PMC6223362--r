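ref3 <- reference_seq("ref", "AGS")

struct_seq <- function(seq, keys) {
  list(sequence = seq, index = data.frame(key = keys))
}

test_that("structure-to-reference alignment maps matched and absent residues", {
  # identity
  m <- align_protein_to_reference(struct_seq("AGS", c("A:1", "A:2", "A:3")), ref3)
  expect_equal(m, c("A:1" = 1L, "A:2" = 2L, "A:3" = 3L))
  # unresolved middle residue: A and S still map, nothing maps to position 2
  m <- align_protein_to_reference(struct_seq("AS", c("A:1", "A:3")), ref3)
  expect_equal(m, c("A:1" = 1L, "A:3" = 3L))
  # N-terminal purification tag on the structure: tag residues unmapped
  m <- align_protein_to_reference(
    struct_seq("HHHAGS", paste0("A:", 1:6)), ref3)
  expect_equal(m[c("A:4", "A:5", "A:6")],
               c("A:4" = 1L, "A:5" = 2L, "A:6" = 3L))
  expect_false(any(c("A:1", "A:2", "A:3") %in% names(m)))
  # mismatched aligned pairs still map: the reference drives the data
  m <- align_protein_to_reference(struct_seq("AGT", c("A:1", "A:2", "A:3")),
                                  ref3, min_identity = 0.5)
  expect_equal(unname(m["A:3"]), 3L)
})

test_that("alignments below the identity floor are rejected", {
  long_ref <- reference_seq("r", "MKVLAETWQHNDYRFGIPCS")
  expect_error(
    align_protein_to_reference(
      struct_seq("WWWWWWWWWWWWWWWWWWWW", paste0("A:", 1:20)), long_ref),
    "identity.*below")
})

test_that("translation follows the standard code with reverse-sense support", {
  expect_equal(translate_dna("ATGGCT"), "MA")
  expect_equal(translate_dna("AGCCAT", strand = "reverse"), "MA")
  expect_equal(translate_dna("ATGNCT"), "MX")
  expect_equal(translate_dna("TTATGA"), "L*")
  expect_equal(translate_dna("AATGGCT", frame = 1), "MA")
  expect_equal(translate_dna("ATGGCTA"), "MA")   # incomplete codon dropped
  expect_error(translate_dna("ATGU"), "invalid nucleotide 'U' at position 4")
  expect_error(translate_dna("AT"), "too short")
})

test_that("reverse-strand translation equals translating the reverse complement", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * sample(2:30, 1),
                      replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(translate_dna(s, strand = "reverse"), translate_dna(rc))
  }
})

test_that("codon mapping handles forward, reverse, and gapped representatives", {
  refMA <- reference_seq("r", "MA")
  fwd <- alignment_data(c("a", "b"), c("ATGGCT", "ATGGCT"), "dna")
  mc <- map_codons(refMA, fwd)
  expect_equal(mc$strand, "forward")
  expect_equal(mc$ref_to_columns, list(`1` = 1:3, `2` = 4:6))
  # reverse-sense: AGCCAT is the reverse complement of ATGGCT; column triplets
  # stay ascending and refer to the reverse-complement reading order
  rev <- alignment_data(c("a", "b"), c("AGCCAT", "AGCCAT"), "dna")
  mc <- map_codons(refMA, rev)
  expect_equal(mc$strand, "reverse")
  expect_equal(mc$ref_to_columns, list(`1` = 4:6, `2` = 1:3))
  # alignment gap inside the representative row is skipped when counting bases
  gapped <- alignment_data(c("a", "b"), c("ATG--GCT", "ATGAAGCT"), "dna")
  mc <- map_codons(refMA, gapped)
  expect_equal(mc$ref_to_columns, list(`1` = c(1L, 2L, 3L), `2` = c(6L, 7L, 8L)))
})

test_that("codon triplets are strictly increasing and non-overlapping", {
  spec <- fixture_spec(n_residues = 25, n_sequences = 6, seed = 9)
  fx <- make_alignment(spec)
  mc <- map_codons(fx$ref, fx$aln)
  cols <- mc$ref_to_columns
  for (v in cols) expect_true(all(diff(v) > 0) && length(v) == 3)
  expect_equal(anyDuplicated(unlist(cols)), 0L)
})

test_that("codon mapping fails with per-frame diagnostics on junk input", {
  refMA <- reference_seq("r", "MKVLAETWQHND")
  junk <- alignment_data("a", paste(rep("GGGGGG", 6), collapse = ""), "dna")
  expect_error(map_codons(refMA, junk), "identity floor.*forward/frame 0")
})

test_that("protein-alignment columns map one-to-one through the representative", {
  ref <- reference_seq("r", "AGS")
  aln <- alignment_data(c("a", "b"), c("A-GS", "ATGS"), "protein")
  pm <- map_protein_columns(ref, aln)
  expect_equal(pm$ref_to_columns, list(`1` = 1L, `2` = 3L, `3` = 4L))
})

test_that("map composition has partial-map semantics", {
  r2r <- c("A:1" = 1L, "A:2" = 2L, "A:3" = 3L)
  rc <- list(`1` = 1:3, `2` = 4:6, `3` = 7:9)
  m <- compose_map(r2r, rc)
  expect_equal(names(m$columns), c("A:1", "A:2", "A:3"))
  # reference position absent from the column map drops the residue
  m <- compose_map(r2r, rc[c("1", "3")])
  expect_equal(names(m$columns), c("A:1", "A:3"))
  m <- compose_map(stats::setNames(integer(0), character(0)), rc)
  expect_equal(length(m$columns), 0L)
})

test_that("gapless identical inputs compose to the identity map", {
  for (seed in c(2, 5, 8)) {
    spec <- fixture_spec(n_residues = 20, n_sequences = 4, seed = seed,
                         mutation_model = "none")
    st <- make_structure(spec)$structure
    fx <- make_alignment(spec)
    r2r <- align_protein_to_reference(polymer_sequence(st), fx$ref)
    mc <- map_codons(fx$ref, fx$aln)
    m <- compose_map(r2r, mc$ref_to_columns, mc$strand)
    expect_equal(unname(r2r), 1:20)
    expect_equal(names(m$columns), paste0("A:", 1:20))
    expect_equal(unname(m$columns), lapply(0:19, function(i) 3L * i + 1:3))
  }
})

test_that("window sub-alignments concatenate codons and apply gap policy", {
  aln <- alignment_data(c("a", "b"), c("ATGGCTAAA", "ATG-CTAAA"), "dna")
  map <- compose_map(c("A:1" = 1L, "A:2" = 2L, "A:3" = 3L),
                     list(`1` = 1:3, `2` = 4:6, `3` = 7:9))
  sub <- window_subalignment(aln, map, c("A:2", "A:1"), "pairwise")
  expect_equal(sub$length, 6L)                       # 3 columns per codon
  expect_equal(sub$rows[1], "ATGGCT")                # residue-id order
  sub <- window_subalignment(aln, map, c("A:1", "A:2"), "complete-deletion")
  expect_equal(sub$length, 5L)                       # the '-' column removed
  expect_equal(sub$rows, c("ATGCT", "ATGCT"))
  # a window with no mapped residue yields a zero-column alignment
  sub <- window_subalignment(aln, map, "B:9", "complete-deletion")
  expect_equal(sub$length, 0L)
  # N is treated like a gap under complete deletion
  alnN <- alignment_data(c("a", "b"), c("ATG", "ATN"), "dna")
  mapN <- compose_map(c("A:1" = 1L), list(`1` = 1:3))
  expect_equal(window_subalignment(alnN, mapN, "A:1")$length, 2L)
})

test_that("alignment and table readers validate their inputs", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment_fasta(f), "unequal lengths")
  writeLines(c(">a desc", "ACGT", ">b", "ACGA"), f)
  aln <- read_alignment_fasta(f)
  expect_equal(aln$names, c("a", "b"))
  expect_equal(aln$alphabet, "dna")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("position\tvalue", "1\t0.5", "3\t-1.25"), tsv)
  expect_equal(read_numeric_table(tsv), c(`1` = 0.5, `3` = -1.25))
  writeLines(c("1\t0.5", "1\t0.7"), tsv)
  expect_error(read_numeric_table(tsv), "duplicate positions")
})
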