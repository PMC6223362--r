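#' Multiple sequence alignment container
#'
#' An equal-length multiple sequence alignment carrying the population data.
#' Nucleotide rows are over `{A,C,G,T,N,-}`, protein rows over the amino-acid
#' alphabet plus `{X,-}`. Columns are addressed 1-based throughout the
#' package.
#'
#' @param names sequence labels
#' @param rows character vector of equal-length aligned sequences
#' @param alphabet `"dna"`, `"protein"`, or `"auto"` (detected from content)
#' @return an `alignment_data` object (fields `names`, `rows`, `alphabet`,
#'   `length`)
#' @export
alignment_data <- function(names, rows, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  rows <- toupper(rows)
  if (length(rows) == 0L) stop("alignment has no rows")
  L <- unique(nchar(rows))
  if (length(L) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(nchar(rows)), collapse = ", "))
  }
  if (length(names) != length(rows)) stop("names and rows differ in length")
  if (alphabet == "auto") {
    ch <- strsplit(paste(rows, collapse = ""), "")[[1L]]
    frac_nt <- mean(ch %in% c("A", "C", "G", "T", "N", "-"))
    alphabet <- if (frac_nt >= 0.95) "dna" else "protein"
  }
  if (alphabet == "dna") {
    bad <- grepl("[^ACGTN-]", rows)
    if (any(bad)) {
      stop("row '", names[which(bad)[1L]], "' contains characters outside ",
           "the nucleotide alphabet {A,C,G,T,N,-}")
    }
  }
  structure(list(names = as.character(names), rows = unname(rows),
                 alphabet = alphabet, length = L),
            class = "alignment_data")
}

#' @export
print.alignment_data <- function(x, ...) {
  cat(sprintf("<alignment_data> %d x %d (%s)\n",
              length(x$rows), x$length, x$alphabet))
  invisible(x)
}

# n x L character matrix view
aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (aln$length == 0L) {
    return(matrix(character(0), nrow = length(aln$rows), ncol = 0L))
  }
  do.call(rbind, strsplit(aln$rows, ""))
}

#' Reference protein sequence
#'
#' @param id label
#' @param residues one-letter protein string, positions 1-based
#' @return a `reference_seq` object
#' @export
reference_seq <- function(id, residues) {
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("reference sequence is empty")
  if (grepl("-", residues, fixed = TRUE)) {
    stop("reference sequence must not contain gap characters")
  }
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "reference_seq")
}

#' Read FASTA inputs
#'
#' `read_alignment_fasta()` reads a pre-aligned (equal-length) multiple
#' sequence alignment; `read_reference_fasta()` reads the first record of a
#' FASTA file as the reference protein sequence.
#'
#' @param path FASTA file path
#' @param alphabet passed to [alignment_data()]
#' @return an `alignment_data` / `reference_seq` object
#' @export
read_alignment_fasta <- function(path, alphabet = "auto") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  alignment_data(sub("\\s.*$", "", names(set)), as.character(set), alphabet)
}

#' @rdname read_alignment_fasta
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  reference_seq(sub("\\s.*$", "", names(set)[1L]),
                gsub("-", "", as.character(set)[[1L]]))
}

#' Read a per-reference-position numeric table
#'
#' Tab-separated table with columns `position` (1-based reference position)
#' and `value`; a header line is optional.
#'
#' @param path TSV path
#' @return named numeric vector (names are reference positions)
#' @export
read_numeric_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*-?[0-9]", first)
  tab <- utils::read.delim(path, header = has_header,
                           col.names = c("position", "value"))
  pos <- as.integer(tab$position)
  val <- as.numeric(tab$value)
  if (anyNA(pos) || anyNA(val)) stop("malformed numeric table: ", path)
  if (anyDuplicated(pos)) stop("duplicate positions in numeric table: ", path)
  stats::setNames(val, pos)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# global (Needleman-Wunsch) alignment with affine gaps, BLOSUM62, open 11 /
# extend 1 -- the classic protein-alignment defaults
.align_global <- function(a, b) {
  sub <- .blosum62()
  clean <- function(s) {
    ch <- strsplit(toupper(s), "")[[1L]]
    ch[!(ch %in% rownames(sub))] <- "X"
    paste(ch, collapse = "")
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = clean(a), subject = clean(b), type = "global",
    substitutionMatrix = sub, gapOpening = 11, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- p != "-" & s != "-"
  list(
    score = methods::slot(pa, "score"),
    pattern_pos = cumsum(p != "-")[both],
    subject_pos = cumsum(s != "-")[both],
    identity = if (any(both)) mean(p[both] == s[both]) else 0
  )
}

#' Align the structure sequence to the reference
#'
#' Global pairwise alignment (affine gaps, BLOSUM62, gap open 11, gap extend
#' 1) of the structure's polymer sequence against the reference. Every aligned
#' non-gap pair contributes one map entry — mismatched pairs still map, since
#' the reference drives the data while the structure drives space; positions
#' aligned to gaps are absent from the map.
#'
#' @param structure_seq a [polymer_sequence()] result (or a list with
#'   `sequence` and `index$key`)
#' @param ref a [reference_seq()]
#' @param min_identity identity floor over aligned non-gap pairs; below it the
#'   alignment is rejected as a probable input mix-up
#' @return named integer vector: residue key -> reference position
#' @export
align_protein_to_reference <- function(structure_seq, ref, min_identity = 0.3) {
  stopifnot(inherits(ref, "reference_seq"))
  seq <- structure_seq$sequence
  keys <- structure_seq$index$key
  if (!nzchar(seq)) stop("structure sequence is empty")
  al <- .align_global(seq, ref$residues)
  if (al$identity < min_identity) {
    stop(sprintf(
      "structure/reference alignment identity %.1f%% is below the %.1f%% floor; check that the reference matches the structure",
      100 * al$identity, 100 * min_identity))
  }
  stats::setNames(al$subject_pos, keys[al$pattern_pos])
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code. `strand = "reverse"` translates the reverse
#' complement (reverse-sense translation). The first `frame` bases are
#' skipped, an incomplete trailing codon is dropped, codons containing `N`
#' translate to `X`, and stop codons to `*`.
#'
#' @param dna ungapped nucleotide string over `{A,C,G,T,N}`
#' @param frame 0, 1, or 2
#' @param strand `"forward"` or `"reverse"`
#' @return protein string
#' @export
translate_dna <- function(dna, frame = 0, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  dna <- toupper(dna)
  ch <- strsplit(dna, "")[[1L]]
  bad <- which(!(ch %in% c("A", "C", "G", "T", "N")))
  if (length(bad)) {
    stop("invalid nucleotide '", ch[bad[1L]], "' at position ", bad[1L])
  }
  if (!(frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  if (strand == "reverse") {
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    ch <- strsplit(dna, "")[[1L]]
  }
  if (length(ch) - frame < 3L) {
    stop("sequence too short to translate (", length(ch), " bases, frame ",
         frame, ")")
  }
  ch <- ch[(frame + 1L):length(ch)]
  ncod <- length(ch) %/% 3L
  ch <- ch[seq_len(3L * ncod)]
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(ch, collapse = "")),
    if.fuzzy.codon = "X"
  ))
}

#' Map reference positions to codon columns of a nucleotide alignment
#'
#' Establishes the coding frame from a designated representative row: the row
#' is ungapped and translated in all six frame/strand combinations, each
#' translation is globally aligned to the reference, and the best-scoring
#' combination wins (ties resolved toward the forward strand, then the lowest
#' frame). Each mapped reference position receives the three alignment columns
#' holding that codon's bases in the representative row (gap columns are
#' skipped when counting bases). Column triplets are reported in ascending
#' column order; for the reverse strand they are read in reverse-complement
#' order, recorded in the `strand` field.
#'
#' @param ref a [reference_seq()]
#' @param aln an [alignment_data()] with `alphabet == "dna"`
#' @param representative row used to establish the coding frame (default 1)
#' @param min_identity identity floor; if no frame/strand combination reaches
#'   it, mapping fails with the best identity per combination reported
#' @return list with `ref_to_columns` (named list: reference position ->
#'   integer vector of 3 strictly increasing columns), `strand`, `frame`,
#'   `identity`
#' @export
map_codons <- function(ref, aln, representative = 1L, min_identity = 0.3) {
  stopifnot(inherits(ref, "reference_seq"), inherits(aln, "alignment_data"))
  if (aln$alphabet != "dna") stop("map_codons requires a nucleotide alignment")
  rep_row <- aln$rows[[representative]]
  rep_ch <- strsplit(rep_row, "")[[1L]]
  nongap_cols <- which(rep_ch != "-")
  ungapped <- paste(rep_ch[nongap_cols], collapse = "")
  Lu <- length(nongap_cols)
  if (Lu < 3L) stop("representative row has fewer than 3 bases")

  combos <- expand.grid(frame = 0:2, strand = c("forward", "reverse"),
                        stringsAsFactors = FALSE)
  best <- NULL
  tried <- character(0)
  for (i in seq_len(nrow(combos))) {
    fr <- combos$frame[i]; st <- combos$strand[i]
    if (Lu - fr < 3L) next
    prot <- translate_dna(ungapped, fr, st)
    al <- .align_global(prot, ref$residues)
    tried <- c(tried, sprintf("%s/frame %d: %.1f%%", st, fr, 100 * al$identity))
    if (is.null(best) || al$score > best$score) {
      best <- list(score = al$score, frame = fr, strand = st, al = al)
    }
  }
  if (is.null(best) || best$al$identity < min_identity) {
    stop("no frame/strand combination aligns the representative row to the ",
         "reference above the ", sprintf("%.0f%%", 100 * min_identity),
         " identity floor; best identities: ", paste(tried, collapse = "; "))
  }
  al <- best$al
  ref_to_columns <- list()
  for (k in seq_along(al$pattern_pos)) {
    p <- al$pattern_pos[k]        # codon index in the chosen translation
    rpos <- al$subject_pos[k]     # reference position
    base_idx <- best$frame + 3L * (p - 1L) + 1:3
    if (best$strand == "reverse") base_idx <- sort(Lu - base_idx + 1L)
    ref_to_columns[[as.character(rpos)]] <- nongap_cols[base_idx]
  }
  list(ref_to_columns = ref_to_columns, strand = best$strand,
       frame = best$frame, identity = al$identity)
}

#' Map reference positions to columns of a protein alignment
#'
#' Protein analogue of [map_codons()]: the ungapped representative row is
#' aligned to the reference and each mapped reference position receives the
#' single alignment column holding that residue in the representative row.
#'
#' @inheritParams map_codons
#' @return list with `ref_to_columns` (named list: reference position ->
#'   single column), `strand` (always `"forward"`), `identity`
#' @export
map_protein_columns <- function(ref, aln, representative = 1L,
                                min_identity = 0.3) {
  stopifnot(inherits(ref, "reference_seq"), inherits(aln, "alignment_data"))
  if (aln$alphabet != "protein") {
    stop("map_protein_columns requires a protein alignment")
  }
  rep_ch <- strsplit(aln$rows[[representative]], "")[[1L]]
  nongap_cols <- which(rep_ch != "-")
  ungapped <- paste(rep_ch[nongap_cols], collapse = "")
  al <- .align_global(ungapped, ref$residues)
  if (al$identity < min_identity) {
    stop(sprintf(
      "representative row aligns to the reference at %.1f%% identity, below the %.1f%% floor",
      100 * al$identity, 100 * min_identity))
  }
  ref_to_columns <- stats::setNames(
    lapply(seq_along(al$pattern_pos),
           function(k) nongap_cols[al$pattern_pos[k]]),
    as.character(al$subject_pos)
  )
  list(ref_to_columns = ref_to_columns, strand = "forward",
       identity = al$identity)
}

#' Compose the structure-to-reference and reference-to-column maps
#'
#' Produces the three-way correspondence structure residue <-> reference
#' position <-> alignment column(s). The composition is defined exactly on
#' residues where both partial maps are defined.
#'
#' @param residue_to_ref named integer vector from
#'   [align_protein_to_reference()]
#' @param ref_to_columns named list from [map_codons()] /
#'   [map_protein_columns()], or `NULL` for numeric-table data (reference
#'   positions then address the table directly)
#' @param strand `"forward"` or `"reverse"` (recorded for provenance)
#' @return a `residue_data_map`: list with `residue_to_ref`,
#'   `ref_to_columns`, `columns` (residue key -> alignment columns), `strand`
#' @export
compose_map <- function(residue_to_ref, ref_to_columns, strand = "forward") {
  columns <- list()
  if (!is.null(ref_to_columns)) {
    for (k in names(residue_to_ref)) {
      rp <- as.character(residue_to_ref[[k]])
      if (!is.null(ref_to_columns[[rp]])) columns[[k]] <- ref_to_columns[[rp]]
    }
  }
  structure(list(residue_to_ref = residue_to_ref,
                 ref_to_columns = ref_to_columns,
                 columns = columns, strand = strand),
            class = "residue_data_map")
}

#' Assemble the sub-alignment for one spatial window
#'
#' Concatenates, in residue-identifier order, the alignment columns of every
#' mapped residue in the window (unmapped residues contribute nothing). Under
#' `"complete-deletion"` any column containing a gap or an ambiguous state
#' (`N` for nucleotide, `X` for protein data) is removed; under `"pairwise"`
#' columns are kept and downstream statistics handle gaps pair-by-pair.
#'
#' @param aln an [alignment_data()]
#' @param map a [compose_map()] result
#' @param window character vector of residue keys
#' @param gap_policy `"complete-deletion"` or `"pairwise"`
#' @return an [alignment_data()] with the window's columns (possibly zero
#'   columns; scoring functions decide nullness)
#' @export
window_subalignment <- function(aln, map, window,
                                gap_policy = c("complete-deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "alignment_data"), inherits(map, "residue_data_map"))
  if (length(window) == 0L) stop("window is empty")
  window <- sort_residue_keys(window)
  cols <- unlist(map$columns[window], use.names = FALSE)
  mat <- aln_matrix(aln)
  sub <- mat[, cols, drop = FALSE]
  if (gap_policy == "complete-deletion" && ncol(sub) > 0L) {
    ambig <- if (aln$alphabet == "dna") c("-", "N") else c("-", "X")
    keep <- !apply(sub, 2L, function(col) any(col %in% ambig))
    sub <- sub[, keep, drop = FALSE]
  }
  rows <- if (ncol(sub) == 0L) rep("", nrow(sub))
          else apply(sub, 1L, paste, collapse = "")
  alignment_data(aln$names, rows, alphabet = aln$alphabet)
}
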