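#' Read a protein structure from PDB or mmCIF
#'
#' Parses a structure file into a uniform chain/residue/atom model. Alternate
#' locations are resolved to a single conformer per atom name (highest
#' occupancy wins; ties keep the first record encountered). Waters and hetero
#' ligands are retained but flagged, hydrogens are retained but
#' distinguishable by element, and only the first model of a multi-model
#' (e.g. NMR) file is used.
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF files are read from their
#' `atom_site` category directly. The original PDB text (or, for mmCIF input,
#' a canonical PDB serialization) is kept alongside the parsed model so that
#' [write_bfactor_pdb()] can alter the B-factor column and nothing else.
#'
#' @param path path to a structure file
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect by extension, then
#'   by content)
#' @param id optional structure label; defaults to the file name
#' @return an object of class `spatwin_structure`: a list with elements
#'   `atoms` (one row per atom after altloc resolution: `record`, `serial`,
#'   `name`, `altloc`, `resname`, `chain`, `resnum`, `icode`, `x`, `y`, `z`,
#'   `occ`, `bfactor`, `element`, `is_hetero`, `key`), `residues` (one row per
#'   residue, ordered by chain, number, insertion code, with `one_letter`
#'   codes), `lines` (the PDB serialization), and `source_format`.
#' @seealso [polymer_sequence()], [write_bfactor_pdb()]
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else {
                head <- readLines(path, n = 50L, warn = FALSE)
                if (any(grepl("^data_", head)) || any(grepl("^_atom_site\\.", head)))
                  "mmcif" else "pdb"
              }
  }
  parsed <- if (format == "pdb") .parse_pdb(path) else .parse_mmcif(path)
  .finish_structure(parsed, format, id = if (is.null(id)) basename(path) else id,
                    path = path)
}

.WATER_RESNAMES <- c("HOH", "DOD", "WAT", "H2O")

.parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # first model only: truncate the record scan at the first ENDMDL
  endmdl <- grep("^ENDMDL", lines)
  scan_to <- if (length(endmdl)) endmdl[1L] - 1L else length(lines)
  atom_idx <- grep("^(ATOM  |HETATM)", lines[seq_len(scan_to)])
  if (length(atom_idx) == 0L) {
    stop("no ATOM/HETATM records found in PDB file: ", path)
  }
  coords <- suppressWarnings(cbind(
    as.numeric(substr(lines[atom_idx], 31L, 38L)),
    as.numeric(substr(lines[atom_idx], 39L, 46L)),
    as.numeric(substr(lines[atom_idx], 47L, 54L))
  ))
  bad <- which(!stats::complete.cases(coords))
  if (length(bad)) {
    stop("malformed coordinate record at line ", atom_idx[bad[1L]], " of ",
         path, ": ", trimws(lines[atom_idx[bad[1L]]]))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("malformed PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) > length(atom_idx)) {
    at <- at[seq_along(atom_idx), , drop = FALSE]   # bio3d read extra models
  } else if (nrow(at) < length(atom_idx)) {
    atom_idx <- atom_idx[seq_len(nrow(at))]
  }
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad)) {
    stop("malformed coordinate record at line ", atom_idx[bad[1L]], " of ",
         path, ": ", lines[atom_idx[bad[1L]]])
  }
  full <- data.frame(
    record = at$type, serial = at$eleno, name = trimws(at$elety),
    altloc = at$alt, resname = trimws(at$resid), chain = at$chain,
    resnum = at$resno, icode = at$insert,
    x = at$x, y = at$y, z = at$z, occ = at$o, bfactor = at$b,
    element = at$elesy, line = atom_idx,
    stringsAsFactors = FALSE
  )
  list(full = full, lines = lines)
}

# minimal mmCIF reader: the atom_site loop is sufficient for this package
.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  loops <- which(trimmed == "loop_")
  start <- NA_integer_
  for (i in loops) {
    j <- i + 1L
    while (j <= length(lines) && !nzchar(trimmed[j])) j <- j + 1L
    if (j <= length(lines) && startsWith(trimmed[j], "_atom_site.")) {
      start <- j
      break
    }
  }
  if (is.na(start)) stop("no atom_site loop found in mmCIF file: ", path)
  tags <- character(0)
  j <- start
  while (j <= length(lines) && startsWith(trimmed[j], "_atom_site.")) {
    tags <- c(tags, sub("^_atom_site\\.", "", sub("\\s.*$", "", trimmed[j])))
    j <- j + 1L
  }
  tokens <- character(0)
  row_list <- list()
  while (j <= length(lines)) {
    tj <- trimmed[j]
    if (!nzchar(tj)) { j <- j + 1L; next }
    if (startsWith(tj, "#") || tj == "loop_" || startsWith(tj, "_") ||
        startsWith(tj, "data_")) break
    tok <- regmatches(tj, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", tj))[[1L]]
    tok <- gsub("^['\"]|['\"]$", "", tok)
    tokens <- c(tokens, tok)
    while (length(tokens) >= length(tags)) {
      row_list[[length(row_list) + 1L]] <- tokens[seq_along(tags)]
      tokens <- tokens[-seq_along(tags)]
    }
    j <- j + 1L
  }
  if (length(row_list) == 0L) stop("empty atom_site loop in mmCIF file: ", path)
  m <- do.call(rbind, row_list)
  colnames(m) <- tags
  get <- function(primary, fallback = NULL, default = "") {
    v <- if (primary %in% tags) m[, primary]
         else if (!is.null(fallback) && fallback %in% tags) m[, fallback]
         else rep(default, nrow(m))
    v[v %in% c(".", "?")] <- default
    v
  }
  model <- get("pdbx_PDB_model_num", default = "1")
  keep <- model == model[1L]
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(out))
    if (length(bad)) {
      stop("malformed ", what, " in mmCIF atom_site record ", bad[1L],
           " of ", path, ": '", v[bad[1L]], "'")
    }
    out
  }
  full <- data.frame(
    record  = ifelse(get("group_PDB", default = "ATOM")[keep] == "HETATM",
                     "HETATM", "ATOM"),
    serial  = suppressWarnings(as.integer(get("id", default = NA)[keep])),
    name    = get("auth_atom_id", "label_atom_id")[keep],
    altloc  = get("label_alt_id")[keep],
    resname = get("auth_comp_id", "label_comp_id")[keep],
    chain   = get("auth_asym_id", "label_asym_id")[keep],
    resnum  = as.integer(num(get("auth_seq_id", "label_seq_id")[keep], "residue number")),
    icode   = get("pdbx_PDB_ins_code")[keep],
    x = num(get("Cartn_x")[keep], "Cartn_x"),
    y = num(get("Cartn_y")[keep], "Cartn_y"),
    z = num(get("Cartn_z")[keep], "Cartn_z"),
    occ     = suppressWarnings(as.numeric(get("occupancy", default = "1")[keep])),
    bfactor = suppressWarnings(as.numeric(get("B_iso_or_equiv", default = "0")[keep])),
    element = get("type_symbol")[keep],
    stringsAsFactors = FALSE
  )
  if (anyNA(full$serial)) full$serial <- seq_len(nrow(full))
  # canonical PDB serialization stands in for the original text
  full$line <- seq_len(nrow(full))
  lines <- c(format_pdb_atom_lines(full), "END")
  list(full = full, lines = lines)
}

.finish_structure <- function(parsed, source_format, id, path) {
  full <- parsed$full
  full$icode[is.na(full$icode)] <- ""
  full$icode <- trimws(full$icode)
  full$altloc[is.na(full$altloc)] <- ""
  full$altloc <- trimws(full$altloc)
  full$occ[is.na(full$occ)] <- 1
  full$bfactor[is.na(full$bfactor)] <- 0
  full$element <- toupper(trimws(full$element))
  noel <- !nzchar(full$element) | is.na(full$element)
  if (any(noel)) {
    guess <- gsub("[0-9']", "", full$name[noel])
    full$element[noel] <- ifelse(substr(guess, 1L, 1L) == "H", "H",
                                 substr(guess, 1L, 1L))
  }
  full$chain[is.na(full$chain) | !nzchar(full$chain)] <- " "
  full$key <- residue_key(full$chain, full$resnum, full$icode)

  # polymer vs hetero: ATOM records, or HETATM with a (possibly modified)
  # amino-acid resname such as MSE; waters are always hetero
  polymer_atom <- (full$record == "ATOM" | full$resname %in% names(.AA_3TO1)) &
    !(full$resname %in% .WATER_RESNAMES)
  het_by_key <- !tapply(polymer_atom, full$key, any)
  full$is_hetero <- as.logical(het_by_key[full$key])

  # altloc resolution: highest occupancy, tie -> first encountered
  grp <- paste(full$key, full$name, sep = "\r")
  ord <- order(grp, -full$occ, seq_len(nrow(full)), method = "radix")
  keep_rows <- sort(seq_len(nrow(full))[ord][!duplicated(grp[ord])])
  resolved <- full[keep_rows, , drop = FALSE]
  rownames(resolved) <- NULL

  ukey <- !duplicated(resolved$key)
  residues <- data.frame(
    key = resolved$key[ukey],
    chain = resolved$chain[ukey],
    number = resolved$resnum[ukey],
    icode = resolved$icode[ukey],
    resname = resolved$resname[ukey],
    is_hetero = resolved$is_hetero[ukey],
    stringsAsFactors = FALSE
  )
  residues$one_letter <- ifelse(residues$is_hetero, "X",
                                aa_three_to_one(residues$resname))
  residues <- residues[order_residue_keys(residues$key), , drop = FALSE]
  rownames(residues) <- NULL
  if (!any(!residues$is_hetero)) {
    stop("empty structure: no polymer residues in ", path)
  }
  structure(
    list(
      id = id, source_format = source_format, path = path,
      atoms = resolved, residues = residues,
      lines = parsed$lines,
      atom_lines = full$line, atom_line_keys = full$key
    ),
    class = "spatwin_structure"
  )
}

#' @export
print.spatwin_structure <- function(x, ...) {
  pol <- sum(!x$residues$is_hetero)
  cat(sprintf(
    "<spatwin_structure> %s (%s)\n  chains: %s\n  polymer residues: %d  hetero: %d  atoms: %d\n",
    x$id, x$source_format,
    paste(unique(x$residues$chain), collapse = ", "),
    pol, nrow(x$residues) - pol, nrow(x$atoms)
  ))
  invisible(x)
}

#' Extract the polymer sequence of a structure
#'
#' Returns the one-letter sequence of the selected chains together with the
#' residue identifier of each position. Hetero residues and waters are
#' excluded; unresolved residues are simply absent (no gap characters are
#' inserted). With `chains = "all"`, chains are concatenated in
#' (chain, number, icode) order.
#'
#' @param structure a [parse_structure()] result
#' @param chains `"all"` or a character vector of chain identifiers
#' @return a list with `sequence` (one-letter string) and `index`
#'   (data frame: `key`, `chain`, `number`, `icode`; row i corresponds to
#'   `substr(sequence, i, i)`)
#' @export
polymer_sequence <- function(structure, chains = "all") {
  res <- structure$residues[!structure$residues$is_hetero, , drop = FALSE]
  if (!identical(chains, "all")) {
    avail <- unique(structure$residues$chain)
    unknown <- setdiff(chains, avail)
    if (length(unknown)) {
      stop("unknown chain(s): ", paste(unknown, collapse = ", "),
           "; available chains: ", paste(avail, collapse = ", "))
    }
    res <- res[res$chain %in% chains, , drop = FALSE]
  }
  list(
    sequence = paste(res$one_letter, collapse = ""),
    index = res[, c("key", "chain", "number", "icode")]
  )
}

#' Write per-residue scores into the B-factor column of a PDB file
#'
#' Re-serializes the structure with every atom's B-factor replaced by its
#' residue's score, formatted to the PDB fixed-column convention (width 6,
#' 2 decimals). Residues absent from `scores`, or with an undefined (`NA`)
#' score, receive `missing_value`. All other fields are byte-identical to a
#' plain re-serialization of the input.
#'
#' @param structure a [parse_structure()] result
#' @param scores a named numeric vector (names are residue keys, `NA` for
#'   undefined) or a [run_window_analysis()] result
#' @param out_path output file path
#' @param missing_value value written for residues without a score
#' @return `out_path`, invisibly
#' @export
write_bfactor_pdb <- function(structure, scores, out_path, missing_value = 0) {
  if (inherits(scores, "window_result")) scores <- scores$scores
  stopifnot(is.numeric(scores))
  unknown <- setdiff(names(scores), structure$residues$key)
  if (length(unknown)) {
    stop("scores refer to residues absent from the structure: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  vals <- c(scores[!is.na(scores)], missing_value)
  if (any(vals >= 1000 | vals <= -100)) {
    stop("score(s) not representable in the 6-column B-factor field ",
         "(need -100 < value < 1000); rescale before writing")
  }
  b <- rep(missing_value, length(structure$atom_lines))
  m <- match(structure$atom_line_keys, names(scores))
  hit <- !is.na(m) & !is.na(scores[m])
  b[hit] <- scores[m[hit]]

  lines <- structure$lines
  idx <- structure$atom_lines
  padded <- sprintf("%-66s", lines[idx])
  tails <- ifelse(nchar(lines[idx]) > 66L, substring(lines[idx], 67L), "")
  lines[idx] <- paste0(substr(padded, 1L, 60L), sprintf("%6.2f", b), tails)
  con <- file(out_path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(out_path)
}

#' @rdname write_bfactor_pdb
#' @description `pdb_lines()` returns the plain PDB re-serialization of a
#'   structure (the original text for PDB input, a canonical serialization
#'   for mmCIF input).
#' @export
pdb_lines <- function(structure) structure$lines

# PDB v3.3 fixed-column ATOM/HETATM lines from an atom table
format_pdb_atom_lines <- function(at) {
  name4 <- vapply(seq_len(nrow(at)), function(i) {
    nm <- at$name[i]
    el <- toupper(trimws(if (is.null(at$element)) "" else at$element[i]))
    if (nchar(nm) >= 4L) sprintf("%-4s", substr(nm, 1L, 4L))
    else if (nchar(el) == 2L) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, "")
  altloc <- ifelse(nzchar(at$altloc), at$altloc, " ")
  icode <- ifelse(nzchar(at$icode), at$icode, " ")
  el <- toupper(trimws(at$element))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
          at$record, at$serial %% 100000L, name4, altloc, at$resname, at$chain,
          at$resnum %% 10000L, icode, at$x, at$y, at$z, at$occ, at$bfactor, el)
}

# single-residue view used by residue_distance()
structure_residue <- function(structure, key) {
  at <- structure$atoms[structure$atoms$key == key, , drop = FALSE]
  if (nrow(at) == 0L) stop("unknown residue: ", key)
  list(key = key, resname = at$resname[1L], atoms = at)
}
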