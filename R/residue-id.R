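#' Residue identifiers
#'
#' Residues are addressed by author chain, author residue number and insertion
#' code, never by serial position, so output can be cross-referenced with the
#' deposited structure. The canonical textual key is `"<chain>:<number><icode>"`
#' (insertion code omitted when blank), e.g. `"A:100"` or `"H:52A"`.
#'
#' @param chain chain identifier(s)
#' @param number author residue number(s), integer
#' @param icode insertion code(s); `""` or `" "` for none
#' @return `residue_key()` returns a character vector of keys;
#'   `parse_residue_key()` the inverse as a data frame with columns
#'   `chain`, `number`, `icode`.
#' @examples
#' residue_key("A", 100)            # "A:100"
#' parse_residue_key("H:52A")
#' @export
residue_key <- function(chain, number, icode = "") {
  icode <- trimws(icode)
  paste0(chain, ":", as.integer(number), icode)
}

#' @rdname residue_key
#' @param key character vector of residue keys
#' @export
parse_residue_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):(-?[0-9]+)([^0-9]?)$", key))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed residue key(s): ", paste(key[bad], collapse = ", "))
  }
  data.frame(
    chain  = vapply(m, `[`, "", 2L),
    number = as.integer(vapply(m, `[`, "", 3L)),
    icode  = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# total order (chain, number, icode), lexicographic / numeric / lexicographic
order_residue_keys <- function(key) {
  p <- parse_residue_key(key)
  order(p$chain, p$number, p$icode, method = "radix")
}

#' @rdname residue_key
#' @export
sort_residue_keys <- function(key) key[order_residue_keys(key)]

# three-letter -> one-letter table: the standard 20 plus common modified
# residues collapsed to their parent (MSE is ubiquitous in X-ray structures
# and would otherwise break the structure-to-reference alignment)
.AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O",
  SEP = "S", TPO = "T", PTR = "Y", HYP = "P", MLY = "K", CSO = "C"
)

.AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

aa_three_to_one <- function(resname) {
  out <- unname(.AA_3TO1[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}
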