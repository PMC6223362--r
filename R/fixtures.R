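#' Specify a synthetic structure/alignment fixture
#'
#' The generator produces matched toy structures and coding-sequence
#' alignments with known statistical structure, so the whole pipeline is
#' testable with no external downloads. A random ancestral coding sequence
#' (3 x `n_residues` bases, no internal stops) defines both the reference
#' protein (its translation, which is also the structure's sequence) and the
#' ancestor of the sampled sequences.
#'
#' Mutation models:
#' \describe{
#'   \item{`none`}{all rows identical (S = 0 everywhere downstream).}
#'   \item{`neutral-infinite-sites`}{each variable site is a new mutation at a
#'     random codon third position; the derived-allele count is drawn from the
#'     neutral site-frequency spectrum (P(i) proportional to 1/i,
#'     i = 1..n-1), under which pi and Watterson's theta have equal
#'     expectation and Tajima's D is centred near 0.}
#'   \item{`planted-balanced-cluster`}{neutral background plus, at the codons
#'     of `cluster_residues`, biallelic sites split across two equal haplotype
#'     groups (frequency ~50\%) — the balanced-polymorphism configuration
#'     that elevates pi relative to theta and hence D within the cluster.}
#' }
#' Mutations are restricted to third codon positions so the reading frame and
#' the reference translation stay easy to verify by eye; stop codons are
#' never introduced.
#'
#' @param n_residues number of residues (codons)
#' @param geometry `"ideal-helix"` (CA trace at 1.5 A rise / 100 degree twist
#'   / 2.3 A radius, plus 4 dummy heavy atoms per residue), `"random-coil"`
#'   (3.8 A random walk), or `"two-cluster"` (two compact blobs >= 40 A
#'   apart)
#' @param n_sequences rows in the generated alignment
#' @param mutation_model see above
#' @param cluster_residues residue positions of the planted cluster (defaults
#'   to a centered 5-residue run for the planted model)
#' @param snp_rate expected neutral segregating sites per residue (Poisson);
#'   0.25 by default, i.e. ~15 background SNPs on a 60-residue fragment
#' @param seed integer; fully determines all outputs
#' @return a `fixture_spec` list
#' @seealso [make_structure()], [make_alignment()]
#' @export
fixture_spec <- function(n_residues = 60L,
                         geometry = c("ideal-helix", "random-coil", "two-cluster"),
                         n_sequences = 24L,
                         mutation_model = c("neutral-infinite-sites", "none",
                                            "planted-balanced-cluster"),
                         cluster_residues = NULL,
                         snp_rate = 0.25,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  mutation_model <- match.arg(mutation_model)
  stopifnot(n_residues >= 2L, n_sequences >= 2L, snp_rate >= 0)
  if (mutation_model == "planted-balanced-cluster" && is.null(cluster_residues)) {
    mid <- n_residues %/% 2L
    cluster_residues <- (mid - 2L):(mid + 2L)
  }
  if (!is.null(cluster_residues)) {
    cluster_residues <- as.integer(cluster_residues)
    stopifnot(all(cluster_residues >= 1L), all(cluster_residues <= n_residues))
  }
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 n_sequences = as.integer(n_sequences),
                 mutation_model = mutation_model,
                 cluster_residues = cluster_residues,
                 snp_rate = snp_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# ancestor coding sequence: shared by make_structure and make_alignment
.ancestor_codons <- function(spec) {
  .with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    sense <- setdiff(all_codons, .STOP_CODONS)
    sample(sense, spec$n_residues, replace = TRUE)
  })
}

#' Generate a synthetic structure
#'
#' Builds the geometry described by the spec, emits PDB v3.3 text, and
#' returns the parsed structure (the emitted text re-parses to an equal
#' model by construction). Each residue carries five heavy atoms (N, CA, C,
#' O, CB); residue names follow the translated ancestor sequence so the
#' structure aligns exactly to the fixture reference.
#'
#' @param spec a [fixture_spec()]
#' @return list with `structure` (a [parse_structure()] result) and
#'   `pdb_lines` (character vector of PDB text)
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  ca <- .with_seed(spec$seed + 1L, switch(
    spec$geometry,
    "ideal-helix" = {
      i <- seq_len(n) - 1L
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    },
    "random-coil" = {
      dirs <- matrix(stats::rnorm(3L * n), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(3.8 * dirs, 2L, cumsum)
    },
    "two-cluster" = {
      centers <- rbind(c(0, 0, 0), c(60, 0, 0))
      half <- ceiling(n / 2L)
      grp <- rep(1:2, c(half, n - half))
      u <- matrix(stats::rnorm(3L * n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      rad <- 8 * stats::runif(n)^(1 / 3)
      centers[grp, , drop = FALSE] + u * rad
    }
  ))
  offsets <- rbind(
    N  = c(-1.20,  0.80, -0.50),
    CA = c( 0.00,  0.00,  0.00),
    C  = c( 1.25,  0.60,  0.40),
    O  = c( 2.10,  1.40,  0.20),
    CB = c( 0.30, -1.40,  0.90)
  )
  one <- strsplit(translate_dna(paste(.ancestor_codons(spec), collapse = "")),
                  "")[[1L]]
  resn <- unname(.AA_1TO3[one])
  k <- nrow(offsets)
  at <- data.frame(
    record = "ATOM",
    serial = seq_len(n * k),
    name = rep(rownames(offsets), n),
    altloc = "",
    resname = rep(resn, each = k),
    chain = "A",
    resnum = rep(seq_len(n), each = k),
    icode = "",
    x = rep(ca[, 1L], each = k) + offsets[, 1L],
    y = rep(ca[, 2L], each = k) + offsets[, 2L],
    z = rep(ca[, 3L], each = k) + offsets[, 3L],
    occ = 1, bfactor = 0,
    element = rep(c("N", "C", "C", "O", "C"), n),
    stringsAsFactors = FALSE
  )
  lines <- c(format_pdb_atom_lines(at), "END")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  st <- parse_structure(tmp, format = "pdb",
                        id = sprintf("fixture-%s-%d", spec$geometry, spec$seed))
  st$path <- NA_character_
  # keep full-precision coordinates in memory; the PDB text carries the
  # fixed-column 3-decimal rounding
  stopifnot(nrow(st$atoms) == nrow(at))
  st$atoms$x <- at$x; st$atoms$y <- at$y; st$atoms$z <- at$z
  list(structure = st, pdb_lines = lines)
}

#' Generate a synthetic coding-sequence alignment
#'
#' @param spec a [fixture_spec()]
#' @return list with `aln` (an [alignment_data()], nucleotide), `ref` (the
#'   ancestor translation as a [reference_seq()]), and `info` (positions of
#'   planted and background mutations)
#' @export
make_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  codons <- .ancestor_codons(spec)
  n <- spec$n_sequences
  R <- spec$n_residues
  anc <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  mat <- matrix(rep(anc, each = n), nrow = n)

  third_of <- function(res) 3L * res          # column of residue's 3rd base
  alt_base <- function(site) {
    codon_start <- site - 3L + 1L
    cod <- anc[codon_start:(codon_start + 2L)]
    cand <- setdiff(c("A", "C", "G", "T"), anc[site])
    ok <- vapply(cand, function(b) {
      !(paste0(cod[1L], cod[2L], b) %in% .STOP_CODONS)
    }, TRUE)
    cand <- cand[ok]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }

  planted <- integer(0)
  background <- integer(0)
  .with_seed(spec$seed + 2L, {
    if (spec$mutation_model == "planted-balanced-cluster") {
      planted <- third_of(spec$cluster_residues)
      group2 <- (ceiling(n / 2L) + 1L):n       # two fixed haplotype groups
      for (s in planted) mat[group2, s] <- alt_base(s)
    }
    if (spec$mutation_model != "none") {
      avail <- setdiff(third_of(seq_len(R)), planted)
      n_mut <- min(stats::rpois(1L, spec$snp_rate * R), length(avail))
      background <- sort(sample(avail, n_mut))
      sfs_p <- 1 / seq_len(n - 1L)
      for (s in background) {
        i <- sample.int(n - 1L, 1L, prob = sfs_p)
        carriers <- sample.int(n, i)
        mat[carriers, s] <- alt_base(s)
      }
    }
  })
  rows <- apply(mat, 1L, paste, collapse = "")
  list(
    aln = alignment_data(sprintf("seq%03d", seq_len(n)), rows, "dna"),
    ref = reference_seq(sprintf("fixture-ref-%d", spec$seed),
                        translate_dna(paste(codons, collapse = ""))),
    info = list(planted_columns = planted, background_columns = background)
  )
}

#' Write fixture outputs as FASTA
#'
#' @param x an [alignment_data()] or [reference_seq()]
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "alignment_data")) {
    set <- Biostrings::BStringSet(stats::setNames(x$rows, x$names))
  } else if (inherits(x, "reference_seq")) {
    set <- Biostrings::BStringSet(stats::setNames(x$residues, x$id))
  } else {
    stop("write_fasta expects an alignment_data or reference_seq object")
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
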