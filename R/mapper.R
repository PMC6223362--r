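#' Scoring functions for windowed data
#'
#' A scoring function takes the data aggregated over one spatial window — a
#' windowed sub-alignment for `"dna-alignment"`/`"protein-alignment"` kinds,
#' or a numeric vector for the `"numeric"` kind — and returns a single number
#' or `NA` (an explicit "no value"). `min_data` is the minimum number of
#' mapped residues a window must contain before the function is called.
#'
#' `builtin_scoring_function()` provides the predefined choices:
#' `"tajimas-d"`, `"pi"`, `"theta-w"`, `"seg-sites"` (nucleotide data),
#' `"entropy"` (mean per-column Shannon entropy, protein data), and `"mean"`
#' (numeric data). Users can supply their own via `scoring_function()`.
#'
#' @param name label recorded in results
#' @param kind `"dna-alignment"`, `"protein-alignment"`, or `"numeric"`
#' @param fn the function; must be deterministic for a given input
#' @param min_data minimum mapped residues per window (default 1)
#' @return a `scoring_function` object
#' @export
scoring_function <- function(name, kind = c("dna-alignment", "protein-alignment",
                                            "numeric"),
                             fn, min_data = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.function(fn), min_data >= 1L)
  structure(list(name = name, kind = kind, fn = fn,
                 min_data = as.integer(min_data)),
            class = "scoring_function")
}

#' @rdname scoring_function
#' @param gap_policy gap policy the built-in alignment statistics should
#'   assume was applied (`"complete-deletion"`) or should handle themselves
#'   (`"pairwise"`)
#' @export
builtin_scoring_function <- function(name = c("tajimas-d", "pi", "theta-w",
                                              "seg-sites", "entropy", "mean"),
                                     min_data = 1L,
                                     gap_policy = "complete-deletion") {
  name <- match.arg(name)
  gap <- if (gap_policy == "pairwise") "pairwise" else "forbid"
  null_if_empty <- function(f) {
    function(sub) if (sub$length == 0L) NA_real_ else f(sub)
  }
  switch(name,
    "tajimas-d" = scoring_function("tajimas-d", "dna-alignment",
      null_if_empty(function(sub) tajimas_d(sub, gap = gap)), min_data),
    "pi" = scoring_function("pi", "dna-alignment",
      null_if_empty(function(sub) nucleotide_diversity(sub, gap = gap)), min_data),
    "theta-w" = scoring_function("theta-w", "dna-alignment",
      null_if_empty(function(sub) wattersons_theta(sub, gap = gap)), min_data),
    "seg-sites" = scoring_function("seg-sites", "dna-alignment",
      null_if_empty(function(sub) as.numeric(segregating_sites(sub, gap = gap))),
      min_data),
    "entropy" = scoring_function("entropy", "protein-alignment",
      null_if_empty(function(sub) mean(shannon_entropy_profile(sub, gap = gap))),
      min_data),
    "mean" = scoring_function("mean", "numeric",
      function(v) if (length(v) == 0L) NA_real_ else mean(v), min_data)
  )
}

#' Run a 3D sliding-window analysis
#'
#' The engine of the package: for every polymer residue of the structure (the
#' central residue), all residues within the configured radius are collected,
#' the data mapped to those residues is aggregated — alignment columns
#' concatenated into a windowed sub-alignment, or numeric values pooled — and
#' the scoring function's value is mapped back to the central residue.
#'
#' Sequence data is attached to structure residues by a global alignment of
#' each selected chain's polymer sequence to the reference, composed with a
#' codon-wise (nucleotide) or column-wise (protein) map from reference
#' positions to alignment columns. In oligomers where several chains map to
#' the same reference positions, each chain's residues are scored
#' independently and a window spanning protomers includes each mapped residue
#' once per distinct residue identifier (shared columns are duplicated, not
#' deduplicated).
#'
#' @param structure a [parse_structure()] result
#' @param data an [alignment_data()] (nucleotide or protein) or a named
#'   numeric vector of per-reference-position values (see
#'   [read_numeric_table()])
#' @param ref a [reference_seq()]
#' @param fn a [scoring_function()] or the name of a built-in one
#' @param config a [neighbor_config()]
#' @param gap_policy `"complete-deletion"` (default: drop, within each
#'   window's sub-alignment, every column containing a gap or ambiguity) or
#'   `"pairwise"`
#' @param chains chains to score (`"all"` or a character vector); each
#'   selected chain must align to the reference
#' @param representative alignment row used to establish the codon frame
#' @param min_identity identity floor for the structure/reference and
#'   representative/reference alignments
#' @return a `window_result`: list with `scores` (named numeric, `NA` for
#'   null), `window_sizes`, `mapped_counts`, `columns_used` (post-filter
#'   column counts), `config` (full snapshot for reproducibility), and the
#'   input `structure`
#' @examples
#' spec <- fixture_spec(n_residues = 30, n_sequences = 12,
#'                      mutation_model = "planted-balanced-cluster",
#'                      cluster_residues = 14:18, seed = 7)
#' st <- make_structure(spec)$structure
#' fx <- make_alignment(spec)
#' res <- run_window_analysis(st, fx$aln, fx$ref, "tajimas-d",
#'                            neighbor_config(radius = 10))
#' head(as.data.frame(res))
#' @export
run_window_analysis <- function(structure, data, ref, fn,
                                config = neighbor_config(),
                                gap_policy = c("complete-deletion", "pairwise"),
                                chains = "all", representative = 1L,
                                min_identity = 0.3) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(structure, "spatwin_structure"),
            inherits(ref, "reference_seq"),
            inherits(config, "neighbor_config"))
  if (is.character(fn)) {
    fn <- builtin_scoring_function(fn, gap_policy = gap_policy)
  }
  stopifnot(inherits(fn, "scoring_function"))

  is_numeric_data <- is.numeric(data)
  if (is_numeric_data) {
    if (fn$kind != "numeric") {
      stop("numeric data requires a scoring function of kind 'numeric', not '",
           fn$kind, "' (", fn$name, ")")
    }
    if (is.null(names(data))) stop("numeric data must be named by reference position")
  } else {
    stopifnot(inherits(data, "alignment_data"))
    want <- paste0(data$alphabet, "-alignment")
    if (fn$kind != want) {
      stop("scoring function '", fn$name, "' has kind '", fn$kind,
           "' but the alignment is ", data$alphabet)
    }
    if (length(data$rows) < 2L) {
      stop("population statistics need an alignment with >= 2 rows")
    }
  }

  # chain-wise structure -> reference residue map
  scope_chains <- if (identical(chains, "all")) {
    sort(unique(structure$residues$chain[!structure$residues$is_hetero]))
  } else chains
  residue_to_ref <- integer(0)
  for (ch in scope_chains) {
    ps <- polymer_sequence(structure, ch)
    m <- tryCatch(
      align_protein_to_reference(ps, ref, min_identity),
      error = function(e) stop("chain ", ch, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    residue_to_ref <- c(residue_to_ref, m)
  }

  # reference -> data columns
  if (is_numeric_data) {
    map <- compose_map(residue_to_ref, NULL)
    value_of <- stats::setNames(as.numeric(data), names(data))
    mapped_keys <- names(residue_to_ref)[
      as.character(residue_to_ref) %in% names(value_of)]
  } else if (data$alphabet == "dna") {
    cm <- map_codons(ref, data, representative, min_identity)
    map <- compose_map(residue_to_ref, cm$ref_to_columns, cm$strand)
    mapped_keys <- names(map$columns)
  } else {
    pm <- map_protein_columns(ref, data, representative, min_identity)
    map <- compose_map(residue_to_ref, pm$ref_to_columns, pm$strand)
    mapped_keys <- names(map$columns)
  }

  index <- build_neighbor_index(structure, config)
  centers <- structure$residues$key[!structure$residues$is_hetero &
                                      structure$residues$chain %in% scope_chains]
  centers <- sort_residue_keys(centers)

  scores <- stats::setNames(rep(NA_real_, length(centers)), centers)
  window_sizes <- stats::setNames(integer(length(centers)), centers)
  mapped_counts <- stats::setNames(integer(length(centers)), centers)
  columns_used <- stats::setNames(rep(NA_integer_, length(centers)), centers)

  for (ck in centers) {
    window <- neighbors_within(index, ck, config)
    window_sizes[[ck]] <- length(window)
    in_win <- intersect(window, mapped_keys)
    mapped_counts[[ck]] <- length(in_win)
    if (length(in_win) < fn$min_data) next
    val <- tryCatch({
      if (is_numeric_data) {
        v <- unname(value_of[as.character(residue_to_ref[in_win])])
        fn$fn(v)
      } else {
        sub <- window_subalignment(data, map, in_win, gap_policy)
        columns_used[[ck]] <- sub$length
        fn$fn(sub)
      }
    }, error = function(e) {
      stop("scoring function '", fn$name, "' failed at central residue ", ck,
           " (window of ", length(window), " residues): ",
           conditionMessage(e), call. = FALSE)
    })
    scores[[ck]] <- if (is.null(val) || length(val) == 0L) NA_real_
                    else as.numeric(val)
  }

  structure(list(
    scores = scores,
    window_sizes = window_sizes,
    mapped_counts = mapped_counts,
    columns_used = columns_used,
    config = list(
      radius = config$radius, metric = config$metric,
      chain_scope = config$chain_scope,
      include_hetero = config$include_hetero,
      include_hydrogens = config$include_hydrogens,
      gap_policy = gap_policy, fn = fn$name, min_data = fn$min_data,
      data_kind = if (is_numeric_data) "numeric" else data$alphabet,
      chains = scope_chains,
      strand = map$strand %||% "forward",
      n_sequences = if (is_numeric_data) NA_integer_ else length(data$rows),
      oligomer_columns = "duplicated"
    ),
    structure = structure
  ), class = "window_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.window_result <- function(x, ...) {
  defined <- sum(!is.na(x$scores))
  cat(sprintf(
    "<window_result> %s, radius %.1f A (%s)\n  %d residues scored (%d defined, %d null)\n  window size: %d-%d residues\n",
    x$config$fn, x$config$radius, x$config$metric, length(x$scores), defined,
    sum(is.na(x$scores)), min(x$window_sizes), max(x$window_sizes)))
  invisible(x)
}

#' @export
as.data.frame.window_result <- function(x, ...) {
  p <- parse_residue_key(names(x$scores))
  data.frame(chain = p$chain, resnum = p$number, icode = p$icode,
             score = unname(x$scores),
             window_size = unname(x$window_sizes),
             mapped_residues = unname(x$mapped_counts),
             columns_used = unname(x$columns_used),
             stringsAsFactors = FALSE)
}

#' Export window-analysis results
#'
#' Writes results as TSV (columns `chain`, `resnum`, `icode`, `score` —
#' empty for null — and `window_size`), JSON (residue-to-score mapping plus
#' the full configuration snapshot), and/or a PDB file with scores in the
#' B-factor column via [write_bfactor_pdb()].
#'
#' @param result a [run_window_analysis()] result
#' @param format subset of `c("tsv", "json", "pdb")`
#' @param prefix output path prefix; files are written as
#'   `<prefix>.tsv|json|pdb`
#' @param missing_value B-factor written for residues with a null score
#' @return named character vector of the files written, invisibly
#' @export
export_results <- function(result, format = c("tsv", "json", "pdb"),
                           prefix = "spatwin", missing_value = 0) {
  stopifnot(inherits(result, "window_result"))
  format <- match.arg(format, several.ok = TRUE)
  written <- character(0)
  if ("tsv" %in% format) {
    path <- paste0(prefix, ".tsv")
    df <- as.data.frame(result)[, c("chain", "resnum", "icode", "score",
                                    "window_size")]
    df$score <- ifelse(is.na(df$score), "", format(df$score, digits = 10,
                                                   trim = TRUE,
                                                   scientific = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written["tsv"] <- path
  }
  if ("json" %in% format) {
    path <- paste0(prefix, ".json")
    payload <- list(
      config = result$config,
      scores = as.list(result$scores),
      window_sizes = as.list(result$window_sizes)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    written["json"] <- path
  }
  if ("pdb" %in% format) {
    path <- paste0(prefix, ".pdb")
    write_bfactor_pdb(result$structure, result$scores, path, missing_value)
    written["pdb"] <- path
  }
  invisible(written)
}
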