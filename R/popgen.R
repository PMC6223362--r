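#' Diversity statistics on an alignment
#'
#' Statistics are computed on the per-alignment (total) scale, as Tajima's D
#' requires: `nucleotide_diversity()` returns the average number of
#' differences per sequence *pair* (not per site), and `wattersons_theta()`
#' is on the same scale. Per-site variants are obtained by dividing by the
#' column count. Multi-allelic columns count once toward S and contribute
#' per-pair state mismatches to pi.
#'
#' By default (`gap = "forbid"`) the functions require the gap policy to have
#' been applied already and raise an error on any residual `-`/`N`/`X`
#' character. With `gap = "pairwise"`, gaps and ambiguities are handled in
#' place: pi compares each pair over the columns where both rows are
#' unambiguous, and S counts columns with two or more distinct unambiguous
#' states.
#'
#' @param aln an [alignment_data()], or a character matrix (rows = sequences)
#' @param gap `"forbid"` or `"pairwise"`
#' @return `segregating_sites()`: integer count of columns with more than one
#'   state. `nucleotide_diversity()`: mean pairwise difference (numeric).
#'   `wattersons_theta()`: S divided by the harmonic number a1.
#' @seealso [tajimas_d()], [diversity_summary()]
#' @export
segregating_sites <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  mat <- .popgen_matrix(aln, gap)
  if (ncol(mat) == 0L) return(0L)
  amb <- .ambiguous_states(aln)
  sum(apply(mat, 2L, function(col) {
    states <- unique(col[!(col %in% amb)])
    length(states) > 1L
  }))
}

#' @rdname segregating_sites
#' @export
nucleotide_diversity <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  mat <- .popgen_matrix(aln, gap)
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: nucleotide diversity needs >= 2 sequences")
  if (gap == "forbid") {
    # column-wise state counts: pairwise diffs per column = C(n,2) - sum C(c_a,2)
    npairs <- n * (n - 1) / 2
    if (ncol(mat) == 0L) return(0)
    diffs <- vapply(seq_len(ncol(mat)), function(j) {
      cnt <- table(mat[, j])
      npairs - sum(cnt * (cnt - 1) / 2)
    }, 0)
    sum(diffs) / npairs
  } else {
    amb <- .ambiguous_states(aln)
    tot <- 0
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        ok <- !(mat[i, ] %in% amb) & !(mat[k, ] %in% amb)
        tot <- tot + sum(mat[i, ok] != mat[k, ok])
      }
    }
    tot / (n * (n - 1) / 2)
  }
}

#' @rdname segregating_sites
#' @export
wattersons_theta <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  n <- nrow(.popgen_matrix(aln, gap))
  if (n < 2L) stop("insufficient data: Watterson's theta needs >= 2 sequences")
  segregating_sites(aln, gap) / sum(1 / seq_len(n - 1L))
}

#' Tajima's D
#'
#' Compares mean pairwise differences (pi) with Watterson's estimator
#' (S / a1): positive values indicate an excess of intermediate-frequency
#' variants (a balancing-selection signature), negative values an excess of
#' rare variants. The variance coefficients follow the classical
#' derivation: with a1 = sum 1/i and a2 = sum 1/i^2 (i = 1..n-1),
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2), and
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)).
#'
#' Returns `NA` (an explicit "undefined", distinct from 0) when the variance
#' estimate degenerates: S = 0, n < 3, or n = 3 (where c1 and c2 are
#' identically zero).
#'
#' @inheritParams segregating_sites
#' @return numeric, or `NA` when undefined
#' @export
tajimas_d <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  mat <- .popgen_matrix(aln, gap)
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: Tajima's D needs >= 2 sequences")
  S <- segregating_sites(aln, gap = gap)
  if (S == 0L || n < 3L) return(NA_real_)
  pi_total <- nucleotide_diversity(aln, gap = gap)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  var_est <- e1 * S + e2 * S * (S - 1)
  # at n = 3 the coefficients c1 and c2 vanish identically and the variance
  # estimate is 0: D is undefined there as well
  if (!is.finite(var_est) || var_est <= 0) return(NA_real_)
  (pi_total - S / a1) / sqrt(var_est)
}

#' Per-column Shannon entropy
#'
#' For each column, the entropy -sum p_a log2 p_a over observed states, in
#' bits. The usual window score is the mean over columns.
#'
#' @inheritParams segregating_sites
#' @return numeric vector of per-column entropies (length 0 for a zero-column
#'   alignment)
#' @export
shannon_entropy_profile <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  mat <- .popgen_matrix(aln, gap)
  amb <- .ambiguous_states(aln)
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (gap == "pairwise") col <- col[!(col %in% amb)]
    p <- table(col) / length(col)
    -sum(p * log2(p))
  }, 0)
}

#' Summary of diversity statistics
#'
#' @inheritParams segregating_sites
#' @return a `diversity_summary` list: `n` (sequences), `L` (columns after
#'   gap policy), `S`, `pi_total`, `theta_w`, `tajimas_d` (`NA` when
#'   undefined)
#' @export
diversity_summary <- function(aln, gap = c("forbid", "pairwise")) {
  gap <- match.arg(gap)
  mat <- .popgen_matrix(aln, gap)
  structure(list(
    n = nrow(mat), L = ncol(mat),
    S = segregating_sites(aln, gap = gap),
    pi_total = nucleotide_diversity(aln, gap = gap),
    theta_w = wattersons_theta(aln, gap = gap),
    tajimas_d = tajimas_d(aln, gap = gap)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("n = %d, L = %d, S = %d\npi = %.4f, theta_w = %.4f, Tajima's D = %s\n",
              x$n, x$L, x$S, x$pi_total, x$theta_w,
              if (is.na(x$tajimas_d)) "NA (undefined)"
              else sprintf("%.4f", x$tajimas_d)))
  invisible(x)
}

.ambiguous_states <- function(aln) {
  if (inherits(aln, "alignment_data") && aln$alphabet == "protein") c("-", "X")
  else c("-", "N")
}

.popgen_matrix <- function(aln, gap) {
  mat <- if (is.matrix(aln)) aln else aln_matrix(aln)
  if (gap == "forbid" && ncol(mat) > 0L) {
    amb <- .ambiguous_states(aln)
    if (any(mat %in% amb)) {
      stop("alignment contains gap/ambiguity characters (",
           paste(amb, collapse = ", "), "); apply a gap policy first or ",
           "use gap = \"pairwise\"")
    }
  }
  mat
}
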