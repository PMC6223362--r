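# Independent straight-line oracles. These are deliberately naive (explicit
# loops, no shared code with R/) and were written before the corresponding
# package code; tests compare the package against them.

# Tajima 1989 coefficient chain, evaluated literally from a character matrix.
oracle_tajimas_d <- function(mat) {
  n <- nrow(mat)
  # S: columns with more than one state
  S <- 0L
  for (j in seq_len(ncol(mat))) {
    if (length(unique(mat[, j])) > 1L) S <- S + 1L
  }
  # pi: mean pairwise difference over all unordered pairs
  npairs <- 0L
  tot <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (k in (i + 1L):n) {
        npairs <- npairs + 1L
        tot <- tot + sum(mat[i, ] != mat[k, ])
      }
    }
  }
  pi_total <- if (npairs > 0L) tot / npairs else NA_real_
  if (S == 0L || n < 3L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0L; npairs <- 0L
  for (i in 1:(n - 1L)) {
    for (k in (i + 1L):n) {
      npairs <- npairs + 1L
      tot <- tot + sum(mat[i, ] != mat[k, ])
    }
  }
  tot / npairs
}

oracle_segregating_sites <- function(mat) {
  s <- 0L
  for (j in seq_len(ncol(mat))) if (length(unique(mat[, j])) > 1L) s <- s + 1L
  s
}

# Brute-force residue neighborhood: plain O(n^2) loops over the structure's
# atom table, no spatial index. Returns sorted residue keys.
oracle_neighbors <- function(structure, center, radius, metric = "min-atom",
                             include_hetero = FALSE, include_hydrogens = FALSE,
                             chain_scope = "all-chains") {
  at <- structure$atoms
  if (!include_hetero)    at <- at[!at$is_hetero, , drop = FALSE]
  if (!include_hydrogens) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  keys <- unique(at$key)
  stopifnot(center %in% keys)
  ctr_chain <- at$chain[match(center, at$key)]
  dist_rr <- function(ka, kb) {
    a <- at[at$key == ka, , drop = FALSE]
    b <- at[at$key == kb, , drop = FALSE]
    if (metric == "c-alpha") {
      a <- a[a$name == "CA", , drop = FALSE]
      b <- b[b$name == "CA", , drop = FALSE]
      stopifnot(nrow(a) == 1L, nrow(b) == 1L)
      return(sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2)))
    }
    if (metric == "centroid") {
      pa <- c(mean(a$x), mean(a$y), mean(a$z))
      pb <- c(mean(b$x), mean(b$y), mean(b$z))
      return(sqrt(sum((pa - pb)^2)))
    }
    best <- Inf
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
        if (d < best) best <- d
      }
    }
    best
  }
  hits <- character(0)
  for (k in keys) {
    if (chain_scope == "same-chain" && at$chain[match(k, at$key)] != ctr_chain) next
    if (dist_rr(center, k) <= radius) hits <- c(hits, k)
  }
  sort_residue_keys_oracle(hits)
}

# (chain, number, icode) lexicographic order, recomputed here from the key text
sort_residue_keys_oracle <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):(-?[0-9]+)([^0-9]?)$", keys))
  ch <- vapply(m, `[`, "", 2L)
  no <- as.integer(vapply(m, `[`, "", 3L))
  ic <- vapply(m, `[`, "", 4L)
  keys[order(ch, no, ic)]
}

# Whole-structure brute force: one full point-point distance matrix, no
# spatial index. Returns a list center key -> sorted neighbor keys.
oracle_neighbor_sets <- function(structure, radius, metric = "min-atom",
                                 include_hetero = FALSE,
                                 include_hydrogens = FALSE,
                                 chain_scope = "all-chains") {
  at <- structure$atoms
  if (!include_hetero)    at <- at[!at$is_hetero, , drop = FALSE]
  if (!include_hydrogens) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  keys <- unique(at$key)
  if (metric == "c-alpha") {
    ca <- at[at$name == "CA", , drop = FALSE]
    pts <- cbind(ca$x, ca$y, ca$z); pkey <- ca$key
  } else if (metric == "centroid") {
    pts <- t(vapply(keys, function(k) {
      a <- at[at$key == k, , drop = FALSE]
      c(mean(a$x), mean(a$y), mean(a$z))
    }, numeric(3)))
    pkey <- keys
  } else {
    pts <- cbind(at$x, at$y, at$z); pkey <- at$key
  }
  d <- as.matrix(stats::dist(pts))
  # residue-by-residue minimum distance, reducing rows then columns
  grp <- split(seq_along(pkey), pkey)[keys]
  rowmin <- t(vapply(grp, function(ix) {
    apply(d[ix, , drop = FALSE], 2L, min)
  }, numeric(ncol(d))))
  dres <- vapply(grp, function(jx) {
    apply(rowmin[, jx, drop = FALSE], 1L, min)
  }, numeric(length(keys)))          # keys x keys
  rownames(dres) <- keys
  colnames(dres) <- keys
  chain_of <- stats::setNames(at$chain[match(keys, at$key)], keys)
  out <- list()
  for (ck in keys) {
    nb <- keys[dres[ck, ] <= radius]
    if (chain_scope == "same-chain") nb <- nb[chain_of[nb] == chain_of[[ck]]]
    out[[ck]] <- sort_residue_keys_oracle(nb)
  }
  out
}

# Straight-line reference pipeline: loops residues, collects neighbors by the
# O(n^2) oracle, assembles the windowed sub-alignment by plain column
# concatenation + complete deletion, and scores with the popgen oracle.
oracle_pipeline_tajima <- function(structure, aln_rows, columns_by_residue,
                                   radius, metric = "min-atom") {
  mat <- do.call(rbind, strsplit(aln_rows, ""))
  at <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  keys <- sort_residue_keys_oracle(unique(at$key))
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (k in keys) {
    win <- oracle_neighbors(structure, k, radius, metric)
    cols <- integer(0)
    for (w in win) cols <- c(cols, columns_by_residue[[w]])
    if (length(cols) == 0L) next
    sub <- mat[, cols, drop = FALSE]
    keep <- logical(ncol(sub))
    for (j in seq_len(ncol(sub))) keep[j] <- !any(sub[, j] %in% c("-", "N"))
    sub <- sub[, keep, drop = FALSE]
    if (ncol(sub) == 0L) next
    out[k] <- oracle_tajimas_d(sub)
  }
  out
}
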