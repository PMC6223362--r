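#' Configure a 3D residue-neighborhood query
#'
#' A neighborhood (the 3D window) is the set of residues within `radius`
#' angstroms of a central residue, under one of three inter-residue distance
#' metrics:
#' \describe{
#'   \item{`min-atom`}{minimum Euclidean distance over eligible atom pairs
#'     (default; the most inclusive reading of a spatial window, appropriate
#'     for surface epitopes)}
#'   \item{`c-alpha`}{distance between the two CA atoms}
#'   \item{`centroid`}{distance between unweighted mean atom coordinates}
#' }
#' Distances are compared with `<=` (a closed ball), so boundary ties are
#' included deterministically. Hydrogens are excluded from distance
#' calculations by default: most crystal structures lack them, and including
#' them would make neighborhoods differ between X-ray and NMR inputs. Hetero
#' residues are excluded by default since they carry no alignment data.
#'
#' @param radius window radius in angstroms; must be positive. 15 is the
#'   typical maximum dimension of an antibody-antigen interface.
#' @param metric `"min-atom"`, `"c-alpha"`, or `"centroid"`
#' @param include_hetero include hetero residues (ligands, waters) in windows
#' @param include_hydrogens include hydrogen atoms in distance calculations
#' @param chain_scope `"all-chains"` (windows may span chains, e.g. across an
#'   oligomer interface) or `"same-chain"`
#' @return a `neighbor_config` list
#' @export
neighbor_config <- function(radius = 15,
                            metric = c("min-atom", "c-alpha", "centroid"),
                            include_hetero = FALSE,
                            include_hydrogens = FALSE,
                            chain_scope = c("all-chains", "same-chain")) {
  metric <- match.arg(metric)
  chain_scope <- match.arg(chain_scope)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("radius must be a single positive number (angstroms)")
  }
  structure(list(radius = radius, metric = metric,
                 include_hetero = include_hetero,
                 include_hydrogens = include_hydrogens,
                 chain_scope = chain_scope),
            class = "neighbor_config")
}

#' Distance between two residues
#'
#' @param a,b single-residue views as returned by `structure_residue()`, or
#'   data frames of atoms with `x`, `y`, `z`, `name`, `element` columns
#' @param metric distance definition, see [neighbor_config()]
#' @param include_hydrogens include hydrogens among eligible atoms
#' @return distance in angstroms; symmetric, and 0 for a residue against
#'   itself
#' @export
residue_distance <- function(a, b, metric = c("min-atom", "c-alpha", "centroid"),
                             include_hydrogens = FALSE) {
  metric <- match.arg(metric)
  pa <- .metric_points(a, metric, include_hydrogens)
  pb <- .metric_points(b, metric, include_hydrogens)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(max(min(d2), 0))
}

.metric_points <- function(res, metric, include_hydrogens) {
  at <- if (is.data.frame(res)) res else res$atoms
  label <- if (is.data.frame(res)) "residue" else res$key
  if (!include_hydrogens) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (metric == "c-alpha") {
    at <- at[at$name == "CA", , drop = FALSE]
    if (nrow(at) == 0L) {
      stop("c-alpha metric inapplicable: residue ", label, " has no CA atom")
    }
    at <- at[1L, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("residue ", label, " has no eligible atoms")
  p <- cbind(at$x, at$y, at$z)
  if (metric == "centroid") p <- matrix(colMeans(p), nrow = 1L)
  p
}

#' Build a spatial index over a structure
#'
#' Precomputes, per residue, the point set its distance metric uses (all
#' eligible atoms for `min-atom`, the CA atom for `c-alpha`, the atom centroid
#' for `centroid`) and bins the points on a uniform grid with cell edge equal
#' to the configured radius, so that radius queries only examine neighboring
#' cells. Queries return exactly the brute-force answer.
#'
#' @param structure a [parse_structure()] result
#' @param config a [neighbor_config()]
#' @return a `neighbor_index` object for [neighbors_within()]
#' @export
build_neighbor_index <- function(structure, config) {
  stopifnot(inherits(config, "neighbor_config"))
  at <- structure$atoms
  if (!config$include_hetero) at <- at[!at$is_hetero, , drop = FALSE]
  if (!config$include_hydrogens) {
    at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("no atoms eligible for the spatial index ",
         "(check include_hetero / include_hydrogens)")
  }
  keys <- unique(at$key)
  if (config$metric == "c-alpha") {
    ca <- at[at$name == "CA", , drop = FALSE]
    ca <- ca[!duplicated(ca$key), , drop = FALSE]
    missing <- setdiff(keys, ca$key)
    if (length(missing)) {
      stop("c-alpha metric inapplicable: residue ", missing[1L],
           " has no CA atom")
    }
    pts <- cbind(ca$x, ca$y, ca$z); pt_key <- ca$key; pt_chain <- ca$chain
  } else if (config$metric == "centroid") {
    cx <- tapply(at$x, at$key, mean)[keys]
    cy <- tapply(at$y, at$key, mean)[keys]
    cz <- tapply(at$z, at$key, mean)[keys]
    pts <- cbind(unname(cx), unname(cy), unname(cz))
    pt_key <- keys; pt_chain <- at$chain[match(keys, at$key)]
  } else {
    pts <- cbind(at$x, at$y, at$z); pt_key <- at$key; pt_chain <- at$chain
  }
  cell_edge <- config$radius
  cell <- floor(pts / cell_edge)
  cell_id <- paste(cell[, 1L], cell[, 2L], cell[, 3L], sep = ",")
  structure(list(
    points = pts, point_key = pt_key, point_chain = pt_chain,
    cell = cell, cell_edge = cell_edge,
    cell_members = split(seq_len(nrow(pts)), cell_id),
    residue_keys = sort_residue_keys(keys),
    residue_chain = at$chain[match(keys, at$key)][order_residue_keys(keys)] ,
    config = config
  ), class = "neighbor_index")
}

#' Residues within a radius of a central residue
#'
#' Returns every residue (the center included) whose distance to `center`
#' under the configured metric is at most the configured radius, restricted by
#' `chain_scope`, ordered by residue identifier.
#'
#' @param index a [build_neighbor_index()] result
#' @param center residue key of the central residue (see [residue_key()])
#' @param config a [neighbor_config()]; the metric and eligibility flags must
#'   match those the index was built with
#' @return character vector of residue keys
#' @export
neighbors_within <- function(index, center, config = index$config) {
  stopifnot(inherits(index, "neighbor_index"))
  if (!identical(config$metric, index$config$metric) ||
      !identical(config$include_hetero, index$config$include_hetero) ||
      !identical(config$include_hydrogens, index$config$include_hydrogens)) {
    stop("query config metric/eligibility differs from the indexed config; ",
         "rebuild the index")
  }
  ctr <- which(index$point_key == center)
  if (length(ctr) == 0L) {
    stop("unknown center residue: ", center,
         " (not present in the indexed structure)")
  }
  r <- config$radius
  reach <- ceiling(r / index$cell_edge)
  cand <- if (reach > 4L) {
    seq_len(nrow(index$points))        # radius spans most of the grid
  } else {
    offs <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
    ids <- unique(unlist(lapply(ctr, function(i) {
      paste(index$cell[i, 1L] + offs[, 1L],
            index$cell[i, 2L] + offs[, 2L],
            index$cell[i, 3L] + offs[, 3L], sep = ",")
    })))
    unlist(index$cell_members[ids], use.names = FALSE)
  }
  if (length(cand) == 0L) cand <- ctr
  cpts <- index$points[cand, , drop = FALSE]
  hit <- rep(FALSE, length(cand))
  for (i in ctr) {
    d2 <- (cpts[, 1L] - index$points[i, 1L])^2 +
          (cpts[, 2L] - index$points[i, 2L])^2 +
          (cpts[, 3L] - index$points[i, 3L])^2
    hit <- hit | d2 <= r * r
  }
  found <- unique(index$point_key[cand[hit]])
  if (config$chain_scope == "same-chain") {
    ctr_chain <- index$point_chain[ctr[1L]]
    found <- found[index$point_chain[match(found, index$point_key)] == ctr_chain]
  }
  sort_residue_keys(found)
}
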