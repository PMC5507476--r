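#' Distance-threshold neighbour graph
#'
#' Symmetric adjacency by centre distance: cells i and j are neighbours when
#' their distance is at most `radius`. This is the neighbourhood used by the
#' developmental rules in 2D.
#'
#' @param pos matrix of coordinates (rows = cells) or an embryo.
#' @param radius distance threshold (cell radii).
#' @return a logical adjacency matrix (no self loops).
#' @export
neighbor_graph <- function(pos, radius) {
  if (inherits(pos, "embryo")) pos <- pos$pos
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n == 0) stop("need at least one cell")
  dm <- as.matrix(stats::dist(pos))
  adj <- dm <= radius
  diag(adj) <- FALSE
  adj
}

#' Halfway-point true nearest neighbours
#'
#' The neighbour rule used in 3D, where a centre distance threshold confuses
#' nearest with next-nearest neighbours: for each cell the `k` closest cells
#' are candidates, and a candidate j is kept when no other candidate lies
#' strictly closer to the midpoint of (i, j) than the endpoints themselves
#' (equidistant ties are retained). The result is symmetrised.
#'
#' @param pos coordinate matrix (>= 2 distinct points) or an embryo.
#' @param k number of closest candidates per cell (all available when fewer).
#' @return a logical adjacency matrix.
#' @export
true_nearest_neighbors <- function(pos, k = 20) {
  if (inherits(pos, "embryo")) pos <- pos$pos
  pos <- as.matrix(pos)
  if (nrow(pos) < 2) stop("need at least two points")
  if (any(stats::dist(pos) < 1e-12)) stop("duplicate points")
  cpp_true_nn(pos, as.integer(k))
}

#' Count neighbours of a cell matching a lineage filter
#'
#' @param adj adjacency matrix from [neighbor_graph()] or
#'   [true_nearest_neighbors()].
#' @param lineage character vector of lineage names per cell (or an embryo,
#'   from which both adjacency rows and lineages are taken).
#' @param i cell index.
#' @param filter one of `"icm"` (EPI, PrE or undetermined), `"non_pre_icm"`
#'   (EPI or undetermined), `"epi"`, `"pre"`, `"te"`, `"high_fgf"`
#'   (EPI or undetermined), or `"any"`.
#' @return the number of neighbours matching the filter.
#' @export
count_lineage_neighbors <- function(adj, lineage, i,
                                    filter = c("icm", "non_pre_icm", "epi",
                                               "pre", "te", "high_fgf",
                                               "any")) {
  filter <- match.arg(filter)
  keep <- switch(filter,
    icm = lineage %in% c("EPI", "PRE", "UNDETERMINED_ICM"),
    non_pre_icm = lineage %in% c("EPI", "UNDETERMINED_ICM"),
    high_fgf = lineage %in% c("EPI", "UNDETERMINED_ICM"),
    epi = lineage == "EPI",
    pre = lineage == "PRE",
    te = lineage == "TE",
    any = rep(TRUE, length(lineage)))
  sum(adj[i, ] & keep)
}
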