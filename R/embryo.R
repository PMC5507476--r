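#' @useDynLib blastosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames sd var
#' @importFrom utils write.csv read.csv
NULL

# lineage codes shared with the C++ kernels
LINEAGES <- c(UNDETERMINED_ICM = 0L, TE = 1L, EPI = 2L, PRE = 3L)

lineage_name <- function(code) names(LINEAGES)[match(code, LINEAGES)]
lineage_code <- function(name) unname(LINEAGES[name])

#' Create an embryo
#'
#' An embryo is the collection of simulated circles/spheres plus the
#' simulation clock and state flags. Each biological TE cell is represented
#' by 2 circles; all other cells by 1. Positions are in units of the cell
#' radius.
#'
#' @param n_cells number of initial (undetermined) cells.
#' @param dim 2 or 3.
#' @param params a [model_params()] object.
#' @param rules a [rule_config()] object.
#' @param schedule a [stage_schedule()] object.
#' @return an object of class `embryo`.
#' @export
new_embryo <- function(n_cells = 1, dim = 2,
                       params = model_params(),
                       rules = rule_config(),
                       schedule = stage_schedule()) {
  stopifnot(dim %in% c(2, 3), n_cells >= 1)
  pos <- matrix(0, n_cells, dim)
  if (n_cells > 1) {
    # seed cells on a small ring/shell so no two coincide
    ang <- 2 * pi * seq_len(n_cells) / n_cells
    pos[, 1] <- 1.2 * cos(ang)
    pos[, 2] <- 1.2 * sin(ang)
    if (dim == 3) pos[, 3] <- 0.1 * seq_len(n_cells)
  }
  e <- list(
    pos = pos,
    lineage = rep(LINEAGES[["UNDETERMINED_ICM"]], n_cells),
    pol = matrix(0, n_cells, dim),
    te_pair = rep(NA_integer_, n_cells),
    id = seq_len(n_cells),
    next_id = n_cells + 1L,
    time = if (n_cells > 1) sum(1 / seq_len(n_cells - 1)) else 0,
    dim = dim,
    params = params,
    rules = rules,
    schedule = schedule,
    rule1_done = FALSE,
    rule3_done = FALSE,
    apoptosis_count = 0L,
    deep_pre_before_rule4 = NA_integer_)
  class(e) <- "embryo"
  e
}

n_circles <- function(embryo) nrow(embryo$pos)

# current adhesion mode for the force kernels
adhesion_mode <- function(embryo) {
  if (!embryo$rule3_done) return(0L)
  if (embryo$rules$rule3_mode == "neutralized") return(2L) else return(1L)
}

#' Biological cell counts and lineage fractions
#'
#' Each biological TE cell is simulated by 2 circles, so the biological TE
#' count is the number of TE circles divided by 2, rounded half up. The ICM
#' count is the number of epiblast, PrE and undetermined cells.
#'
#' @param embryo an [new_embryo()] object.
#' @return a list with per-lineage counts (`te`, `epi`, `pre`, `undet`,
#'   `icm`, `total`) and fractions (`icm_total`, `epi_icm`, `pre_icm`).
#' @export
biological_counts <- function(embryo) {
  if (n_circles(embryo) == 0) stop("empty embryo: no living cells")
  lin <- embryo$lineage
  te_circ <- sum(lin == LINEAGES[["TE"]])
  te <- floor(te_circ / 2 + 0.5)
  epi <- sum(lin == LINEAGES[["EPI"]])
  pre <- sum(lin == LINEAGES[["PRE"]])
  undet <- sum(lin == LINEAGES[["UNDETERMINED_ICM"]])
  icm <- epi + pre + undet
  total <- te + icm
  list(te = te, epi = epi, pre = pre, undet = undet, icm = icm,
       total = total,
       icm_total = if (total > 0) icm / total else NA_real_,
       epi_icm = if (icm > 0) (epi + undet) / icm else NA_real_,
       pre_icm = if (icm > 0) pre / icm else NA_real_)
}

#' Tabular snapshot of an embryo
#'
#' One row per circle: id, coordinates, lineage, polarity components,
#' TE pair link and the simulation time.
#'
#' @param embryo an embryo.
#' @return a data.frame.
#' @export
cells_df <- function(embryo) {
  d <- embryo$dim
  out <- data.frame(id = embryo$id,
                    x = embryo$pos[, 1],
                    y = embryo$pos[, 2])
  if (d == 3) out$z <- embryo$pos[, 3]
  out$lineage <- lineage_name(embryo$lineage)
  out$pol_x <- embryo$pol[, 1]
  out$pol_y <- embryo$pol[, 2]
  if (d == 3) out$pol_z <- embryo$pol[, 3]
  out$te_pair_id <- embryo$te_pair
  out$time <- embryo$time
  out
}

#' @export
print.embryo <- function(x, ...) {
  b <- biological_counts(x)
  cat(sprintf("<embryo> %dD, t = %.3f, %d circles\n", x$dim, x$time,
              n_circles(x)))
  cat(sprintf("  biological cells: %d (TE %d, EPI %d, PrE %d, undet %d)\n",
              b$total, b$te, b$epi, b$pre, b$undet))
  cat(sprintf("  rule1 %s, rule3 %s, apoptosis removed %d\n",
              if (x$rule1_done) "applied" else "pending",
              if (x$rule3_done) "applied" else "pending",
              x$apoptosis_count))
  invisible(x)
}

# internal: remove circles by index, keeping all vectors aligned
remove_circles <- function(embryo, idx) {
  if (length(idx) == 0) return(embryo)
  keep <- setdiff(seq_len(n_circles(embryo)), idx)
  embryo$pos <- embryo$pos[keep, , drop = FALSE]
  embryo$lineage <- embryo$lineage[keep]
  embryo$pol <- embryo$pol[keep, , drop = FALSE]
  embryo$te_pair <- embryo$te_pair[keep]
  embryo$id <- embryo$id[keep]
  embryo
}

# internal: append one circle
add_circle <- function(embryo, pos, lineage, pol = NULL, te_pair = NA_integer_) {
  embryo$pos <- rbind(embryo$pos, pos)
  embryo$lineage <- c(embryo$lineage, lineage)
  if (is.null(pol)) pol <- rep(0, embryo$dim)
  embryo$pol <- rbind(embryo$pol, pol)
  embryo$te_pair <- c(embryo$te_pair, te_pair)
  embryo$id <- c(embryo$id, embryo$next_id)
  embryo$next_id <- embryo$next_id + 1L
  embryo
}
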