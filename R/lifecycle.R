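#' Rule 1: develop polarity, if surface cell
#'
#' At the polarity stage the outer cells are identified by counting
#' neighbours: cells with fewer than `rule1_neighbor_threshold` neighbours
#' become trophectoderm and receive a polarity unit vector pointing radially
#' outwards from the cell-mass centroid; the remaining cells become
#' undetermined ICM. Because TE cells are about twice the size of the
#' others, each new TE cell is expanded to 2 unit circles (the twin is
#' placed along the local tangent and inherits the polarity), and TE
#' divisions thereafter run at twice the biological ICM rate. In the
#' polarity-deletion mode (`rules$rule1 = FALSE`) no polarity is assigned
#' and every cell keeps the default attraction factor.
#'
#' @param embryo an embryo at the polarity stage.
#' @return the embryo with lineages assigned (not yet relaxed).
#' @export
apply_rule1_polarity <- function(embryo) {
  if (n_circles(embryo) < 2) stop("rule 1 needs at least 2 cells")
  embryo$rule1_done <- TRUE
  if (!embryo$rules$rule1) return(embryo)   # polarity deletion: all stay ICM

  p <- embryo$params
  # surface cells by the scale-free halfway-point neighbour rule (a fixed
  # radius over-counts neighbours in the compressed pre-compaction packing)
  adj <- cpp_true_nn(embryo$pos, p$nn_k)
  thr <- if (embryo$dim == 2) p$rule1_neighbor_threshold else
    p$rule1_neighbor_threshold_3d
  counts <- rowSums(adj)
  outer_cells <- which(counts < thr)
  centroid <- colMeans(embryo$pos)

  for (i in outer_cells) {
    v <- embryo$pos[i, ] - centroid
    nv <- sqrt(sum(v^2))
    e <- if (nv > 1e-9) v / nv else c(1, rep(0, embryo$dim - 1))
    embryo$lineage[i] <- LINEAGES[["TE"]]
    embryo$pol[i, ] <- e
    embryo$te_pair[i] <- embryo$id[i]
  }
  # expand each TE cell to 2 circles adjacent along the local tangent
  if (embryo$dim == 2 && length(outer_cells) > 1) {
    # twins at the angular midpoints between consecutive TE mothers, so the
    # nascent ring is evenly loaded and expands rather than buckling
    rel <- sweep(embryo$pos[outer_cells, , drop = FALSE], 2, centroid)
    ang <- atan2(rel[, 2], rel[, 1])
    rad <- sqrt(rowSums(rel^2))
    ord <- order(ang)
    oc <- outer_cells[ord]; ang <- ang[ord]; rad <- rad[ord]
    k <- length(oc)
    for (q in seq_len(k)) {
      qn <- if (q == k) 1 else q + 1
      gap <- (ang[qn] - ang[q]) %% (2 * pi)
      amid <- ang[q] + gap / 2
      rmid <- (rad[q] + rad[qn]) / 2
      twin_pos <- centroid + rmid * c(cos(amid), sin(amid)) +
        rnorm(2, 0, p$division_jitter_sd)
      embryo <- add_circle(embryo, twin_pos, LINEAGES[["TE"]],
                           embryo$pol[oc[q], ], te_pair = embryo$te_pair[oc[q]])
    }
  } else {
    for (i in outer_cells) {
      e <- embryo$pol[i, ]
      if (embryo$dim == 2) {
        tangent <- c(-e[2], e[1])
      } else {
        ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        tangent <- c(e[2] * ref[3] - e[3] * ref[2],
                     e[3] * ref[1] - e[1] * ref[3],
                     e[1] * ref[2] - e[2] * ref[1])
        tangent <- tangent / sqrt(sum(tangent^2))
      }
      twin_pos <- embryo$pos[i, ] + tangent +
        rnorm(embryo$dim, 0, p$division_jitter_sd)
      embryo <- add_circle(embryo, twin_pos, LINEAGES[["TE"]], e,
                           te_pair = embryo$te_pair[i])
    }
  }
  embryo
}

#' Select the next cell to divide
#'
#' Uniform selection among circles. Each biological TE cell is two circles,
#' so uniform circle selection realises the 2-fold biological TE division
#' rate exactly; before polarity all cells are single circles and selection
#' is uniform over cells. Early in the fate-switching window the dividing
#' ICM cells are consequently the undetermined ones (they are all that
#' exists); once all have specified, a random epiblast/PrE cell divides.
#'
#' @param embryo an embryo.
#' @return the index of the dividing circle.
#' @export
select_divider <- function(embryo) {
  n <- n_circles(embryo)
  if (n == 0) stop("empty embryo")
  i <- sample.int(n, 1)
  if (rule2_active(embryo)) {
    # while unspecified ICM cells remain, ICM divisions are drawn from them
    # first (TE circles keep their weight, so the TE:ICM rate is unchanged)
    undet <- which(embryo$lineage == LINEAGES[["UNDETERMINED_ICM"]])
    det_icm <- embryo$lineage[i] %in% LINEAGES[c("EPI", "PRE")]
    if (det_icm && length(undet) > 0)
      i <- undet[sample.int(length(undet), 1)]
  }
  i
}

# nearest neighbour (any lineage) of circle i
nearest_neighbor_of <- function(embryo, i) {
  d2 <- rowSums(sweep(embryo$pos, 2, embryo$pos[i, ])^2)
  d2[i] <- Inf
  which.min(d2)
}

#' Divide a cell
#'
#' The daughter circle is inserted at the midpoint between the mother and
#' its nearest neighbour (with a small jitter to break exact overlap); in 3D
#' it is placed at the centre of the mother's 3 nearest neighbours, which is
#' closer to the minimal-energy configuration. Daughters inherit the
#' mother's fate and, for TE, the polarity orientation. The caller is
#' responsible for relaxing afterwards.
#'
#' @param embryo an embryo.
#' @param i index of the dividing circle.
#' @return list with the updated `embryo` and the `daughter` index.
#' @export
divide_cell <- function(embryo, i) {
  n <- n_circles(embryo)
  p <- embryo$params
  if (n == 1) {
    newpos <- embryo$pos[1, ] + c(2, rep(0, embryo$dim - 1)) +
      rnorm(embryo$dim, 0, p$division_jitter_sd)
  } else if (embryo$dim == 3 && n >= 4) {
    d2 <- rowSums(sweep(embryo$pos, 2, embryo$pos[i, ])^2)
    d2[i] <- Inf
    nn3 <- order(d2)[1:3]
    newpos <- colMeans(embryo$pos[nn3, , drop = FALSE]) +
      rnorm(embryo$dim, 0, p$division_jitter_sd)
  } else {
    j <- nearest_neighbor_of(embryo, i)
    newpos <- (embryo$pos[i, ] + embryo$pos[j, ]) / 2 +
      rnorm(embryo$dim, 0, p$division_jitter_sd)
  }
  lin <- embryo$lineage[i]
  pol <- if (lin == LINEAGES[["TE"]]) embryo$pol[i, ] else NULL
  embryo <- add_circle(embryo, newpos, lin, pol, te_pair = NA_integer_)
  list(embryo = embryo, daughter = n_circles(embryo))
}

# is the fate-switching rule live at the current time? (needs defined ICM,
# i.e. rule 1 must have fired, and the FGF window to be open)
rule2_active <- function(embryo) {
  mode <- embryo$rules$rule2_mode
  if (mode == "off") return(FALSE)
  embryo$rule1_done && embryo$time >= embryo$schedule$rule2_start - 1e-12
}

#' Rule-2 conversion probability of a cell
#'
#' The probability that an ICM cell converts to PrE at division: the
#' weighted fraction of high-FGF4 cells (epiblast weight 1, undetermined ICM
#' weight `fgf_undetermined_weight`, PrE weight 0) among its ICM contact
#' neighbours (halfway-point nearest neighbours; FGF4 is short-ranged). With
#' no ICM neighbours the cell adopts epiblast (probability 0).
#'
#' @param embryo an embryo.
#' @param i circle index (ICM lineage).
#' @param exclude optional indices excluded from the neighbourhood (e.g. a
#'   just-inserted daughter).
#' @return the probability of converting to PrE.
#' @export
rule2_probability <- function(embryo, i, exclude = integer()) {
  p <- embryo$params
  adj <- rule_neighbor_adj(embryo, exclude = exclude)
  nb <- which(adj[i, ])
  lin <- embryo$lineage[nb]
  n_epi <- sum(lin == LINEAGES[["EPI"]])
  n_undet <- sum(lin == LINEAGES[["UNDETERMINED_ICM"]])
  n_pre <- sum(lin == LINEAGES[["PRE"]])
  w <- p$fgf_undetermined_weight
  H <- n_epi + w * n_undet
  N <- n_epi + w * n_undet + n_pre
  if (N == 0) return(0)
  H / N
}

#' Rule 2: switch fate, if surrounded by too many cells of the same type
#'
#' Applied at ICM divisions while the FGF window is open: one conversion
#' probability is computed from the mother's neighbourhood and applied
#' independently to mother and daughter (PrE with that probability,
#' epiblast otherwise). The perturbation modes force epiblast (`no_fgf`),
#' force PrE (`excess_fgf`), leave the rule inert — cells stay undetermined,
#' i.e. unresolved — until the delayed onset (`delayed`, paired with a
#' schedule `fgf_delay`), or leave cells undetermined for good (`off`).
#'
#' @param embryo an embryo (daughter already inserted).
#' @param mother,daughter circle indices.
#' @return the embryo with fates updated.
#' @export
apply_rule2_fate <- function(embryo, mother, daughter) {
  if (embryo$lineage[mother] == LINEAGES[["TE"]]) return(embryo)
  if (!rule2_active(embryo)) return(embryo)
  mode <- embryo$rules$rule2_mode
  if (mode == "delayed") mode <- "normal"  # inert until the delayed onset
  set_fate <- function(e, idx, code) { e$lineage[idx] <- code; e }
  epi <- LINEAGES[["EPI"]]; pre <- LINEAGES[["PRE"]]
  if (mode == "no_fgf") {
    embryo <- set_fate(embryo, mother, epi)
    embryo <- set_fate(embryo, daughter, epi)
  } else if (mode == "excess_fgf") {
    embryo <- set_fate(embryo, mother, pre)
    embryo <- set_fate(embryo, daughter, pre)
  } else { # normal (or delayed past its onset)
    pr <- rule2_probability(embryo, mother, exclude = daughter)
    embryo <- set_fate(embryo, mother, if (runif(1) < pr) pre else epi)
    embryo <- set_fate(embryo, daughter, if (runif(1) < pr) pre else epi)
  }
  embryo
}

#' Rule 3: less adhesion, if PrE progenitor
#'
#' Flags differential adhesion as active: from here on the attraction
#' factor of every pair involving a PrE cell is `S_pre`. In the neutralized
#' mode all ICM-ICM pairs get `S_neutral_adhesion` instead (TE contacts keep
#' the default factor).
#'
#' @param embryo an embryo at the differential-adhesion stage.
#' @return the embryo.
#' @export
apply_rule3_adhesion <- function(embryo) {
  embryo$rule3_done <- TRUE
  embryo
}

# contact neighbourhood used by the developmental rules: halfway-point true
# nearest neighbours (scale-free, robust to the compressed packing), capped
# at the interaction range
rule_neighbor_adj <- function(embryo, exclude = integer()) {
  n <- n_circles(embryo)
  keep <- setdiff(seq_len(n), exclude)
  adj_sub <- cpp_true_nn(embryo$pos[keep, , drop = FALSE],
                         embryo$params$nn_k)
  dm <- as.matrix(stats::dist(embryo$pos[keep, , drop = FALSE]))
  adj_sub <- adj_sub & dm <= embryo$params$global_cutoff
  adj <- matrix(FALSE, n, n)
  adj[keep, keep] <- adj_sub
  adj
}

# indices of PrE circles in the "deep" position: more than `thr` non-PrE ICM
# contact neighbours (TE neighbours are not counted)
deep_pre_cells <- function(embryo) {
  p <- embryo$params
  pre <- which(embryo$lineage == LINEAGES[["PRE"]])
  if (length(pre) == 0) return(integer())
  adj <- rule_neighbor_adj(embryo)
  nonpre_icm <- embryo$lineage %in% LINEAGES[c("EPI", "UNDETERMINED_ICM")]
  deep <- vapply(pre, function(i) {
    sum(adj[i, ] & nonpre_icm) > p$apoptosis_nonpre_neighbor_threshold
  }, logical(1))
  pre[deep]
}

#' Rule 4: die, if in a wrong position
#'
#' At the endpoint every PrE cell surrounded by more than
#' `apoptosis_nonpre_neighbor_threshold` non-PrE ICM cells (a PrE progenitor
#' trapped in the epiblast core) is removed. If `epi_apoptosis_fraction` is
#' positive, that fraction of epiblast cells is additionally removed at
#' random. The caller is responsible for relaxing afterwards.
#'
#' @param embryo an embryo at the endpoint stage.
#' @return the embryo, with `apoptosis_count` updated.
#' @export
apply_rule4_apoptosis <- function(embryo) {
  victims <- deep_pre_cells(embryo)
  frac <- embryo$params$epi_apoptosis_fraction
  if (frac > 0) {
    epi <- which(embryo$lineage == LINEAGES[["EPI"]])
    n_extra <- round(frac * length(epi))
    if (n_extra > 0)
      victims <- union(victims, sample(epi, n_extra))
  }
  embryo$apoptosis_count <- embryo$apoptosis_count + length(victims)
  remove_circles(embryo, victims)
}
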