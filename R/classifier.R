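#' Classify a blastocyst endpoint
#'
#' A successful blastocyst must satisfy four criteria: (i) the TE circles
#' form one connected ring (2D; shell in 3D) enclosing all ICM cells;
#' (ii) a cavity — an interior region void of cells, at least
#' `cavity_min_area` cell cross-sections in size — exists with the ICM on
#' one side of it; (iii) the PrE lies between the cavity and the epiblast,
#' operationalised as every straight path from an epiblast cell to the
#' cavity centre passing within `seal_distance` of a PrE cell; (iv) no
#' epiblast cell sits inside the PrE layer and no PrE cell deep inside the
#' epiblast core. Double PrE layers count as success as long as they seal
#' the epiblast. Undetermined ICM cells remaining at the endpoint are
#' counted as epiblast.
#'
#' Failures map to five categories: `EPI_ONLY` / `PRE_ONLY` (single-lineage
#' ICM — the defining readout of the FGF-modulation mutants, assigned
#' first), `NO_TE` (no closed TE ring or no cavity), `EPI_IN_PRE_ERROR`
#' (epiblast exposed to the cavity through a defective PrE layer, or
#' embedded among PrE), and `PRE_IN_EPI_ERROR` (a PrE progenitor trapped in
#' the epiblast core). The categories are checked in that order, so every
#' endpoint maps to exactly one.
#'
#' @param embryo an endpoint embryo.
#' @return a list of class `blastosim_outcome`: `category`, biological
#'   `counts`, `fractions`, `apoptosis_count` and geometric `diagnostics`.
#' @export
classify <- function(embryo) {
  if (n_circles(embryo) == 0) stop("cannot classify an empty embryo")
  b <- biological_counts(embryo)
  p <- embryo$params
  diag <- endpoint_diagnostics(embryo)

  if (embryo$dim == 3) {
    # qualitative in 3D: neighbour-count thresholds are calibrated for the
    # planar geometry, so only shell, cavity, composition and seal decide
    diag$misplaced_pre_in_epi <- 0L
    diag$misplaced_epi_in_pre <- 0L
  }

  icm_n <- b$icm
  category <- if (icm_n > 0 && b$pre == 0) {
    "EPI_ONLY"
  } else if (icm_n > 0 && b$epi + b$undet == 0) {
    "PRE_ONLY"
  } else if (!diag$te_shell_intact || !diag$cavity_present ||
             !diag$icm_one_sided) {
    "NO_TE"
  } else if (diag$misplaced_pre_in_epi > 0) {
    "PRE_IN_EPI_ERROR"
  } else if (!diag$pre_layer_seals_epi || diag$misplaced_epi_in_pre > 0) {
    "EPI_IN_PRE_ERROR"
  } else {
    "SUCCESS"
  }

  out <- list(category = category,
              counts = b[c("te", "epi", "pre", "undet", "icm", "total")],
              fractions = b[c("icm_total", "epi_icm", "pre_icm")],
              apoptosis_count = embryo$apoptosis_count,
              diagnostics = diag)
  class(out) <- "blastosim_outcome"
  out
}

#' @export
print.blastosim_outcome <- function(x, ...) {
  cat(sprintf("<outcome> %s | total %d (TE %d, EPI %d, PrE %d)\n",
              x$category, x$counts$total, x$counts$te, x$counts$epi,
              x$counts$pre))
  cat(sprintf("  ICM/total %.2f, EPI/ICM %.2f, apoptosis %d\n",
              x$fractions$icm_total, x$fractions$epi_icm,
              x$apoptosis_count))
  invisible(x)
}

# geometric endpoint diagnostics shared by 2D and 3D classification
endpoint_diagnostics <- function(embryo) {
  p <- embryo$params
  te <- which(embryo$lineage == LINEAGES[["TE"]])
  icm <- which(embryo$lineage != LINEAGES[["TE"]])

  diag <- list(te_shell_intact = FALSE, cavity_present = FALSE,
               icm_one_sided = FALSE, pre_layer_seals_epi = TRUE,
               misplaced_epi_in_pre = 0L, misplaced_pre_in_epi = 0L,
               cavity_center = NULL, cavity_radius = NA_real_)

  if (length(te) < 3) return(diag)

  # (i) one connected TE shell at contact distance
  te_pos <- embryo$pos[te, , drop = FALSE]
  adj <- neighbor_graph(te_pos, p$te_te_cutoff)
  if (n_components(adj) != 1) return(diag)

  if (embryo$dim == 2) {
    # ring as the polygon of TE circles ordered by angle about their centroid
    ctr <- colMeans(te_pos)
    ord <- order(atan2(te_pos[, 2] - ctr[2], te_pos[, 1] - ctr[1]))
    poly <- te_pos[ord, , drop = FALSE]
    # closure: consecutive circles along the ring (wrap included) in contact
    gaps <- sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), , drop = FALSE])^2))
    if (max(gaps) > p$te_te_cutoff) return(diag)
    icm_pos <- embryo$pos[icm, , drop = FALSE]
    if (length(icm) > 0) {
      inside <- points_in_polygon(icm_pos, poly)
      if (!all(inside)) return(diag)
    }
    diag$te_shell_intact <- TRUE

    # (ii) largest empty disc inside the ring (grid at 0.5-radius resolution)
    cav <- largest_empty_disc(embryo$pos, poly, resolution = 0.5)
    diag$cavity_center <- cav$center
    diag$cavity_radius <- cav$radius
    if (is.na(cav$radius) ||
        pi * cav$radius^2 < p$cavity_min_area * pi) return(diag)
    diag$cavity_present <- TRUE
    icm_ctr <- if (length(icm) > 0) colMeans(icm_pos) else ctr
    diag$icm_one_sided <-
      sqrt(sum((cav$center - icm_ctr)^2)) >= p$cavity_offset_min
  } else {
    # 3D: qualitative shell test — every ICM cell lies radially inside the
    # TE along its own direction from the embryo centroid
    ctr <- colMeans(embryo$pos)
    diag$te_shell_intact <- TRUE
    if (length(icm) > 0) {
      for (q in icm) {
        v <- embryo$pos[q, ] - ctr
        r_icm <- sqrt(sum(v^2))
        if (r_icm < 1e-9) next
        u <- v / r_icm
        proj <- as.vector((te_pos - matrix(ctr, nrow(te_pos), 3,
                                           byrow = TRUE)) %*% u)
        ang_ok <- proj > 0.5 * r_icm
        if (!any(ang_ok) || max(proj[ang_ok]) < r_icm - 1) {
          diag$te_shell_intact <- FALSE
          break
        }
      }
    }
    if (!diag$te_shell_intact) return(diag)
    cav <- largest_empty_ball_3d(embryo$pos, resolution = 1)
    diag$cavity_center <- cav$center
    diag$cavity_radius <- cav$radius
    if (is.na(cav$radius) || cav$radius < sqrt(p$cavity_min_area))
      return(diag)
    diag$cavity_present <- TRUE
    icm_ctr <- if (length(icm) > 0)
      colMeans(embryo$pos[icm, , drop = FALSE]) else ctr
    diag$icm_one_sided <-
      sqrt(sum((cav$center - icm_ctr)^2)) >= p$cavity_offset_min
  }

  # (iii)/(iv) layer diagnostics
  diag$misplaced_pre_in_epi <- length(deep_pre_cells(embryo))
  epi_like <- which(embryo$lineage %in%
                      LINEAGES[c("EPI", "UNDETERMINED_ICM")])
  pre <- which(embryo$lineage == LINEAGES[["PRE"]])

  # epiblast embedded among PrE: more than the apoptosis threshold of PrE
  # neighbours among its contact neighbours
  if (length(epi_like) > 0 && length(pre) > 0) {
    adj_all <- rule_neighbor_adj(embryo)
    is_pre <- embryo$lineage == LINEAGES[["PRE"]]
    n_emb <- sum(vapply(epi_like, function(i)
      sum(adj_all[i, ] & is_pre) > p$apoptosis_nonpre_neighbor_threshold,
      logical(1)))
    diag$misplaced_epi_in_pre <- n_emb
  }

  # seal test: every epiblast-to-cavity path passes near a PrE cell. On a 3D
  # shell the largest hole of a close-packed monolayer sits at a triangle
  # circumcentre, so the qualitative 3D test uses 1.5x the planar distance.
  seal_dist <- p$seal_distance * if (embryo$dim == 3) 1.5 else 1
  if (!is.null(diag$cavity_center) && diag$cavity_present &&
      length(epi_like) > 0) {
    if (length(pre) == 0) {
      diag$pre_layer_seals_epi <- FALSE
    } else {
      pre_pos <- embryo$pos[pre, , drop = FALSE]
      sealed <- vapply(epi_like, function(i) {
        dmin <- min(segment_point_distance(embryo$pos[i, ],
                                           diag$cavity_center, pre_pos))
        dmin <= seal_dist
      }, logical(1))
      diag$pre_layer_seals_epi <- all(sealed)
    }
  }
  diag
}

# number of connected components of a logical adjacency matrix
n_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  cur
}

# even-odd point-in-polygon test, vectorised over points
points_in_polygon <- function(points, poly) {
  points <- matrix(points, ncol = 2)
  nx <- nrow(poly)
  inside <- rep(FALSE, nrow(points))
  j <- nx
  for (i in seq_len(nx)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > points[, 2]) != (yj > points[, 2])) &
      (points[, 1] < (xj - xi) * (points[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# largest disc empty of cells inside a polygon, by grid rasterisation
largest_empty_disc <- function(pos, poly, resolution = 0.5) {
  rng_x <- range(poly[, 1]); rng_y <- range(poly[, 2])
  gx <- seq(rng_x[1], rng_x[2], by = resolution)
  gy <- seq(rng_y[1], rng_y[2], by = resolution)
  if (length(gx) < 2 || length(gy) < 2)
    return(list(center = NULL, radius = NA_real_))
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- points_in_polygon(grid, poly)
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0) return(list(center = NULL, radius = NA_real_))
  # distance from each grid point to the nearest cell surface
  dmin <- sqrt(pmax(rowmin_cross_dist2(grid, pos), 0)) - 1
  best <- which.max(dmin)
  list(center = grid[best, ], radius = max(dmin[best], 0))
}

# row-wise minimum squared distance from each row of a to the rows of b
rowmin_cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  out <- d2[, 1]
  if (ncol(d2) > 1)
    for (j in 2:ncol(d2)) out <- pmin(out, d2[, j])
  out
}

# largest cell-free ball inside the convex region spanned by the cells (3D)
largest_empty_ball_3d <- function(pos, resolution = 1) {
  rng <- apply(pos, 2, range)
  gx <- seq(rng[1, 1], rng[2, 1], by = resolution)
  gy <- seq(rng[1, 2], rng[2, 2], by = resolution)
  gz <- seq(rng[1, 3], rng[2, 3], by = resolution)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  ctr <- colMeans(pos)
  rmax <- max(sqrt(rowSums(sweep(pos, 2, ctr)^2)))
  inside <- sqrt(rowSums(sweep(grid, 2, ctr)^2)) < rmax - 1
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0) return(list(center = NULL, radius = NA_real_))
  dmin <- sqrt(pmax(rowmin_cross_dist2(grid, pos), 0)) - 1
  best <- which.max(dmin)
  list(center = grid[best, ], radius = max(dmin[best], 0))
}

# minimum distances from points to the segment [a, b]
segment_point_distance <- function(a, b, points) {
  points <- matrix(points, ncol = length(a))
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) return(sqrt(rowSums(sweep(points, 2, a)^2)))
  t <- pmin(pmax(as.vector(sweep(points, 2, a) %*% ab) / len2, 0), 1)
  proj <- outer(t, ab) + matrix(a, nrow(points), length(a), byrow = TRUE)
  sqrt(rowSums((points - proj)^2))
}

#' Ensemble summary statistics
#'
#' @param outcomes a list of outcomes from [classify()], or a
#'   `blastosim_ensemble` data frame from [run_ensemble()].
#' @return a list with per-category fractions and mean/sd of the total cell
#'   count, lineage fractions and apoptosis counts.
#' @export
ensemble_stats <- function(outcomes) {
  if (inherits(outcomes, "blastosim_ensemble")) {
    df <- outcomes
  } else {
    stopifnot(length(outcomes) >= 1)
    df <- do.call(rbind, lapply(outcomes, function(o)
      data.frame(category = o$category, total = o$counts$total,
                 icm_total = o$fractions$icm_total,
                 epi_icm = o$fractions$epi_icm,
                 pre_icm = o$fractions$pre_icm,
                 apoptosis = o$apoptosis_count)))
  }
  cats <- c("SUCCESS", "NO_TE", "EPI_ONLY", "PRE_ONLY",
            "EPI_IN_PRE_ERROR", "PRE_IN_EPI_ERROR")
  frac <- vapply(cats, function(cc) mean(df$category == cc), numeric(1))
  list(n = nrow(df),
       category_fractions = frac,
       success_rate = unname(frac["SUCCESS"]),
       total_mean = mean(df$total), total_sd = sd(df$total),
       icm_total_mean = mean(df$icm_total, na.rm = TRUE),
       icm_total_sd = sd(df$icm_total, na.rm = TRUE),
       epi_icm_mean = mean(df$epi_icm, na.rm = TRUE),
       epi_icm_sd = sd(df$epi_icm, na.rm = TRUE),
       pre_icm_mean = mean(df$pre_icm, na.rm = TRUE),
       pre_icm_sd = sd(df$pre_icm, na.rm = TRUE),
       apoptosis_mean = mean(df$apoptosis))
}

#' Convert cell counts between 2D and 3D
#'
#' Surface (TE) cells follow \eqn{N_{2D} = \sqrt{\pi N_{3D}}}; bulk
#' (EPI/PrE/ICM) cells follow
#' \eqn{N_{2D} = (\tfrac{3}{4} N_{3D} \sqrt{\pi})^{2/3}}.
#'
#' @param n cell count (nonnegative; vectorised).
#' @param type `"te"` for surface cells, `"bulk"` for interior lineages.
#' @return the corresponding count in the other dimensionality.
#' @export
scale_3d_to_2d <- function(n, type = c("te", "bulk")) {
  type <- match.arg(type)
  if (any(n < 0)) stop("counts must be nonnegative")
  if (type == "te") sqrt(pi * n) else (0.75 * n * sqrt(pi))^(2 / 3)
}

#' @rdname scale_3d_to_2d
#' @export
scale_2d_to_3d <- function(n, type = c("te", "bulk")) {
  type <- match.arg(type)
  if (any(n < 0)) stop("counts must be nonnegative")
  if (type == "te") n^2 / pi else n^(3 / 2) * 4 / (3 * sqrt(pi))
}
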