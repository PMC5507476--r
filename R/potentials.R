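#' Pairwise interaction potential
#'
#' \deqn{V(d) = e^{-d} - S e^{-d/\beta}}
#' repulsive below the equilibrium distance and attractive beyond it. With
#' cells of unit radius, two cells closer than one diameter (d < 2) repel.
#'
#' @param d centre-to-centre distance (cell radii), positive.
#' @param S attraction factor.
#' @param beta range parameter (> 1).
#' @return potential energy (vectorised over `d`).
#' @export
pair_potential <- function(d, S = 0.6, beta = 5) {
  if (any(d <= 0)) stop("overlapping cells: distance must be positive")
  exp(-d) - S * exp(-d / beta)
}

#' Derivative of the pair potential with respect to distance
#' @inheritParams pair_potential
#' @return dV/dd.
#' @export
pair_potential_deriv <- function(d, S = 0.6, beta = 5) {
  -exp(-d) + (S / beta) * exp(-d / beta)
}

#' Equilibrium distance of the pair potential
#'
#' Closed-form root of dV/dd = 0: `log(beta / S) / (1 - 1/beta)`.
#'
#' @inheritParams pair_potential
#' @return the distance at which the pairwise force vanishes.
#' @export
equilibrium_distance <- function(S = 0.6, beta = 5) {
  log(beta / S) / (1 - 1 / beta)
}

#' Polarity-dependent attraction factor for TE-TE pairs
#'
#' \deqn{S = -1.4\,(\hat e_1 \times \hat r_{12}) \cdot (\hat e_2 \times \hat r_{21})}
#' where the `e` are polarity unit vectors and `r12` the unit separation
#' vector from cell 1 to cell 2 (`r21 = -r12`). In 2D the cross products are
#' the scalar z-components. The factor is maximal (+prefactor) for parallel
#' polarities perpendicular to the separation, zero when a polarity is
#' parallel to the separation, and negative (net repulsion) for antiparallel
#' polarities.
#'
#' @param e1,e2 polarity unit vectors (length 2 or 3).
#' @param r12 unit vector from cell 1 to cell 2.
#' @param prefactor polar prefactor (default 1.4).
#' @return the attraction factor.
#' @export
polar_attraction_factor <- function(e1, e2, r12, prefactor = 1.4) {
  stopifnot(length(e1) == length(e2), length(e1) == length(r12),
            length(e1) %in% c(2, 3))
  for (v in list(e1, e2, r12))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
      stop("polar_attraction_factor expects unit vectors")
  cross <- function(a, b) {
    if (length(a) == 2) a[1] * b[2] - a[2] * b[1]
    else c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  }
  r21 <- -r12
  -prefactor * sum(cross(e1, r12) * cross(e2, r21))
}

#' Effective attraction factor and interaction range of a cell pair
#'
#' Applies the lineage rules: TE-TE pairs use the polar factor and interact
#' only below the TE-TE cutoff; TE-ICM pairs interact within the TE-ICM
#' range with `S` reduced for PrE once differential adhesion is active;
#' ICM-ICM pairs use the default factor (reduced for any pair involving PrE
#' after differential adhesion, or the neutral value in the neutralized
#' mode) with the global truncation unless `icm_global_potential` is set.
#'
#' @param embryo an embryo.
#' @param i,j circle indices.
#' @return list with `S`, `d` and `in_range`.
#' @export
effective_s <- function(embryo, i, j) {
  p <- embryo$params
  mode <- adhesion_mode(embryo)
  li <- embryo$lineage[i]; lj <- embryo$lineage[j]
  r <- embryo$pos[j, ] - embryo$pos[i, ]
  d <- sqrt(sum(r^2))
  te <- LINEAGES[["TE"]]; pre <- LINEAGES[["PRE"]]
  if (li == te && lj == te) {
    S <- polar_attraction_factor(embryo$pol[i, ], embryo$pol[j, ], r / d,
                                 p$polar_prefactor)
    in_range <- d < p$te_te_cutoff
    if (embryo$dim == 3 && in_range) {
      adj <- cpp_true_nn(embryo$pos, p$nn_k)
      in_range <- adj[i, j]
    }
  } else if (li == te || lj == te) {
    S <- if (mode == 1L && (li == pre || lj == pre)) p$S_pre else p$S_default
    in_range <- d <= p$te_icm_cutoff
  } else {
    S <- switch(as.character(mode),
                "0" = p$S_default,
                "1" = if (li == pre || lj == pre) p$S_pre else p$S_default,
                "2" = p$S_neutral_adhesion)
    in_range <- p$icm_global_potential || d <= p$global_cutoff
  }
  list(S = S, d = d, in_range = in_range)
}

#' Total force on every circle
#'
#' Sum of the negative gradients of the pair potential over all in-range
#' pairs. For TE-TE pairs the gradient includes the dependence of the polar
#' attraction factor on the separation direction, so the force is the exact
#' gradient of the total potential energy at fixed polarities.
#'
#' @param embryo an embryo.
#' @return a matrix (circles x dimension) of force vectors.
#' @export
total_force <- function(embryo) {
  cpp_forces(embryo$pos, embryo$lineage, embryo$pol,
             cpp_param_list(embryo$params, adhesion_mode(embryo)),
             embryo$params$nn_k)
}

#' Total potential energy
#' @param embryo an embryo.
#' @return the summed pair energies over in-range pairs.
#' @export
total_energy <- function(embryo) {
  cpp_energy(embryo$pos, embryo$lineage, embryo$pol,
             cpp_param_list(embryo$params, adhesion_mode(embryo)),
             embryo$params$nn_k)
}
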