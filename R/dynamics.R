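#' Relax an embryo towards mechanical equilibrium
#'
#' Interleaved overdamped Euler steps of positions,
#' \deqn{x \leftarrow x + \Delta t\,(-\partial V/\partial x) + \eta,}
#' and of TE polarity vectors under the damped alignment dynamics of the
#' pairwise polarity potential \eqn{V_p = -\cos\theta_{ij}} (prefactor 0.1),
#' with additive Gaussian noise per step. Integration stops early once the
#' largest deterministic displacement per step falls below the convergence
#' tolerance.
#'
#' @param embryo an embryo.
#' @param n_steps cap on the number of steps (default
#'   `params$relax_max_steps`).
#' @param noise include the noise terms?
#' @param min_steps minimum steps before early exit is allowed.
#' @return the embryo, with attributes `relax_steps` (steps taken) and
#'   `max_force` (largest force magnitude at the final step) attached.
#' @export
relax <- function(embryo, n_steps = NULL, noise = TRUE, min_steps = NULL) {
  p <- embryo$params
  if (is.null(n_steps)) n_steps <- p$relax_max_steps
  if (n_steps == 0) return(embryo)
  if (is.null(min_steps)) min_steps <- min(p$relax_min_steps, n_steps)
  res <- cpp_relax(embryo$pos, embryo$lineage, embryo$pol,
                   cpp_param_list(p, adhesion_mode(embryo)),
                   as.integer(n_steps), as.integer(min_steps),
                   p$conv_tol, noise, TRUE, TRUE, 2L, p$nn_k)
  if (!is.finite(res$max_force))
    stop("numerical instability: non-finite forces during relaxation")
  embryo$pos <- res$pos
  embryo$pol <- res$pol
  attr(embryo, "relax_steps") <- res$steps
  attr(embryo, "max_force") <- res$max_force
  embryo
}

#' Single position update
#'
#' One Euler step of the positions only (polarities frozen). Mainly useful
#' for inspecting the dynamics; [relax()] is the workhorse.
#'
#' @inheritParams relax
#' @param n_steps number of steps.
#' @return the embryo.
#' @export
step_positions <- function(embryo, n_steps = 1, noise = TRUE) {
  p <- embryo$params
  res <- cpp_relax(embryo$pos, embryo$lineage, embryo$pol,
                   cpp_param_list(p, adhesion_mode(embryo)),
                   as.integer(n_steps), as.integer(n_steps),
                   0, noise, TRUE, FALSE, 2L, p$nn_k)
  embryo$pos <- res$pos
  embryo
}

#' Single polarity update
#'
#' One (or more) alignment steps of the TE polarity vectors only.
#'
#' @inheritParams step_positions
#' @return the embryo.
#' @export
step_polarities <- function(embryo, n_steps = 1, noise = TRUE) {
  p <- embryo$params
  res <- cpp_relax(embryo$pos, embryo$lineage, embryo$pol,
                   cpp_param_list(p, adhesion_mode(embryo)),
                   as.integer(n_steps), as.integer(n_steps),
                   0, noise, FALSE, TRUE, 2L, p$nn_k)
  embryo$pol <- res$pol
  embryo
}

#' Polarity angles of TE cells (2D)
#'
#' @param embryo a 2D embryo.
#' @return numeric vector of angles `atan2(pol_y, pol_x)` (NA for non-TE).
#' @export
polarity_angles <- function(embryo) {
  stopifnot(embryo$dim == 2)
  ang <- atan2(embryo$pol[, 2], embryo$pol[, 1])
  ang[embryo$lineage != LINEAGES[["TE"]]] <- NA_real_
  ang
}
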