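#' Model parameters
#'
#' Numeric constants of the interaction potential, the integrator and the
#' rules. Cells are unit circles (2D) or unit spheres (3D), so all distances
#' are in cell radii. The pairwise potential is
#' \deqn{V(d) = e^{-d} - S e^{-d/\beta}}
#' with attraction factor `S` and range parameter `beta`; for TE-TE pairs
#' `S` is replaced by the polarity-dependent factor (see
#' [polar_attraction_factor()]).
#'
#' @param S_default attraction factor for ordinary cell pairs (dimensionless).
#' @param S_pre attraction factor for any pair involving a primitive-endoderm
#'   (PrE) cell once differential adhesion is active.
#' @param S_neutral_adhesion attraction factor applied to all ICM-ICM pairs in
#'   the neutralized-adhesion mode (rule-3 deletion).
#' @param beta range parameter of the attraction term; larger values give a
#'   longer-ranged attraction.
#' @param polar_prefactor prefactor of the polar attraction factor for TE-TE
#'   pairs; 1.4 keeps the TE sheet tightly packed but intact.
#' @param global_cutoff distance (cell radii) beyond which the potential is
#'   truncated to zero for non-TE pairs.
#' @param te_te_cutoff TE cells only interact with other TE cells closer than
#'   this distance.
#' @param te_icm_cutoff range of the TE-ICM potential.
#' @param noise_sd_position standard deviation of the additive positional
#'   noise, per coordinate per time step.
#' @param noise_sd_angle standard deviation of the polarity noise per step
#'   (the positional value multiplied by pi).
#' @param polarity_mobility damping prefactor of the polarity alignment
#'   dynamics; below 1 so polarities change slower than positions.
#' @param dt Euler step size.
#' @param relax_max_steps cap on integration steps in one relaxation phase.
#' @param relax_min_steps minimum steps before convergence may stop a
#'   relaxation.
#' @param conv_tol relaxation stops early once the largest deterministic
#'   displacement per step (`dt * max|F|`) falls below this value.
#' @param rule_radius radius (cell radii) for distance-threshold neighbour
#'   graphs ([neighbor_graph()] diagnostics). The developmental rules count
#'   contact neighbours with the scale-free halfway-point rule instead,
#'   capped at `global_cutoff`.
#' @param rule1_neighbor_threshold cells with fewer than this many neighbours
#'   at the polarity stage become TE (2D default 5).
#' @param rule1_neighbor_threshold_3d the corresponding threshold in 3D,
#'   where interior cells have more contacts.
#' @param te_division_rate_multiplier division rate of a biological TE cell
#'   relative to an ICM cell. The value 2 is realised exactly by selecting
#'   uniformly among circles, because each TE cell is simulated by 2 circles.
#' @param apoptosis_nonpre_neighbor_threshold a PrE cell with more than this
#'   many non-PrE ICM neighbours at the endpoint undergoes apoptosis.
#' @param fgf_undetermined_weight FGF4 contribution of an undetermined ICM
#'   cell relative to an epiblast cell (1 in the base model, 0.5 in the
#'   reduced-FGF4 variant).
#' @param epi_apoptosis_fraction fraction of epiblast cells additionally
#'   removed at the endpoint (0 in the base model, 0.2 in the
#'   epiblast-apoptosis variant).
#' @param icm_global_potential if `TRUE` (default), ICM-ICM pairs interact
#'   without a distance cutoff ("global potential", as if by protrusions),
#'   which keeps the ICM one coherent cluster as the blastocyst expands;
#'   `FALSE` applies the `global_cutoff` truncation to ICM-ICM pairs too.
#' @param division_jitter_sd standard deviation of the positional jitter
#'   applied to a newly inserted daughter cell.
#' @param nn_k number of closest candidates examined by the halfway-point
#'   nearest-neighbour rule in 3D.
#' @param seal_distance classifier threshold: a straight path from an
#'   epiblast cell to the cavity centre counts as sealed when it passes
#'   within this distance (one cell radius) of a PrE cell.
#' @param cavity_min_area minimum empty-disc area (in units of the cell
#'   cross-section, pi r^2) required to call a cavity.
#' @param cavity_offset_min minimal distance between the cavity centre and
#'   the ICM centroid for the ICM to count as one-sided.
#'
#' @return an object of class `model_params` (a validated list).
#' @export
model_params <- function(S_default = 0.6,
                         S_pre = 0.4,
                         S_neutral_adhesion = 0.5,
                         beta = 5,
                         polar_prefactor = 1.4,
                         global_cutoff = 5,
                         te_te_cutoff = 2.5,
                         te_icm_cutoff = 5,
                         noise_sd_position = 1e-3,
                         noise_sd_angle = pi * 1e-3,
                         polarity_mobility = 0.1,
                         dt = 0.1,
                         relax_max_steps = 300,
                         relax_min_steps = 20,
                         conv_tol = 1e-3,
                         rule_radius = 2.5,
                         rule1_neighbor_threshold = 5,
                         rule1_neighbor_threshold_3d = 7,
                         te_division_rate_multiplier = 2,
                         apoptosis_nonpre_neighbor_threshold = 3,
                         fgf_undetermined_weight = 1,
                         epi_apoptosis_fraction = 0,
                         icm_global_potential = TRUE,
                         division_jitter_sd = 0.01,
                         nn_k = 20,
                         seal_distance = 1.0,
                         cavity_min_area = 3,
                         cavity_offset_min = 2) {
  p <- list(
    S_default = S_default, S_pre = S_pre,
    S_neutral_adhesion = S_neutral_adhesion,
    beta = beta, polar_prefactor = polar_prefactor,
    global_cutoff = global_cutoff, te_te_cutoff = te_te_cutoff,
    te_icm_cutoff = te_icm_cutoff,
    noise_sd_position = noise_sd_position, noise_sd_angle = noise_sd_angle,
    polarity_mobility = polarity_mobility, dt = dt,
    relax_max_steps = as.integer(relax_max_steps),
    relax_min_steps = as.integer(relax_min_steps),
    conv_tol = conv_tol, rule_radius = rule_radius,
    rule1_neighbor_threshold = rule1_neighbor_threshold,
    rule1_neighbor_threshold_3d = rule1_neighbor_threshold_3d,
    te_division_rate_multiplier = te_division_rate_multiplier,
    apoptosis_nonpre_neighbor_threshold = apoptosis_nonpre_neighbor_threshold,
    fgf_undetermined_weight = fgf_undetermined_weight,
    epi_apoptosis_fraction = epi_apoptosis_fraction,
    icm_global_potential = isTRUE(icm_global_potential),
    division_jitter_sd = division_jitter_sd,
    nn_k = as.integer(nn_k),
    seal_distance = seal_distance,
    cavity_min_area = cavity_min_area,
    cavity_offset_min = cavity_offset_min)
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  svals <- c(p$S_default, p$S_pre, p$S_neutral_adhesion)
  if (any(svals <= 0 | svals >= 1))
    stop("attraction factors S must lie in (0, 1)")
  if (p$beta <= 1) stop("beta must be > 1")
  if (p$te_te_cutoff < 2 || p$te_icm_cutoff < 2 || p$global_cutoff < 2)
    stop("interaction cutoffs must be >= 2 cell radii")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$relax_max_steps <= 0) stop("relax_max_steps must be positive")
  if (p$fgf_undetermined_weight < 0 || p$fgf_undetermined_weight > 1)
    stop("fgf_undetermined_weight must be in [0, 1]")
  if (p$epi_apoptosis_fraction < 0 || p$epi_apoptosis_fraction >= 1)
    stop("epi_apoptosis_fraction must be in [0, 1)")
  invisible(p)
}

# flat list handed to the C++ kernels; adhesion_mode:
# 0 uniform, 1 differential, 2 neutralized
cpp_param_list <- function(params, adhesion_mode) {
  list(S_default = params$S_default, S_pre = params$S_pre,
       S_neutral_adhesion = params$S_neutral_adhesion,
       beta = params$beta, polar_prefactor = params$polar_prefactor,
       global_cutoff = params$global_cutoff,
       te_te_cutoff = params$te_te_cutoff,
       te_icm_cutoff = params$te_icm_cutoff,
       dt = params$dt,
       noise_sd_position = params$noise_sd_position,
       noise_sd_angle = params$noise_sd_angle,
       polarity_mobility = params$polarity_mobility,
       adhesion_mode = as.integer(adhesion_mode),
       icm_global_potential = params$icm_global_potential)
}

#' Stage schedule
#'
#' The model has no absolute time units; the clock is event-driven (each
#' division advances time by 1 over the current number of circles, the
#' expected waiting time when every circle divides at unit rate). Stages are
#' pegged to that clock:
#'
#' * E3.0 is the instant the unperturbed embryo reaches the 16-cell stage,
#'   which under the deterministic clock is the harmonic sum
#'   `t = sum(1/(1:15))`. Polarity (rule 1) is applied and fate switching
#'   (rule 2) becomes active here.
#' * One *stage unit* is the interval E3.0 to E3.5. Differential adhesion
#'   (rule 3) switches on at E3.5 and the simulation ends, with positional
#'   apoptosis (rule 4), at E4.5 = E3.0 + 3 stage units.
#'
#' The default `stage_unit` is calibrated once so that the unperturbed
#' endpoint ensemble averages about 132 biological cells. Triggers are
#' absolute times, so halving or aggregating an embryo before E3.0 leaves
#' the schedule untouched, as in the scaling experiments.
#'
#' @param stage_unit duration of the E3.0 to E3.5 interval in clock time.
#' @param t_E30 absolute time of E3.0.
#' @param fgf_delay delay of fate-switching onset, in stage units (the
#'   delayed-FGF experiment uses 1; FGF signalling is absent before the
#'   delayed onset).
#' @param endpoint_units stage units between E3.0 and the endpoint.
#' @return an object of class `stage_schedule`.
#' @export
stage_schedule <- function(stage_unit = 0.717,
                           t_E30 = sum(1 / (1:15)),
                           fgf_delay = 0,
                           endpoint_units = 3) {
  if (stage_unit <= 0) stop("stage_unit must be positive")
  if (fgf_delay < 0) stop("fgf_delay must be >= 0")
  s <- list(
    t_E30 = t_E30,
    stage_unit = stage_unit,
    t_E35 = t_E30 + stage_unit,
    t_E40 = t_E30 + 2 * stage_unit,
    t_E45 = t_E30 + endpoint_units * stage_unit,
    rule2_start = t_E30 + fgf_delay * stage_unit,
    fgf_delay = fgf_delay,
    endpoint_units = endpoint_units)
  if (s$rule2_start < s$t_E30 - 1e-12)
    stop("rule 2 cannot start before rule 1 (fgf_delay must be >= 0)")
  if (s$t_E35 > s$t_E45)
    stop("rule 3 must trigger before the endpoint")
  class(s) <- "stage_schedule"
  s
}

#' Rule configuration
#'
#' Toggles and modes for the four developmental rules, covering the
#' published perturbations.
#'
#' @param rule1 apply surface polarity at E3.0? `FALSE` reproduces the
#'   polarity-deletion experiment (uniform `S`, no TE, no cavity).
#' @param rule2_mode `"normal"` for neighbourhood-dependent fate switching;
#'   `"no_fgf"` (all ICM becomes epiblast), `"excess_fgf"` (all PrE),
#'   `"delayed"` (inert until the schedule's delayed onset, then normal;
#'   cells specified late leave unresolved, epiblast-counted cells at the
#'   endpoint), or `"off"` (ICM stays undetermined).
#' @param rule3_mode `"normal"` differential adhesion, or `"neutralized"`
#'   (every ICM-ICM pair gets the intermediate attraction factor).
#' @param rule4 apply positional apoptosis at the endpoint?
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(rule1 = TRUE,
                        rule2_mode = c("normal", "no_fgf", "excess_fgf",
                                       "delayed", "off"),
                        rule3_mode = c("normal", "neutralized"),
                        rule4 = TRUE) {
  r <- list(rule1 = isTRUE(rule1),
            rule2_mode = match.arg(rule2_mode),
            rule3_mode = match.arg(rule3_mode),
            rule4 = isTRUE(rule4))
  class(r) <- "rule_config"
  r
}
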