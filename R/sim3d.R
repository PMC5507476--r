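#' 3D validation run
#'
#' Runs the full rule pipeline in 3D: positions and polarities are
#' 3-vectors, TE-TE interactions are restricted to halfway-point true
#' nearest neighbours (a centre-distance threshold confuses nearest with
#' next-nearest neighbours in 3D), daughters are placed at the centre of the
#' mother's 3 nearest neighbours, and development is initialised at the
#' 3-cell stage. Classification in 3D is qualitative (shell connectivity,
#' cavity, seal test).
#'
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param params,rules,schedule model configuration (see
#'   [simulate_embryo()]).
#' @return a list of `blastosim_run` objects with an [ensemble_stats()]
#'   summary attached as attribute `"summary"`.
#' @export
run_3d_validation <- function(n_replicates = 1, seed = 1,
                              params = model_params(),
                              rules = rule_config(),
                              schedule = stage_schedule()) {
  seeds <- replicate_seeds(seed, n_replicates)
  runs <- lapply(seq_len(n_replicates), function(r)
    simulate_embryo(params = params, rules = rules, schedule = schedule,
                    dim = 3, seed = seeds[r], record = "stages"))
  attr(runs, "summary") <- ensemble_stats(lapply(runs, `[[`, "outcome"))
  runs
}
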