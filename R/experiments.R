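#' Built-in experiment specifications
#'
#' Named presets for the published in silico experiments: the wild type, the
#' four rule deletions, FGF modulation and delay, embryo halving and
#' aggregation, and the two model variants (epiblast apoptosis, reduced
#' FGF4 from undetermined ICM).
#'
#' @param name experiment name, one of `"wild_type"`, `"drule1"`,
#'   `"drule2_low"`, `"drule2_high"`, `"drule2_delay"`, `"drule3"`,
#'   `"drule4"`, `"halve"`, `"aggregate2"`, `"aggregate3"`,
#'   `"epi_apoptosis"`, `"half_fgf_undetermined"`.
#' @param n_replicates ensemble size (the published setting is 200; 50 is a
#'   desk-scale default).
#' @param seed master seed from which per-replicate seeds are derived.
#' @param stage manipulation stage for halving/aggregation (2, 4 or 8).
#' @param params base [model_params()], modified as the experiment requires.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, n_replicates = 50, seed = 1, stage = 8,
                            params = model_params()) {
  known <- c("wild_type", "drule1", "drule2_low", "drule2_high",
             "drule2_delay", "drule3", "drule4", "halve", "aggregate2",
             "aggregate3", "epi_apoptosis", "half_fgf_undetermined")
  if (!name %in% known)
    stop("unknown experiment: ", name)
  rules <- rule_config()
  schedule <- stage_schedule()
  manipulation <- NULL
  if (name == "drule1") rules <- rule_config(rule1 = FALSE)
  if (name == "drule2_low") rules <- rule_config(rule2_mode = "no_fgf")
  if (name == "drule2_high") rules <- rule_config(rule2_mode = "excess_fgf")
  if (name == "drule2_delay") {
    rules <- rule_config(rule2_mode = "delayed")
    schedule <- stage_schedule(fgf_delay = 1)
  }
  if (name == "drule3") rules <- rule_config(rule3_mode = "neutralized")
  if (name == "drule4") rules <- rule_config(rule4 = FALSE)
  if (name == "halve") manipulation <- list(type = "halve", stage = stage)
  if (name == "aggregate2")
    manipulation <- list(type = "aggregate", k = 2, stage = stage)
  if (name == "aggregate3")
    manipulation <- list(type = "aggregate", k = 3, stage = stage)
  if (name == "epi_apoptosis") params$epi_apoptosis_fraction <- 0.2
  if (name == "half_fgf_undetermined") params$fgf_undetermined_weight <- 0.5
  spec <- list(name = name, rules = rules, schedule = schedule,
               manipulation = manipulation, params = params,
               n_replicates = as.integer(n_replicates),
               seed = as.integer(seed))
  class(spec) <- "experiment_spec"
  spec
}

#' Derive independent per-replicate seeds from a master seed
#'
#' @param master_seed integer master seed.
#' @param n number of replicates.
#' @return an integer vector of seeds.
#' @export
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an ensemble of replicates for one experiment
#'
#' Replicates are independent given their derived seeds, so results do not
#' depend on execution order. Each replicate is simulated, classified, and
#' summarised into one row.
#'
#' @param spec an [experiment_spec()], or an experiment name passed on to
#'   [experiment_spec()].
#' @param ... forwarded to [experiment_spec()] when `spec` is a name.
#' @return a `blastosim_ensemble` data frame with one row per replicate
#'   (seed, outcome category, biological counts, fractions, apoptosis count,
#'   deep-PrE diagnostics), with the experiment spec and an
#'   [ensemble_stats()] summary attached as attributes.
#' @export
run_ensemble <- function(spec, ...) {
  if (is.character(spec)) spec <- experiment_spec(spec, ...)
  stopifnot(inherits(spec, "experiment_spec"))
  seeds <- replicate_seeds(spec$seed, spec$n_replicates)
  rows <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    run <- simulate_embryo(params = spec$params, rules = spec$rules,
                           schedule = spec$schedule,
                           manipulation = spec$manipulation,
                           seed = seeds[r], record = "none")
    o <- run$outcome
    rows[[r]] <- data.frame(
      replicate = r, seed = seeds[r],
      category = o$category,
      total = o$counts$total, te = o$counts$te, epi = o$counts$epi,
      pre = o$counts$pre, undet = o$counts$undet, icm = o$counts$icm,
      icm_total = o$fractions$icm_total,
      epi_icm = o$fractions$epi_icm,
      pre_icm = o$fractions$pre_icm,
      apoptosis = run$diagnostics$apoptosis_count,
      deep_pre_before_rule4 = run$diagnostics$deep_pre_before_rule4,
      deep_pre_endpoint = o$diagnostics$misplaced_pre_in_epi)
  }
  df <- do.call(rbind, rows)
  class(df) <- c("blastosim_ensemble", "data.frame")
  attr(df, "spec") <- spec
  attr(df, "summary") <- ensemble_stats(df)
  df
}

#' Run and tabulate a suite of experimental conditions
#'
#' @param names character vector of experiment names (see
#'   [experiment_spec()]).
#' @param n_replicates replicates per condition.
#' @param seed master seed (each condition derives its own stream).
#' @param params base model parameters.
#' @return a data frame with one row per condition: stacked category
#'   fractions, ensemble means and standard deviations. The per-condition
#'   ensembles are attached as attribute `"ensembles"`.
#' @export
run_condition_suite <- function(names, n_replicates = 50, seed = 1,
                                params = model_params()) {
  stopifnot(length(names) >= 1)
  ensembles <- list()
  rows <- lapply(seq_along(names), function(q) {
    spec <- experiment_spec(names[q], n_replicates = n_replicates,
                            seed = seed + q, params = params)
    ens <- run_ensemble(spec)
    ensembles[[names[q]]] <<- ens
    s <- attr(ens, "summary")
    data.frame(condition = names[q], n = s$n,
               success = s$category_fractions[["SUCCESS"]],
               no_te = s$category_fractions[["NO_TE"]],
               epi_only = s$category_fractions[["EPI_ONLY"]],
               pre_only = s$category_fractions[["PRE_ONLY"]],
               epi_in_pre = s$category_fractions[["EPI_IN_PRE_ERROR"]],
               pre_in_epi = s$category_fractions[["PRE_IN_EPI_ERROR"]],
               total_mean = s$total_mean, total_sd = s$total_sd,
               icm_total_mean = s$icm_total_mean,
               epi_icm_mean = s$epi_icm_mean,
               pre_icm_mean = s$pre_icm_mean,
               apoptosis_mean = s$apoptosis_mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "ensembles") <- ensembles
  out
}
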