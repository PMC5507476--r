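#' Simulate one embryo from a single cell to the endpoint
#'
#' Growth is event-driven: a circle is selected to divide, the daughter is
#' inserted, fates are updated by rule 2 when its window is open, and the
#' system relaxes before the next division. The clock advances by
#' `1 / n_circles` per division (the expected waiting time when every circle
#' divides at unit rate), so growth is exponential and, because each
#' biological TE cell is two circles, TE proliferates at twice the
#' biological ICM rate. Polarity (rule 1) fires at E3.0, differential
#' adhesion (rule 3) at E3.5, and positional apoptosis (rule 4) at the E4.5
#' endpoint; see [stage_schedule()].
#'
#' @param params a [model_params()] object.
#' @param rules a [rule_config()] object.
#' @param schedule a [stage_schedule()] object.
#' @param dim 2 (default) or 3.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @param manipulation optional list describing an embryo manipulation
#'   before compaction: `list(type = "halve", stage = 8)` removes half the
#'   cells at the given cell stage; `list(type = "aggregate", k = 2,
#'   stage = 8)` merges `k` embryos grown to that stage. The stage schedule
#'   is left unchanged in absolute time.
#' @param init_cells number of starting cells (1 in 2D; 3D runs start at the
#'   3-cell stage by default).
#' @param record `"stages"` records a snapshot at each stage marker,
#'   `"events"` after every division, `"none"` only the endpoint.
#' @return an object of class `blastosim_run`: the final `embryo`, the
#'   classified `outcome`, per-run `diagnostics` and recorded `trajectory`.
#' @export
simulate_embryo <- function(params = model_params(),
                            rules = rule_config(),
                            schedule = stage_schedule(),
                            dim = 2,
                            seed = NULL,
                            manipulation = NULL,
                            init_cells = if (dim == 3) 3 else 1,
                            record = c("stages", "events", "none")) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(manipulation)) {
    stopifnot(is.list(manipulation), !is.null(manipulation$type))
    if (is.null(manipulation$stage)) manipulation$stage <- 8
    if (manipulation$stage > 8)
      stop("manipulations are only supported up to the 8-cell stage")
  }

  if (!is.null(manipulation) && manipulation$type == "aggregate") {
    k <- if (is.null(manipulation$k)) 2 else manipulation$k
    stopifnot(k %in% c(2, 3))
    parts <- lapply(seq_len(k), function(.)
      grow_to_count(new_embryo(init_cells, dim, params, rules, schedule),
                    manipulation$stage))
    embryo <- merge_embryos(parts)
    embryo <- relax(embryo)
  } else {
    embryo <- new_embryo(init_cells, dim, params, rules, schedule)
    if (!is.null(manipulation) && manipulation$type == "halve") {
      embryo <- grow_to_count(embryo, manipulation$stage)
      embryo <- halve_embryo(embryo)
      embryo <- relax(embryo)
    }
  }

  traj <- list()
  snap <- function(label) {
    if (record == "none") return()
    df <- cells_df(embryo)
    df$stage <- label
    traj[[length(traj) + 1]] <<- df
  }

  repeat {
    # polarity fires at the 16-cell stage (manipulated embryos reach it at
    # a different absolute time; rules 2-4 stay pegged to absolute time)
    if (!embryo$rule1_done && biological_counts(embryo)$total >= 16) {
      snap("16cell_pre_polarity")
      embryo <- apply_rule1_polarity(embryo)
      embryo <- relax(embryo, n_steps = 2L * params$relax_max_steps)
      snap("16cell_polarity")
    }
    t_next <- embryo$time + 1 / n_circles(embryo)
    if (!embryo$rule3_done && t_next >= embryo$schedule$t_E35) {
      embryo$time <- embryo$schedule$t_E35
      embryo <- apply_rule3_adhesion(embryo)
      snap("E3.5")
      next
    }
    if (t_next >= embryo$schedule$t_E45) {
      embryo$time <- embryo$schedule$t_E45
      break
    }
    embryo$time <- t_next
    i <- select_divider(embryo)
    div <- divide_cell(embryo, i)
    embryo <- apply_rule2_fate(div$embryo, i, div$daughter)
    embryo <- relax(embryo)
    if (record == "events") snap(sprintf("t%.3f", embryo$time))
  }

  embryo$deep_pre_before_rule4 <- length(deep_pre_cells(embryo))
  snap("E4.5_pre_apoptosis")
  if (embryo$rules$rule4 || params$epi_apoptosis_fraction > 0) {
    if (embryo$rules$rule4) {
      embryo <- apply_rule4_apoptosis(embryo)
    } else if (params$epi_apoptosis_fraction > 0) {
      epi <- which(embryo$lineage == LINEAGES[["EPI"]])
      n_extra <- round(params$epi_apoptosis_fraction * length(epi))
      if (n_extra > 0) {
        victims <- sample(epi, n_extra)
        embryo$apoptosis_count <- embryo$apoptosis_count + length(victims)
        embryo <- remove_circles(embryo, victims)
      }
    }
    embryo <- relax(embryo)
  }
  snap("E4.5")

  out <- classify(embryo)
  res <- list(embryo = embryo,
              outcome = out,
              diagnostics = list(
                deep_pre_before_rule4 = embryo$deep_pre_before_rule4,
                apoptosis_count = embryo$apoptosis_count),
              trajectory = traj,
              seed = seed)
  class(res) <- "blastosim_run"
  res
}

#' @export
print.blastosim_run <- function(x, ...) {
  cat(sprintf("<blastosim run> outcome: %s\n", x$outcome$category))
  print(x$embryo)
  invisible(x)
}

# grow (divide + relax) until the biological cell count reaches `target`
grow_to_count <- function(embryo, target) {
  while (biological_counts(embryo)$total < target) {
    embryo$time <- embryo$time + 1 / n_circles(embryo)
    i <- select_divider(embryo)
    div <- divide_cell(embryo, i)
    embryo <- apply_rule2_fate(div$embryo, i, div$daughter)
    embryo <- relax(embryo)
  }
  embryo
}

#' Remove half the cells of an embryo
#'
#' A random half of the cells is removed (for odd counts, `floor(n/2)` cells
#' are retained); the stage schedule continues unchanged in absolute time.
#' Set `spatial = TRUE` to bisect along a random axis instead.
#'
#' @param embryo an embryo at or before the 8-cell stage.
#' @param spatial remove one side of a random bisection plane instead of a
#'   random half.
#' @return the halved embryo (not relaxed).
#' @export
halve_embryo <- function(embryo, spatial = FALSE) {
  n <- n_circles(embryo)
  if (n < 2) stop("cannot halve an embryo with fewer than 2 cells")
  keep_n <- floor(n / 2)
  if (spatial) {
    dir <- rnorm(embryo$dim)
    dir <- dir / sqrt(sum(dir^2))
    proj <- as.vector(embryo$pos %*% dir)
    drop_idx <- order(proj, decreasing = TRUE)[seq_len(n - keep_n)]
  } else {
    drop_idx <- sample.int(n, n - keep_n)
  }
  remove_circles(embryo, drop_idx)
}

#' Aggregate embryos
#'
#' Unions the cell sets of 2 or 3 embryos at the same pre-compaction stage,
#' with centroids offset by about one embryo diameter so the cell masses
#' touch; the combined embryo keeps the absolute stage schedule of its
#' parts.
#'
#' @param embryos a list of embryos at the same stage.
#' @return the merged embryo (not relaxed).
#' @export
merge_embryos <- function(embryos) {
  k <- length(embryos)
  stopifnot(k %in% c(2, 3))
  counts <- vapply(embryos, function(e) biological_counts(e)$total, numeric(1))
  if (length(unique(counts)) != 1)
    stop("embryos must be at the same stage to aggregate")
  base <- embryos[[1]]
  # one embryo diameter, estimated from the first embryo's extent
  span <- max(2.5, 2 * max(sqrt(rowSums(
    sweep(base$pos, 2, colMeans(base$pos))^2))) + 2)
  offsets <- list(c(0, 0, 0),
                  c(span, 0, 0),
                  c(span / 2, span * sqrt(3) / 2, 0))
  out <- base
  out$pos <- sweep(out$pos, 2, colMeans(out$pos))
  for (m in seq_len(k)[-1]) {
    e <- embryos[[m]]
    shift <- offsets[[m]][seq_len(base$dim)]
    pos <- sweep(e$pos, 2, colMeans(e$pos))
    pos <- sweep(pos, 2, shift, "+")
    for (q in seq_len(nrow(pos)))
      out <- add_circle(out, pos[q, ], e$lineage[q],
                        e$pol[q, ], NA_integer_)
  }
  out$time <- base$time
  out
}
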