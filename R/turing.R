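#' Lattice model of neighbour-mediated fate switching
#'
#' A fixed grid of ICM cells with periodic boundaries, updated
#' asynchronously by the fate-switching rule alone: a random site converts
#' to PrE with probability equal to the fraction of high-FGF4 cells
#' (epiblast or undetermined) in its neighbourhood, and to epiblast
#' otherwise. This is the discrete Turing-like mechanism — local
#' amplification with neighbour-mediated inhibition — whose PrE/ICM ratio
#' converges to about one half independent of grid size.
#'
#' @param width,height grid dimensions.
#' @param init initial state for every site: `"undetermined"`,
#'   `"checkerboard"` (alternating EPI/PrE), or a matrix of lineage names.
#' @param neighborhood `"moore"` (8 sites) or `"von_neumann"` (4 sites).
#' @return an object of class `turing_lattice`.
#' @export
turing_lattice <- function(width = 10, height = width,
                           init = c("undetermined", "checkerboard"),
                           neighborhood = c("moore", "von_neumann")) {
  neighborhood <- match.arg(neighborhood)
  if (is.matrix(init)) {
    states <- matrix(lineage_code(init), nrow(init), ncol(init))
    height <- nrow(init); width <- ncol(init)
    if (any(is.na(states)) || any(states == LINEAGES[["TE"]]))
      stop("lattice states must be UNDETERMINED_ICM, EPI or PRE")
  } else {
    init <- match.arg(init)
    states <- if (init == "undetermined") {
      matrix(LINEAGES[["UNDETERMINED_ICM"]], height, width)
    } else {
      matrix(ifelse((outer(seq_len(height), seq_len(width), "+")) %% 2 == 0,
                    LINEAGES[["EPI"]], LINEAGES[["PRE"]]), height, width)
    }
  }
  l <- list(states = states, width = width, height = height,
            neighborhood = neighborhood)
  class(l) <- "turing_lattice"
  l
}

# periodic neighbour states of site (i, j)
lattice_neighbor_states <- function(lattice, i, j) {
  offs <- if (lattice$neighborhood == "moore") {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  ii <- ((i - 1 + offs[, 1]) %% lattice$height) + 1
  jj <- ((j - 1 + offs[, 2]) %% lattice$width) + 1
  lattice$states[cbind(ii, jj)]
}

#' One asynchronous lattice update
#'
#' A uniformly random site becomes PrE with probability
#' `(high-FGF4 neighbours) / (total neighbours)` and epiblast otherwise.
#'
#' @param lattice a [turing_lattice()].
#' @return the updated lattice.
#' @export
lattice_step <- function(lattice) {
  i <- sample.int(lattice$height, 1)
  j <- sample.int(lattice$width, 1)
  nb <- lattice_neighbor_states(lattice, i, j)
  p_pre <- mean(nb != LINEAGES[["PRE"]])   # EPI and undetermined are high-FGF4
  lattice$states[i, j] <- if (runif(1) < p_pre)
    LINEAGES[["PRE"]] else LINEAGES[["EPI"]]
  lattice
}

#' Run the lattice model and trace the PrE/ICM ratio
#'
#' @param lattice a [turing_lattice()].
#' @param n_updates number of asynchronous site updates.
#' @param record_every record the ratio every this many updates.
#' @return a list with the final `lattice`, the `trace` data frame
#'   (`update`, `pre_icm`) and `long_run_mean` (mean ratio over the final
#'   half of the trace).
#' @export
lattice_run <- function(lattice, n_updates, record_every = 10) {
  stopifnot(n_updates >= 1)
  n_sites <- lattice$width * lattice$height
  nrec <- floor(n_updates / record_every)
  updates <- numeric(nrec); ratios <- numeric(nrec)
  r <- 0L
  # inline the single-site update for speed
  moore <- lattice$neighborhood == "moore"
  st <- lattice$states
  h <- lattice$height; w <- lattice$width
  offs <- if (moore) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  pre_code <- LINEAGES[["PRE"]]; epi_code <- LINEAGES[["EPI"]]
  n_pre <- sum(st == pre_code)
  for (u in seq_len(n_updates)) {
    i <- sample.int(h, 1); j <- sample.int(w, 1)
    ii <- ((i - 1 + offs[, 1]) %% h) + 1
    jj <- ((j - 1 + offs[, 2]) %% w) + 1
    nb <- st[cbind(ii, jj)]
    p_pre <- mean(nb != pre_code)
    old <- st[i, j]
    new <- if (runif(1) < p_pre) pre_code else epi_code
    st[i, j] <- new
    n_pre <- n_pre + (new == pre_code) - (old == pre_code)
    if (u %% record_every == 0) {
      r <- r + 1L
      updates[r] <- u
      ratios[r] <- n_pre / n_sites
    }
  }
  lattice$states <- st
  half <- ratios[seq.int(max(1, floor(r / 2)), r)]
  list(lattice = lattice,
       trace = data.frame(update = updates[seq_len(r)],
                          pre_icm = ratios[seq_len(r)]),
       long_run_mean = mean(half),
       long_run_sd = sd(half))
}

#' PrE/ICM ratio trace of a fresh lattice
#'
#' Convenience wrapper: build a lattice, run it, return the trace and the
#' long-run mean.
#'
#' @param size grid edge length.
#' @param n_updates number of asynchronous updates.
#' @param ... forwarded to [turing_lattice()].
#' @inheritParams lattice_run
#' @return as [lattice_run()].
#' @export
lattice_ratio_trace <- function(size = 10, n_updates = 1e5,
                                record_every = 10, ...) {
  lattice_run(turing_lattice(size, size, ...), n_updates, record_every)
}

#' @export
print.turing_lattice <- function(x, ...) {
  n <- x$width * x$height
  cat(sprintf("<turing lattice> %dx%d (%s), PrE/ICM = %.3f\n",
              x$height, x$width, x$neighborhood,
              sum(x$states == LINEAGES[["PRE"]]) / n))
  invisible(x)
}
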