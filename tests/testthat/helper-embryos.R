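# Shared builders and independent oracles for the test suite.

# build an embryo directly from coordinates / lineage names / polarity
make_embryo <- function(pos, lineage, pol = NULL, params = model_params(),
                        rules = rule_config(), schedule = stage_schedule(),
                        rule3_done = FALSE, time = schedule$t_E45) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  e <- new_embryo(1, dim = ncol(pos), params = params, rules = rules,
                  schedule = schedule)
  e$pos <- pos
  codes <- c(UNDETERMINED_ICM = 0L, TE = 1L, EPI = 2L, PRE = 3L)
  e$lineage <- unname(codes[lineage])
  if (is.null(pol)) pol <- matrix(0, n, ncol(pos))
  e$pol <- as.matrix(pol)
  e$te_pair <- rep(NA_integer_, n)
  e$id <- seq_len(n)
  e$next_id <- n + 1L
  e$rule1_done <- TRUE
  e$rule3_done <- rule3_done
  e$time <- time
  e
}

# closed TE ring of n circles at the given radius, polarities radially out
ring_positions <- function(n, radius) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  list(pos = cbind(radius * cos(ang), radius * sin(ang)),
       pol = cbind(cos(ang), sin(ang)))
}

# hand-built blastocyst: TE ring + epiblast core against the wall + a PrE
# arc sealing the core from the ring centre (the cavity side)
make_blastocyst <- function(ring_n = 60, ring_r = 16) {
  ring <- ring_positions(ring_n, ring_r)
  # epiblast cluster tucked against the inner wall at angle 0
  core_ctr <- c(ring_r - 3.5, 0)
  ang <- seq(0, 2 * pi, length.out = 8)[-8]
  epi <- rbind(core_ctr, sweep(1.4 * cbind(cos(ang), sin(ang)), 2,
                               core_ctr, "+"))
  # PrE shell around the core on the cavity-facing side
  arc <- seq(pi / 2, 3 * pi / 2, length.out = 9)
  pre <- sweep(3.0 * cbind(cos(arc), sin(arc)), 2, core_ctr, "+")
  pos <- rbind(ring$pos, epi, pre)
  lineage <- c(rep("TE", ring_n), rep("EPI", nrow(epi)),
               rep("PRE", nrow(pre)))
  pol <- rbind(ring$pol, matrix(0, nrow(epi) + nrow(pre), 2))
  make_embryo(pos, lineage, pol, rule3_done = TRUE)
}

# brute-force halfway-point nearest neighbours: all points are candidates
brute_true_nn <- function(pos) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mid <- (pos[i, ] + pos[j, ]) / 2
      half <- sqrt(sum((mid - pos[i, ])^2))
      ok <- TRUE
      for (m in seq_len(n)) {
        if (m == i || m == j) next
        if (sqrt(sum((mid - pos[m, ])^2)) < half - 1e-9) { ok <- FALSE; break }
      }
      keep[i, j] <- ok
    }
  }
  keep & t(keep)
}

# central-difference gradient of the total potential energy
numerical_force <- function(embryo, h = 1e-6) {
  n <- nrow(embryo$pos)
  D <- ncol(embryo$pos)
  F <- matrix(0, n, D)
  for (i in seq_len(n)) {
    for (d in seq_len(D)) {
      ep <- embryo; ep$pos[i, d] <- ep$pos[i, d] + h
      em <- embryo; em$pos[i, d] <- em$pos[i, d] - h
      F[i, d] <- -(total_energy(ep) - total_energy(em)) / (2 * h)
    }
  }
  F
}

# quick schedule for smoke runs: small endpoint (~40 cells)
fast_schedule <- function() stage_schedule(stage_unit = 0.35)
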