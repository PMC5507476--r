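# grow a fresh embryo to a given biological cell count
grow_cluster <- function(n_cells, seed = 1, dim = 2) {
  set.seed(seed)
  e <- new_embryo(1, dim = dim)
  while (nrow(e$pos) < n_cells) {
    e$time <- e$time + 1 / nrow(e$pos)
    i <- select_divider(e)
    d <- divide_cell(e, i)
    e <- relax(d$embryo)
  }
  relax(e, 500)
}

test_that("surface cells acquire polarity and are doubled at compaction", {
  e <- grow_cluster(16, seed = 3)
  e2 <- apply_rule1_polarity(e)
  te <- which(e2$lineage == 1L)
  icm <- which(e2$lineage == 0L)
  n_te_cells <- sum(e2$lineage[1:16] == 1L)
  # outer cells became TE, inner stayed undetermined, and each TE cell is
  # represented by two circles
  expect_gt(n_te_cells, 4)
  expect_gt(length(icm), 2)
  expect_equal(nrow(e2$pos), 16 + n_te_cells)
  expect_equal(length(te), 2 * n_te_cells)
  # TE polarities are unit vectors pointing away from the centroid
  ctr <- colMeans(e$pos)
  for (i in te) {
    expect_equal(sqrt(sum(e2$pol[i, ]^2)), 1, tolerance = 1e-9)
  }
  out_dot <- vapply(seq_len(16), function(i) {
    if (e2$lineage[i] != 1L) return(1)
    v <- e2$pos[i, ] - ctr
    sum(v * e2$pol[i, ]) / sqrt(sum(v^2))
  }, numeric(1))
  expect_true(all(out_dot > 0.9))
  # biological count is conserved by the doubling
  expect_equal(biological_counts(e2)$total, 16)
})

test_that("every cell of a small mutually-visible cluster becomes TE", {
  ang <- 2 * pi * (0:4) / 5
  pos <- 1.3 * cbind(cos(ang), sin(ang))
  e <- make_embryo(pos, rep("UNDETERMINED_ICM", 5))
  e$rule1_done <- FALSE
  e2 <- apply_rule1_polarity(e)
  expect_true(all(e2$lineage == 1L))
})

test_that("polarity deletion leaves every cell undetermined ICM", {
  e <- grow_cluster(16, seed = 4)
  e$rules <- rule_config(rule1 = FALSE)
  e2 <- apply_rule1_polarity(e)
  expect_true(all(e2$lineage == 0L))
  expect_equal(nrow(e2$pos), 16)
  expect_true(e2$rule1_done)
})

test_that("TE divides at twice the biological rate of ICM", {
  # 8 biological TE cells (16 circles) + 8 ICM cells: P(TE divider) = 2/3
  pos <- matrix(seq_len(24) * 10, 24, 2)
  e <- make_embryo(pos, c(rep("TE", 16), rep("EPI", 8)))
  set.seed(20)
  draws <- replicate(3000, e$lineage[select_divider(e)] == 1L)
  p_hat <- mean(draws)
  se <- sqrt(2 / 9 / 3000)
  expect_lt(abs(p_hat - 2 / 3), 4 * se)
})

test_that("daughters appear at the midpoint and inherit fate and polarity", {
  e <- make_embryo(rbind(c(0, 0), c(2, 0), c(10, 10)),
                   c("TE", "TE", "EPI"),
                   pol = rbind(c(cos(pi / 4), sin(pi / 4)), c(1, 0), c(0, 0)))
  set.seed(21)
  div <- divide_cell(e, 1)
  expect_equal(div$daughter, 4)
  expect_equal(div$embryo$pos[4, ], c(1, 0), tolerance = 0.1)
  expect_equal(div$embryo$lineage[4], 1L)
  expect_equal(div$embryo$pol[4, ], c(cos(pi / 4), sin(pi / 4)))
  # a single cell still divides (daughter placed adjacent)
  e1 <- make_embryo(matrix(0, 1, 2), "UNDETERMINED_ICM")
  div1 <- divide_cell(e1, 1)
  expect_equal(nrow(div1$embryo$pos), 2)
})

test_that("the fate-switch probability equals the neighbourhood fraction", {
  # centre cell with contact neighbours {EPI, EPI, EPI, PRE} -> P(PrE) = 3/4
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(-2, 0), c(0, -2))
  e <- make_embryo(pos, c("EPI", "EPI", "EPI", "EPI", "PRE"))
  expect_equal(rule2_probability(e, 1), 3 / 4)
  # all-PrE neighbourhood: the cell must become epiblast
  e2 <- make_embryo(pos, c("EPI", rep("PRE", 4)))
  expect_equal(rule2_probability(e2, 1), 0)
  # no ICM neighbours at all -> epiblast by convention
  e3 <- make_embryo(rbind(c(0, 0), c(50, 0)), c("UNDETERMINED_ICM", "EPI"))
  expect_equal(rule2_probability(e3, 1), 0)
  # undetermined neighbours count as high-FGF4 with the configured weight
  e4 <- make_embryo(pos, c("EPI", "UNDETERMINED_ICM", "UNDETERMINED_ICM",
                           "PRE", "PRE"))
  expect_equal(rule2_probability(e4, 1), 2 / 4)
  e4$params$fgf_undetermined_weight <- 0.5
  expect_equal(rule2_probability(e4, 1), 1 / 3)
})

test_that("the fate-switch probability matches brute-force counting", {
  set.seed(22)
  checked <- 0
  while (checked < 1000) {
    n <- sample(6:14, 1)
    pos <- matrix(runif(2 * n, 0, 6), n, 2)
    if (min(dist(pos)) < 0.3) next
    lin <- sample(c("UNDETERMINED_ICM", "EPI", "PRE", "TE"), n, replace = TRUE)
    icm_idx <- which(lin != "TE")
    if (length(icm_idx) == 0) next
    e <- make_embryo(pos, lin)
    i <- icm_idx[sample.int(length(icm_idx), 1)]
    # oracle: brute-force halfway-point neighbours, capped at the range
    adj <- brute_true_nn(pos)
    dm <- as.matrix(dist(pos))
    nb <- which(adj[i, ] & dm[i, ] <= e$params$global_cutoff)
    H <- sum(lin[nb] == "EPI") + sum(lin[nb] == "UNDETERMINED_ICM")
    N <- H + sum(lin[nb] == "PRE")
    expected <- if (N == 0) 0 else H / N
    expect_equal(rule2_probability(e, i), expected)
    checked <- checked + 1
  }
})

test_that("FGF modulation modes force a single fate and TE is terminal", {
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2))
  base <- make_embryo(pos, c("UNDETERMINED_ICM", "UNDETERMINED_ICM", "TE"),
                      pol = rbind(c(0, 0), c(0, 0), c(0, 1)))
  base$time <- base$schedule$t_E35
  low <- base; low$rules <- rule_config(rule2_mode = "no_fgf")
  low <- apply_rule2_fate(low, 1, 2)
  expect_equal(low$lineage[1:2], c(2L, 2L))
  high <- base; high$rules <- rule_config(rule2_mode = "excess_fgf")
  high <- apply_rule2_fate(high, 1, 2)
  expect_equal(high$lineage[1:2], c(3L, 3L))
  # a TE mother is never re-specified
  te <- apply_rule2_fate(base, 3, 1)
  expect_equal(te$lineage[3], 1L)
  # before the window opens the rule is inert
  early <- base
  early$time <- early$schedule$t_E30 - 1
  early$rule1_done <- TRUE
  early2 <- apply_rule2_fate(early, 1, 2)
  expect_equal(early2$lineage[1:2], c(0L, 0L))
  # delayed onset keeps cells undetermined until the delayed start
  del <- base
  del$rules <- rule_config(rule2_mode = "delayed")
  del$schedule <- stage_schedule(fgf_delay = 1)
  del$time <- del$schedule$t_E30 + 0.5 * del$schedule$stage_unit
  del2 <- apply_rule2_fate(del, 1, 2)
  expect_equal(del2$lineage[1:2], c(0L, 0L))
  del$time <- del$schedule$rule2_start
  del3 <- apply_rule2_fate(del, 1, 2)
  expect_true(all(del3$lineage[1:2] %in% c(2L, 3L)))
})

test_that("apoptosis removes PrE cells above the deep-position threshold", {
  # PrE with 4 epiblast contact neighbours: removed
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(-2, 0), c(0, -2))
  e <- make_embryo(pos, c("PRE", rep("EPI", 4)))
  e2 <- apply_rule4_apoptosis(e)
  expect_equal(nrow(e2$pos), 4)
  expect_equal(e2$apoptosis_count, 1)
  expect_false(any(e2$lineage == 3L))
  # 3 non-PrE neighbours is not deep (threshold is strict)
  e3 <- make_embryo(pos, c("PRE", "EPI", "EPI", "EPI", "PRE"))
  e4 <- apply_rule4_apoptosis(e3)
  expect_equal(nrow(e4$pos), 5)
  expect_equal(e4$apoptosis_count, 0)
})

test_that("the epiblast-apoptosis variant removes the configured fraction", {
  pos <- cbind(seq_len(22) * 10, 0)
  e <- make_embryo(pos, c(rep("EPI", 20), "PRE", "PRE"),
                   params = model_params(epi_apoptosis_fraction = 0.2))
  set.seed(23)
  e2 <- apply_rule4_apoptosis(e)
  expect_equal(sum(e2$lineage == 2L), 16)
  expect_equal(e2$apoptosis_count, 4)
})
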