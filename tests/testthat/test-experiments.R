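test_that("halving removes half the cells and keeps the clock", {
  pos <- cbind(seq_len(8) * 3, 0)
  e <- make_embryo(pos, rep("UNDETERMINED_ICM", 8))
  e$rule1_done <- FALSE
  t0 <- e$time
  set.seed(40)
  h <- halve_embryo(e)
  expect_equal(nrow(h$pos), 4)
  expect_equal(h$time, t0)
  # odd counts: floor(n/2) cells are retained
  e7 <- make_embryo(cbind(seq_len(7) * 3, 0), rep("UNDETERMINED_ICM", 7))
  expect_equal(nrow(halve_embryo(e7)$pos), 3)
  expect_error(halve_embryo(make_embryo(matrix(0, 1, 2), "EPI")), "fewer")
  # spatial bisection keeps one side of a plane
  set.seed(41)
  hs <- halve_embryo(e, spatial = TRUE)
  expect_equal(nrow(hs$pos), 4)
})

test_that("aggregation unions embryos at the same stage", {
  mk8 <- function(shift) {
    pos <- cbind(rep(1:4, 2) * 2.2, rep(c(0, 2.2), each = 4) + shift)
    e <- make_embryo(pos, rep("UNDETERMINED_ICM", 8))
    e$rule1_done <- FALSE
    e
  }
  m <- merge_embryos(list(mk8(0), mk8(5)))
  expect_equal(nrow(m$pos), 16)
  expect_equal(biological_counts(m)$total, 16)
  # the two cell masses are offset, not superposed
  expect_gt(max(dist(m$pos)), max(dist(mk8(0)$pos)))
  m3 <- merge_embryos(list(mk8(0), mk8(1), mk8(2)))
  expect_equal(nrow(m3$pos), 24)
  e4 <- make_embryo(cbind(1:4 * 2.2, 0), rep("UNDETERMINED_ICM", 4))
  expect_error(merge_embryos(list(mk8(0), e4)), "same stage")
})

test_that("experiment specs validate their inputs", {
  expect_error(experiment_spec("nonsense"), "unknown experiment")
  spec <- experiment_spec("halve", n_replicates = 5, seed = 3, stage = 4)
  expect_equal(spec$manipulation$stage, 4)
  expect_error(simulate_embryo(manipulation = list(type = "halve",
                                                   stage = 16)),
               "8-cell")
  expect_equal(experiment_spec("epi_apoptosis")$params$epi_apoptosis_fraction,
               0.2)
  expect_equal(
    experiment_spec("half_fgf_undetermined")$params$fgf_undetermined_weight,
    0.5)
  expect_equal(experiment_spec("drule2_delay")$schedule$fgf_delay, 1)
})

test_that("replicate seeds derive deterministically from the master seed", {
  expect_identical(replicate_seeds(7, 10), replicate_seeds(7, 10))
  expect_false(identical(replicate_seeds(7, 10), replicate_seeds(8, 10)))
  expect_equal(length(unique(replicate_seeds(1, 50))), 50)
})

test_that("small ensembles are reproducible and carry the right columns", {
  spec <- experiment_spec("wild_type", n_replicates = 2, seed = 5)
  spec$schedule <- fast_schedule()
  ens1 <- run_ensemble(spec)
  ens2 <- run_ensemble(spec)
  expect_identical(as.data.frame(ens1), as.data.frame(ens2))
  expect_true(all(c("category", "total", "icm_total", "epi_icm",
                    "apoptosis", "deep_pre_before_rule4") %in% names(ens1)))
  expect_equal(nrow(ens1), 2)
  s <- attr(ens1, "summary")
  expect_equal(s$n, 2)
})

test_that("growth conserves circles between events and respects lineages", {
  run <- simulate_embryo(schedule = fast_schedule(), seed = 55,
                         record = "events")
  allowed <- list(UNDETERMINED_ICM = c("UNDETERMINED_ICM", "TE", "EPI", "PRE"),
                  TE = "TE", EPI = c("EPI", "PRE"), PRE = c("PRE", "EPI"))
  snaps <- run$trajectory
  for (q in seq_along(snaps)[-1]) {
    prev <- snaps[[q - 1]]; cur <- snaps[[q]]
    # between special events, each division adds exactly one circle
    if (!grepl("16cell|E4.5|E3", cur$stage[1]))
      expect_equal(nrow(cur) - nrow(prev), 1)
    common <- intersect(prev$id, cur$id)
    from <- prev$lineage[match(common, prev$id)]
    to <- cur$lineage[match(common, cur$id)]
    ok <- mapply(function(f, t) t %in% allowed[[f]], from, to)
    expect_true(all(ok))
  }
  # all pairwise distances stay positive
  final <- run$embryo$pos
  expect_gt(min(dist(final)), 0)
})

test_that("a condition suite stacks category fractions per condition", {
  suite <- run_condition_suite(c("wild_type", "drule1"), n_replicates = 2,
                               seed = 9)
  # note: full-length runs are exercised in the acceptance suite; here we
  # only check the table contract
  expect_equal(nrow(suite), 2)
  expect_true(all(abs(rowSums(suite[, c("success", "no_te", "epi_only",
                                        "pre_only", "epi_in_pre",
                                        "pre_in_epi")]) - 1) < 1e-9))
})
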