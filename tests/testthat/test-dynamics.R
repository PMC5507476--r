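test_that("a pair at equilibrium distance is a fixed point", {
  dstar <- equilibrium_distance(0.6, 5)
  e <- make_embryo(rbind(c(0, 0), c(dstar, 0)), c("EPI", "EPI"))
  e2 <- step_positions(e, 100, noise = FALSE)
  expect_lt(max(abs(e2$pos - e$pos)), 1e-9)
})

test_that("overlapping cells are pushed apart by gradient descent", {
  e <- make_embryo(rbind(c(0, 0), c(1.5, 0)), c("EPI", "EPI"))
  sep <- function(x) abs(diff(x$pos[, 1]))
  d0 <- sep(e)
  for (q in 1:5) {
    e <- step_positions(e, 20, noise = FALSE)
    expect_gt(sep(e), d0)
    d0 <- sep(e)
  }
})

test_that("positional noise accumulates as a Gaussian random walk", {
  # 100 far-separated cells, no forces: displacement after n steps has
  # variance n * sd^2 per coordinate
  n_cells <- 100
  pos <- cbind(seq_len(n_cells) * 100, rep(0, n_cells))
  e <- make_embryo(pos, rep("EPI", n_cells))
  set.seed(10)
  n_steps <- 2000
  e2 <- step_positions(e, n_steps, noise = TRUE)
  disp <- as.vector(e2$pos - pos)
  expect_equal(mean(disp), 0, tolerance = 0.05)
  ratio <- var(disp) / (n_steps * (1e-3)^2)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("polarity alignment damps angle differences and keeps unit norm", {
  pos <- rbind(c(0, 0), c(2, 0))
  e <- make_embryo(pos, c("TE", "TE"),
                   pol = rbind(c(cos(0), sin(0)), c(cos(0.2), sin(0.2))))
  gap <- function(x) {
    a <- atan2(x$pol[, 2], x$pol[, 1])
    abs(a[1] - a[2])
  }
  g0 <- gap(e)
  for (q in 1:5) {
    e <- step_polarities(e, 20, noise = FALSE)
    expect_lt(gap(e), g0)
    g0 <- gap(e)
    expect_equal(sqrt(rowSums(e$pol^2)), c(1, 1), tolerance = 1e-9)
  }
  # aligned polarities are a fixed point
  ea <- make_embryo(pos, c("TE", "TE"), pol = rbind(c(0, 1), c(0, 1)))
  ea2 <- step_polarities(ea, 50, noise = FALSE)
  expect_lt(max(abs(ea2$pol - ea$pol)), 1e-9)
})

test_that("an isolated TE polarity performs a random walk of the stated size", {
  n_cells <- 80
  pos <- cbind(seq_len(n_cells) * 100, rep(0, n_cells))
  e <- make_embryo(pos, rep("TE", n_cells),
                   pol = matrix(rep(c(1, 0), each = n_cells), n_cells))
  set.seed(11)
  n_steps <- 500
  e2 <- step_polarities(e, n_steps, noise = TRUE)
  dang <- atan2(e2$pol[, 2], e2$pol[, 1])
  ratio <- var(dang) / (n_steps * (pi * 1e-3)^2)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.3)
})

test_that("relaxation converges on a small cloud and n_steps = 0 is identity", {
  set.seed(12)
  pos <- matrix(runif(20, 0, 6), 10, 2)
  e <- make_embryo(pos, rep("EPI", 10))
  e2 <- relax(e, 3000, noise = FALSE)
  expect_lt(attr(e2, "max_force") * e$params$dt, 1e-3)
  e3 <- relax(e, 0)
  expect_identical(e3$pos, e$pos)
})

test_that("energy is non-increasing under noise-free relaxation", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    pos <- matrix(runif(2 * n, 0, 8), n, 2)
    if (min(dist(pos)) < 0.4) next
    e <- make_embryo(pos, rep("EPI", n))
    en <- total_energy(e)
    for (q in 1:10) {
      e <- step_positions(e, 10, noise = FALSE)
      en2 <- total_energy(e)
      expect_lte(en2, en + 1e-9)
      en <- en2
    }
  }
})

test_that("a polarised TE ring persists over long integration", {
  ring <- ring_positions(16, 16 * 1.6 / (2 * pi))
  e <- make_embryo(ring$pos, rep("TE", 16), ring$pol)
  r0 <- mean(sqrt(rowSums(ring$pos^2)))
  set.seed(14)
  for (q in 1:10) e <- relax(e, 1000, min_steps = 1000)
  r <- sqrt(rowSums(e$pos^2))
  # no circle strays more than a cell radius from the (possibly expanded) ring
  expect_lt(max(abs(r - mean(r))), 1)
  adj <- neighbor_graph(e$pos, e$params$te_te_cutoff)
  expect_equal(blastosim:::n_components(adj), 1)
})

test_that("identical seeds give bit-identical trajectories", {
  r1 <- simulate_embryo(schedule = fast_schedule(), seed = 99)
  r2 <- simulate_embryo(schedule = fast_schedule(), seed = 99)
  expect_identical(r1$embryo$pos, r2$embryo$pos)
  expect_identical(r1$embryo$lineage, r2$embryo$lineage)
  expect_identical(r1$outcome$category, r2$outcome$category)
  r3 <- simulate_embryo(schedule = fast_schedule(), seed = 100)
  expect_false(identical(r1$embryo$pos, r3$embryo$pos))
})
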