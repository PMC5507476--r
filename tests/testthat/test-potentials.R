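test_that("the pair potential matches its closed form", {
  # exp(-2) - 0.6*exp(-0.4)
  expect_equal(pair_potential(2, 0.6, 5), -0.2668567, tolerance = 1e-6)
  # with attraction off the potential is pure repulsion
  d <- seq(0.5, 10, by = 0.5)
  expect_true(all(pair_potential(d, S = 1e-12) > 0))
  expect_error(pair_potential(0), "positive")
  expect_error(pair_potential(-1), "positive")
})

test_that("the equilibrium distance is the root of the force", {
  dstar <- equilibrium_distance(0.6, 5)
  expect_equal(dstar, 2.650330, tolerance = 1e-6)
  # independent root of dV/dd by bisection
  root <- uniroot(function(d) pair_potential_deriv(d, 0.6, 5), c(1, 10),
                  tol = 1e-12)$root
  expect_equal(dstar, root, tolerance = 1e-9)
  # repulsive below, attractive above
  expect_lt(pair_potential_deriv(dstar - 0.5, 0.6, 5), 0)
  expect_gt(pair_potential_deriv(dstar + 0.5, 0.6, 5), 0)
})

test_that("the polar attraction factor reproduces the alignment table", {
  # parallel polarities perpendicular to the separation: maximal attraction
  expect_equal(polar_attraction_factor(c(0, 1), c(0, 1), c(1, 0)), 1.4)
  # antiparallel: maximal repulsion
  expect_equal(polar_attraction_factor(c(0, 1), c(0, -1), c(1, 0)), -1.4)
  # polarity along the separation: no polar interaction
  expect_equal(polar_attraction_factor(c(1, 0), c(0, 1), c(1, 0)), 0)
  # 3D evaluation agrees with the identity pref*((e1.e2) - (e1.r)(e2.r))
  expect_equal(polar_attraction_factor(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)), 0)
  expect_equal(polar_attraction_factor(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)), 1.4)
  expect_error(polar_attraction_factor(c(0, 2), c(0, 1), c(1, 0)),
               "unit vectors")
})

test_that("the effective attraction factor follows lineage and stage", {
  pos <- rbind(c(0, 0), c(2.2, 0), c(0, 3), c(5, 5))
  e <- make_embryo(pos, c("PRE", "EPI", "PRE", "TE"),
                   pol = rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 1)))
  # before differential adhesion every non-TE pair uses the default factor
  expect_equal(effective_s(e, 1, 2)$S, 0.6)
  expect_equal(effective_s(e, 1, 3)$S, 0.6)
  # after the trigger any pair involving PrE is weakened
  e2 <- apply_rule3_adhesion(e)
  expect_equal(effective_s(e2, 1, 2)$S, 0.4)  # PrE-EPI
  expect_equal(effective_s(e2, 1, 3)$S, 0.4)  # PrE-PrE
  expect_equal(effective_s(e2, 1, 4)$S, 0.4)  # PrE-TE
  # EPI-EPI stays at the default
  e3 <- make_embryo(rbind(c(0, 0), c(2.2, 0)), c("EPI", "EPI"),
                    rule3_done = TRUE)
  expect_equal(effective_s(e3, 1, 2)$S, 0.6)
  # neutralized mode: every ICM-ICM pair gets the intermediate factor
  e4 <- make_embryo(pos, c("PRE", "EPI", "PRE", "TE"),
                    pol = rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 1)),
                    rules = rule_config(rule3_mode = "neutralized"),
                    rule3_done = TRUE)
  expect_equal(effective_s(e4, 1, 2)$S, 0.5)
  expect_equal(effective_s(e4, 2, 3)$S, 0.5)
  expect_equal(effective_s(e4, 1, 4)$S, 0.6)  # TE contacts keep the default
})

test_that("TE-TE pairs interact only within the contact cutoff", {
  ring <- ring_positions(12, 3)
  e <- make_embryo(ring$pos, rep("TE", 12), ring$pol)
  s_near <- effective_s(e, 1, 2)
  expect_true(s_near$in_range)
  s_far <- effective_s(e, 1, 6)
  expect_false(s_far$in_range)
})

test_that("forces vanish for isolated cells and at equilibrium", {
  e1 <- make_embryo(matrix(0, 1, 2), "EPI")
  expect_equal(max(abs(total_force(e1))), 0)
  dstar <- equilibrium_distance(0.6, 5)
  e2 <- make_embryo(rbind(c(0, 0), c(dstar, 0)), c("EPI", "EPI"))
  expect_lt(max(abs(total_force(e2))), 1e-9)
  # below equilibrium the pair is pushed apart
  e3 <- make_embryo(rbind(c(0, 0), c(1.5, 0)), c("EPI", "EPI"))
  F <- total_force(e3)
  expect_lt(F[1, 1], 0)
  expect_gt(F[2, 1], 0)
})

test_that("analytic forces equal the numerical energy gradient", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    lin <- sample(c("UNDETERMINED_ICM", "TE", "EPI", "PRE"), n, replace = TRUE)
    pos <- matrix(runif(2 * n, -4, 4), n, 2)
    ang <- runif(n, 0, 2 * pi)
    e <- make_embryo(pos, lin, cbind(cos(ang), sin(ang)),
                     rule3_done = sample(c(TRUE, FALSE), 1))
    if (min(dist(pos)) < 0.3) next
    expect_equal(total_force(e), numerical_force(e), tolerance = 1e-6)
  }
})

test_that("pairwise forces are antisymmetric (momentum is conserved)", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    lin <- sample(c("TE", "EPI", "PRE"), n, replace = TRUE)
    pos <- matrix(runif(2 * n, -6, 6), n, 2)
    if (min(dist(pos)) < 0.2) next
    ang <- runif(n, 0, 2 * pi)
    e <- make_embryo(pos, lin, cbind(cos(ang), sin(ang)))
    expect_lt(max(abs(colSums(total_force(e)))), 1e-12 * n * 10)
  }
})
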