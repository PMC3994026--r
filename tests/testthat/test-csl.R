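test_that("atomic propositions label states exactly", {
  bd <- bd_fixture()
  mid <- sat_atomic(bd$ss, "X >= 15 & X <= 20")
  expect_equal(sort(bd$ss$states[mid, "X"], decreasing = FALSE),
               structure(15:20, names = rep("X", 6)), ignore_attr = TRUE)
  expect_length(mid, 6)
  expect_equal(sat_atomic(bd$ss, "true"), 1:41)
  expect_length(sat_atomic(bd$ss, "X > 40"), 0)
  expect_error(sat_atomic(bd$ss, "Z > 1"))
})

test_that("until is certain when the start state already satisfies the goal", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network)
  psi <- sat_atomic(bd$ss, "X >= 20")
  i0 <- which(bd$ss$states[, "X"] == 25)
  r <- check_until(bd$ss, box, seq_len(41), psi, 0, 100)
  expect_equal(r$lower[i0], 1)
  expect_equal(r$upper[i0], 1)
})

test_that("until brackets the exact absorbed-chain oracle at parameter points", {
  net <- random_network(7)
  ss <- enumerate_states(net)
  box0 <- perturbation_box(net)
  pt <- box_midpoint(box0)
  box <- stochrob:::point_as_box(net, pt)
  n <- n_states(ss)
  phi <- which(ss$states[, 1] <= max(ss$states[, 1]) - 1)
  psi <- which(ss$states[, 1] >= max(ss$states[, 1]) - 1)
  for (tt in list(c(0, 1), c(0.5, 2))) {
    r <- check_until(ss, box, phi, psi, tt[1], tt[2], tol = 1e-10)
    oracle <- expm_until(ss, pt, phi, psi, tt[1], tt[2])
    expect_equal(r$lower, oracle, tolerance = 1e-6)
    expect_equal(r$upper, oracle, tolerance = 1e-6)
  }
})

test_that("the time-instant query brackets sampled-point probabilities", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network)
  f <- prob_op(path_until(csl_atomic("true"), csl_atomic("X >= 15 & X <= 20"),
                          1000, 1000))
  i0 <- which(bd$ss$states[, "X"] == 25)
  ev <- check_formula(bd$ss, box, f, initial_states = i0)
  sel <- bd$ss$states[, "X"] >= 15 & bd$ss$states[, "X"] <= 20
  for (k1 in c(0.055, 0.07, 0.095)) {
    d <- transient_forward(bd$ss, c(k1 = k1, k2 = 0.005), i0, 1000)
    v <- sum(d$probs[sel])
    expect_gte(v, ev$lambda_min - 1e-9)
    expect_lte(v, ev$lambda_max + 1e-9)
  }
})

test_that("globally holds with certainty when every reachable state satisfies the bound", {
  net <- reaction_network(
    species = list(species("A", 3)),
    reactions = list(
      reaction(products = c(A = 1), rate = mass_action("kp")),
      reaction(reactants = c(A = 1), rate = mass_action("kd"))),
    constants = list(kp = 1, kd = 1),
    initial_states = list(c(A = 1)))
  ss <- enumerate_states(net)
  f <- prob_op(path_globally(csl_atomic("A >= 0 & A <= 3"), 0, 5))
  ev <- check_formula(ss, perturbation_box(net), f)
  expect_equal(ev$lambda_min, 1, tolerance = 1e-7)
  expect_equal(ev$lambda_max, 1)
})

test_that("nested threshold operators match a brute-force per-state oracle", {
  net <- random_network(11)
  ss <- enumerate_states(net)
  pt <- box_midpoint(perturbation_box(net))
  box <- stochrob:::point_as_box(net, pt)
  n <- n_states(ss)
  hi <- max(ss$states[, 1])
  inner <- prob_op(path_until(csl_atomic("true"),
                              csl_atomic(paste("X >=", hi)), 0, 1),
                   cmp = ">=", r = 0.2)
  outer <- prob_op(path_until(csl_atomic("true"), inner, 0, 2))
  ev <- check_formula(ss, box, outer, initial_states = seq_len(n))
  # oracle: decide the inner operator exactly, then the outer reach
  p_inner <- expm_until(ss, pt, seq_len(n), which(ss$states[, 1] >= hi), 0, 1)
  sat_inner <- which(p_inner >= 0.2)
  oracle <- expm_until(ss, pt, seq_len(n), sat_inner, 0, 2)
  expect_true(all(ev$lambda_min <= oracle + 1e-6))
  expect_true(all(ev$lambda_max >= oracle - 1e-6))
  # away from the threshold the bracket is tight
  expect_lt(max(ev$lambda_max - ev$lambda_min), 1e-4)
})

test_that("satisfaction sets stay nested and shrink monotonically with the box", {
  bd <- bd_fixture()
  f_inner <- prob_op(path_until(csl_atomic("true"),
                                csl_atomic("X >= 15 & X <= 20"), 0, 200),
                     cmp = ">=", r = 0.5)
  for (iv in list(c(0.05, 0.1), c(0.06, 0.08), c(0.07, 0.07))) {
    box <- perturbation_box(bd$fx$network, list(k1 = iv))
    b <- check_until(bd$ss, box, seq_len(41),
                     sat_atomic(bd$ss, "X >= 15 & X <= 20"), 0, 200)
    pair <- stochrob:::threshold_sets(b$lower, b$upper, ">=", 0.5)
    expect_true(all(pair$min %in% pair$max))
  }
  wide <- perturbation_box(bd$fx$network)
  narrow <- perturbation_box(bd$fx$network, list(k1 = c(0.06, 0.07)))
  get_pair <- function(box) {
    b <- check_until(bd$ss, box, seq_len(41),
                     sat_atomic(bd$ss, "X >= 15 & X <= 20"), 0, 200)
    stochrob:::threshold_sets(b$lower, b$upper, ">=", 0.5)
  }
  pw <- get_pair(wide); pn <- get_pair(narrow)
  expect_true(all(pw$min %in% pn$min))   # sat_min grows when the box shrinks
  expect_true(all(pn$max %in% pw$max))   # sat_max shrinks
})

test_that("probability-valued results stay within [0, 1]", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network)
  for (f in list(
    prob_op(path_until(csl_atomic("true"), csl_atomic("X >= 30"), 0, 500)),
    prob_op(path_globally(csl_atomic("X <= 30"), 100, 300)))) {
    ev <- check_formula(bd$ss, box, f)
    expect_gte(ev$lambda_min, 0)
    expect_lte(ev$lambda_max, 1)
    expect_lte(ev$lambda_min, ev$lambda_max)
  }
})

test_that("cumulative rewards cover the trivial cases and a quadrature oracle", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network, list(k1 = c(0.07, 0.07)))
  n <- n_states(bd$ss)
  i0 <- which(bd$ss$states[, "X"] == 25)
  # unit reward accumulates the elapsed time exactly
  r1 <- cumulative_reward_bounded(bd$ss, box, rep(1, n), t2 = 50)
  expect_equal(r1$lower[i0], 50, tolerance = 1e-6)
  expect_equal(r1$upper[i0], 50, tolerance = 1e-6)
  # zero reward
  r0 <- cumulative_reward_bounded(bd$ss, box, rep(0, n), t2 = 50)
  expect_equal(r0$lower[i0], 0)
  expect_equal(r0$upper[i0], 0)
  # negative rewards rejected
  expect_error(cumulative_reward_bounded(bd$ss, box, rep(-1, n), t2 = 1),
               "negative")
  # indicator reward vs trapezoid integration of set probabilities
  ind <- as.numeric(bd$ss$states[, "X"] >= 15 & bd$ss$states[, "X"] <= 20)
  rr <- cumulative_reward_bounded(bd$ss, box, ind, t2 = 400)
  ts <- seq(0, 400, length.out = 801)
  vals <- vapply(ts, function(t) {
    d <- transient_forward(bd$ss, c(k1 = 0.07, k2 = 0.005), i0, t, 1e-9)
    sum(d$probs * ind)
  }, numeric(1))
  quad <- sum((vals[-1] + vals[-length(vals)]) / 2 * diff(ts))
  expect_equal(rr$lower[i0], quad, tolerance = 1e-3 * 400)
  expect_equal(rr$upper[i0], quad, tolerance = 1e-3 * 400)
})

test_that("cumulative reward is additive in the reward structure", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network, list(k1 = c(0.06, 0.06)))
  i0 <- which(bd$ss$states[, "X"] == 25)
  r1 <- as.numeric(bd$ss$states[, "X"] <= 10)
  r2 <- as.numeric(bd$ss$states[, "X"] >= 20)
  a <- cumulative_reward_bounded(bd$ss, box, r1, t2 = 200)
  b <- cumulative_reward_bounded(bd$ss, box, r2, t2 = 200)
  ab <- cumulative_reward_bounded(bd$ss, box, r1 + r2, t2 = 200)
  expect_equal(ab$lower[i0], a$lower[i0] + b$lower[i0], tolerance = 1e-6)
})

test_that("mean quadratic deviation bounds are sound and exact on point data", {
  # Dirac distribution has zero deviation
  m <- mqd_bounded(list(lower = 1, upper = 1), populations = 7)
  expect_equal(m$lower, 0)
  expect_equal(m$upper, 0)
  # exact two-point distribution
  m2 <- mqd_bounded(list(lower = c(0.5, 0.5), upper = c(0.5, 0.5)),
                    populations = c(0, 2))
  expect_equal(m2$lower, 1)
  expect_equal(m2$upper, 1)
  # random envelopes on a 10-state line: sampled feasible distributions
  set.seed(9)
  x <- 0:9
  p0 <- stats::runif(10); p0 <- p0 / sum(p0)
  l <- pmax(p0 - stats::runif(10, 0, 0.05), 0)
  u <- pmin(p0 + stats::runif(10, 0, 0.05), 1)
  m3 <- mqd_bounded(list(lower = l, upper = u), populations = x)
  samp <- sample_feasible(l, u, 2000, seed = 10)
  mqds <- apply(samp, 1, function(p) {
    mu <- sum(p * x); sum(p * (x - mu)^2)
  })
  expect_true(all(mqds >= m3$lower - 1e-9))
  expect_true(all(mqds <= m3$upper + 1e-9))
  # infeasible envelopes are rejected
  expect_error(mqd_bounded(list(lower = c(0.8, 0.9), upper = c(0.9, 0.95)),
                           populations = c(0, 1)), "infeasible")
})

test_that("reward and post-processing operators are rejected under nesting", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network)
  bad <- prob_op(path_until(csl_atomic("true"),
                            reward_op("low", t2 = 10), 0, 1))
  expect_error(check_formula(bd$ss, box, bad), "top level")
})
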