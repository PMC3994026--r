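test_that("mass-action propensity follows the combinatorial convention", {
  net <- reaction_network(
    species = list(species("X", 20)),
    reactions = list(
      reaction(reactants = c(X = 1), rate = mass_action("k")),
      reaction(reactants = c(X = 2), rate = mass_action("k2"))),
    constants = list(k = 0.1, k2 = 1),
    initial_states = list(c(X = 10)))
  expect_equal(propensity(net, 1, c(X = 10), c(k = 0.1, k2 = 1)), 1.0)
  # second order: x(x-1)
  expect_equal(propensity(net, 2, c(X = 10), c(k = 0.1, k2 = 1)), 90)
  # insufficient reactants
  expect_equal(propensity(net, 2, c(X = 1), c(k = 0.1, k2 = 1)), 0)
  # successor would violate the bound -> disabled, not clipped
  net2 <- reaction_network(
    species = list(species("X", 5)),
    reactions = list(reaction(products = c(X = 1), rate = mass_action("k"))),
    constants = list(k = 2), initial_states = list(c(X = 0)))
  expect_equal(propensity(net2, 1, c(X = 5), c(k = 2)), 0)
  expect_equal(propensity(net2, 1, c(X = 4), c(k = 2)), 2)
})

test_that("sigmoid production is k_max/2 at n = 0 and monotone in n", {
  net <- reaction_network(
    species = list(species("H", 50)),
    reactions = list(reaction(
      products = c(H = 1),
      rate = sigmoid_production("kmax", "H", midpoint = 30, hill = "n"))),
    constants = list(kmax = 1, n = c(0, 20)),
    initial_states = list(c(H = 0)))
  for (x in c(0, 10, 30, 49))
    expect_equal(propensity(net, 1, c(H = x), c(kmax = 1, n = 0)), 0.5)
  # below the midpoint production grows with n, above it shrinks
  expect_gt(propensity(net, 1, c(H = 10), c(kmax = 1, n = 5)), 0.5)
  expect_lt(propensity(net, 1, c(H = 40), c(kmax = 1, n = 5)), 0.5)
})

test_that("propensity bounds are tight for mass action and enclose a dense grid for the sigmoid", {
  net <- reaction_network(
    species = list(species("X", 10)),
    reactions = list(reaction(reactants = c(X = 1), rate = mass_action("k"))),
    constants = list(k = c(1, 2)), initial_states = list(c(X = 3)))
  expect_equal(propensity_bounds(net, 1, c(X = 3), perturbation_box(net)),
               c(3, 6))
  bp <- perturbation_box(net, list(k = c(1.5, 1.5)))
  expect_equal(propensity_bounds(net, 1, c(X = 3), bp), c(4.5, 4.5))

  sig <- reaction_network(
    species = list(species("H", 50)),
    reactions = list(reaction(
      products = c(H = 1),
      rate = sigmoid_production("kmax", "H", midpoint = 30, hill = "n"))),
    constants = list(kmax = 1, n = c(0, 20)),
    initial_states = list(c(H = 0)))
  box <- perturbation_box(sig)
  b <- propensity_bounds(sig, 1, c(H = 40), box)
  grid <- vapply(seq(0, 20, length.out = 1e4), function(n)
    propensity(sig, 1, c(H = 40), c(kmax = 1, n = n)), numeric(1))
  expect_equal(b[1], min(grid), tolerance = 1e-6)
  expect_equal(b[2], max(grid), tolerance = 1e-6)
})

test_that("propensities of sampled points always lie inside the bounds", {
  for (seed in 1:5) {
    net <- random_network(seed)
    ss <- enumerate_states(net)
    box <- perturbation_box(net)
    set.seed(seed + 100)
    pts <- replicate(20, {
      vapply(box$intervals, function(v) stats::runif(1, v[1], v[2]),
             numeric(1))
    })
    rownames(pts) <- names(box$intervals)
    states <- ss$states[sample(nrow(ss$states), min(10, nrow(ss$states))), ,
                        drop = FALSE]
    for (j in seq_along(net$reactions)) {
      for (si in seq_len(nrow(states))) {
        b <- propensity_bounds(net, j, states[si, ], box)
        for (c in seq_len(ncol(pts))) {
          v <- propensity(net, j, states[si, ], pts[, c])
          expect_gte(v, b[1] - 1e-12)
          expect_lte(v, b[2] + 1e-12)
        }
      }
    }
  }
})

test_that("state-space enumeration is bound-respecting and deterministic", {
  bd <- bd_fixture()
  expect_equal(n_states(bd$ss), 41)
  expect_equal(n_transitions(bd$ss), 80)
  expect_true(all(bd$ss$states[, "X"] >= 0 & bd$ss$states[, "X"] <= 40))
  ss2 <- enumerate_states(bd$fx$network)
  expect_identical(bd$ss$states, ss2$states)
  expect_identical(bd$ss$transitions, ss2$transitions)
  # zero-reaction network
  net0 <- reaction_network(
    species = list(species("X", 3)),
    reactions = list(),
    constants = list(), initial_states = list(c(X = 2)))
  ss0 <- enumerate_states(net0)
  expect_equal(n_states(ss0), 1)
  expect_equal(n_transitions(ss0), 0)
  # a bound is mandatory
  expect_error(species("X", NA), "bound")
})

test_that("exit-rate bound dominates sampled exit rates and degenerates to the classical maximum", {
  bd <- bd_fixture()
  box <- perturbation_box(bd$fx$network)
  q <- exit_rate_bound(bd$ss, box)
  # exhaustive max over states at sampled points
  for (k1 in seq(0.05, 0.1, length.out = 10)) {
    pt <- c(k1 = k1, k2 = 0.005)
    exits <- vapply(seq_len(n_states(bd$ss)), function(s) {
      sum(vapply(1:2, function(j)
        propensity(bd$fx$network, j, bd$ss$states[s, ], pt), numeric(1)))
    }, numeric(1))
    expect_lte(max(exits), q + 1e-12)
  }
  # degenerate box equals the classical maximal exit rate
  ptbox <- perturbation_box(bd$fx$network, list(k1 = c(0.07, 0.07)))
  exits <- vapply(seq_len(n_states(bd$ss)), function(s) {
    sum(vapply(1:2, function(j)
      propensity(bd$fx$network, j, bd$ss$states[s, ],
                 c(k1 = 0.07, k2 = 0.005)), numeric(1)))
  }, numeric(1))
  expect_equal(exit_rate_bound(bd$ss, ptbox), max(exits))
  # absorbing chain
  net0 <- reaction_network(
    species = list(species("X", 3)), reactions = list(),
    constants = list(), initial_states = list(c(X = 0)))
  expect_equal(exit_rate_bound(enumerate_states(net0)), 0)
})
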