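# A landscape object with prescribed per-subspace bounds (used to test
# the robustness definitions independently of the model checker).
stub_landscape <- function(lo, hi, breaks = NULL, dim = "k") {
  m <- length(lo)
  if (is.null(breaks)) breaks <- seq(0, 1, length.out = m + 1)
  sub <- data.frame(lo = breaks[-(m + 1)], hi = breaks[-1],
                    lambda_min = lo, lambda_max = hi,
                    depth = 0L, volume = diff(breaks))
  names(sub)[1:2] <- paste0(dim, c("_lo", "_hi"))
  structure(list(subspaces = sub, dims = dim, err_bound = NA,
                 achieved_err = sum(diff(breaks) * (hi - lo)) /
                   sum(diff(breaks))),
            class = "stochrob_landscape")
}

test_that("a constant evaluation function gives the worked threshold-relative value", {
  ls <- stub_landscape(lo = 0.6, hi = 0.6)
  rd <- robustness_degree(ls, "1b", r = 0.8)
  expect_equal(rd$r_min, 0.75)
  expect_equal(rd$r_max, 0.75)
  # definition consistency: 1b equals 1c / r
  rc <- robustness_degree(ls, "1c")
  expect_equal(rd$r_min, rc$r_min / 0.8)
})

test_that("qualitative robustness counts decided and undecided volumes soundly", {
  # three equal subspaces: holds / undecided / fails for r = 0.5
  ls <- stub_landscape(lo = c(0.8, 0.3, 0.1), hi = c(0.9, 0.7, 0.2))
  rd <- robustness_degree(ls, "1a", r = 0.5)
  expect_equal(rd$r_min, 1 / 3)
  expect_equal(rd$r_max, 2 / 3)
  # property holding everywhere
  all_hold <- stub_landscape(lo = c(0.8, 0.9), hi = c(0.85, 0.95))
  rda <- robustness_degree(all_hold, "1a", r = 0.5)
  expect_equal(rda$r_min, 1)
  expect_equal(rda$r_max, 1)
  # the mirrored comparison
  rdl <- robustness_degree(ls, "1a", r = 0.5, cmp = "<=")
  expect_equal(rdl$r_min, 1 / 3)
  expect_equal(rdl$r_max, 2 / 3)
  expect_error(robustness_degree(ls, "1a"), "threshold")
})

test_that("absolute-mean robustness brackets the exact integral of a linear landscape", {
  # evaluation function lambda(k) = k on [0, 1], 32 exact subspace bounds
  m <- 32
  br <- seq(0, 1, length.out = m + 1)
  ls <- stub_landscape(lo = br[-(m + 1)], hi = br[-1], breaks = br)
  rd <- robustness_degree(ls, "1c")
  expect_lte(rd$r_min, 0.5)
  expect_gte(rd$r_max, 0.5)
  expect_lte(rd$r_max - rd$r_min, 1 / m + 1e-12)
  # 1d adds a non-negative variance estimate and is flagged approximate
  rd4 <- robustness_degree(ls, "1d")
  expect_true(rd4$approximate)
  expect_gte(rd4$variance_estimate, 0)
})

test_that("refinement terminates in one subspace when the formula ignores the perturbed constant", {
  # the perturbed constant drives a reaction that can never fire
  net <- reaction_network(
    species = list(species("X", 5)),
    reactions = list(
      reaction(products = c(X = 1), rate = mass_action("kp")),
      reaction(reactants = c(X = 1), rate = mass_action("kd")),
      reaction(reactants = c(X = 6), rate = mass_action("k_dead"))),
    constants = list(kp = 1, kd = 1, k_dead = c(0.1, 10)),
    initial_states = list(c(X = 0)))
  ss <- enumerate_states(net)
  f <- prob_op(path_until(csl_atomic("true"), csl_atomic("X >= 3"), 0, 2))
  ls <- refine_landscape(ss, f, perturbation_box(net), err_bound = 1e-4,
                         max_depth = 8)
  expect_equal(nrow(ls$subspaces), 1)
  expect_lte(ls$achieved_err, 1e-4)
})

test_that("forced decompositions shrink the overall error monotonically", {
  bd <- bd_fixture()
  f <- bd$fx$properties$mid_at_1000
  box <- perturbation_box(bd$fx$network)
  errs <- vapply(1:4, function(d) {
    ls <- suppressWarnings(
      refine_landscape(bd$ss, f, box, err_bound = 1e-9, max_depth = d))
    expect_equal(nrow(ls$subspaces), 2^d)
    ls$achieved_err
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("subspace volumes partition the root box and errors are volume-weighted widths", {
  bd <- bd_fixture()
  f <- bd$fx$properties$mid_at_1000
  box <- perturbation_box(bd$fx$network)
  ls <- suppressWarnings(
    refine_landscape(bd$ss, f, box, err_bound = 0.1, max_depth = 6))
  expect_equal(sum(ls$subspaces$volume), 0.05, tolerance = 1e-12)
  manual <- sum(ls$subspaces$volume / 0.05 *
                (ls$subspaces$lambda_max - ls$subspaces$lambda_min))
  expect_equal(ls$achieved_err, manual)
  # a stricter request never worsens the achieved error
  ls2 <- suppressWarnings(
    refine_landscape(bd$ss, f, box, err_bound = 0.05, max_depth = 6))
  expect_lte(ls2$achieved_err, ls$achieved_err + 1e-12)
  # degenerate root box is rejected
  expect_error(refine_landscape(bd$ss, f,
                                perturbation_box(bd$fx$network,
                                                 list(k1 = c(0.07, 0.07))),
                                err_bound = 0.1), "zero volume")
})

test_that("mean robustness of the time-instant query brackets a Monte-Carlo integral", {
  bd <- bd_fixture()
  f <- bd$fx$properties$mid_at_1000
  box <- perturbation_box(bd$fx$network)
  ls <- suppressWarnings(
    refine_landscape(bd$ss, f, box, err_bound = 1e-9, max_depth = 4))
  rd <- robustness_degree(ls, "1c")
  i0 <- which(bd$ss$states[, "X"] == 25)
  sel <- bd$ss$states[, "X"] >= 15 & bd$ss$states[, "X"] <= 20
  set.seed(7)
  mc <- mean(vapply(stats::runif(400, 0.05, 0.1), function(k1) {
    d <- transient_forward(bd$ss, c(k1 = k1, k2 = 0.005), i0, 1000)
    sum(d$probs[sel])
  }, numeric(1)))
  expect_gte(mc, rd$r_min - 1e-9)
  expect_lte(mc, rd$r_max + 1e-9)
})

test_that("initial-state averaging reduces to the single-state analysis and to hand-computed means", {
  net <- random_network(5)
  ss <- enumerate_states(net)
  f <- prob_op(path_until(csl_atomic("true"),
                          csl_atomic(paste("X >=", max(ss$states[, 1]))),
                          0, 1.5))
  pt <- box_midpoint(perturbation_box(net))
  box <- stochrob:::point_as_box(net, pt)
  box$intervals[[1]][2] <- box$intervals[[1]][2] * 1.5  # one uncertain dim
  s3 <- seq_len(min(3, n_states(ss)))
  r3 <- robustness_over_initial_states(ss, f, box, s3, "1c",
                                       err_bound = 0.02, max_depth = 8)
  singles <- vapply(s3, function(s) {
    r1 <- robustness_over_initial_states(ss, f, box, s, "1c",
                                         err_bound = 0.02, max_depth = 8)
    c(r1$r_min, r1$r_max)
  }, numeric(2))
  expect_equal(r3$r_min, mean(singles[1, ]), tolerance = 1e-9)
  expect_equal(r3$r_max, mean(singles[2, ]), tolerance = 1e-9)
  # duplicated initial states average to the same value
  rdup <- robustness_over_initial_states(ss, f, box, c(s3[1], s3[1]), "1c",
                                         err_bound = 0.02, max_depth = 8)
  r1 <- robustness_over_initial_states(ss, f, box, s3[1], "1c",
                                       err_bound = 0.02, max_depth = 8)
  expect_equal(rdup$r_min, r1$r_min)
  expect_equal(rdup$r_max, r1$r_max)
})

test_that("piece-wise linear refinement reproduces constant and linear landscapes", {
  cls <- stub_landscape(lo = rep(0.4, 4), hi = rep(0.4, 4))
  p <- pla_refine(cls)
  expect_true(all(p$grid$lo == 0.4 & p$grid$hi == 0.4))
  # exactly linear lambda(k) = k with exact per-box bounds
  m <- 8
  br <- seq(0, 1, length.out = m + 1)
  lin <- stub_landscape(lo = br[-(m + 1)], hi = br[-1], breaks = br)
  pl <- pla_refine(lin)
  # interior grid points intersect two boxes and recover the line exactly;
  # the two border points keep their single box's interval width
  interior <- 2:(nrow(pl$grid) - 1)
  expect_equal(pl$grid$mid[interior], pl$grid$point[interior],
               tolerance = 1e-12)
  expect_lte(max(abs(pl$grid$mid - pl$grid$point)), 1 / m)
  # grid-point intersection is never wider than either incident interval
  bd <- bd_fixture()
  f <- bd$fx$properties$mid_at_1000
  ls <- suppressWarnings(refine_landscape(bd$ss, f,
                                          perturbation_box(bd$fx$network),
                                          err_bound = 1e-9, max_depth = 3))
  pg <- pla_refine(ls)$grid
  sub <- ls$subspaces
  for (i in seq_len(nrow(pg))) {
    inc <- which(sub$k1_lo <= pg$point[i] + 1e-12 &
                 sub$k1_hi >= pg$point[i] - 1e-12)
    w <- pg$hi[i] - pg$lo[i]
    expect_lte(w, min(sub$lambda_max[inc] - sub$lambda_min[inc]) + 1e-12)
  }
})
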