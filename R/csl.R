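# Bounded-time stochastic logic with rewards and post-processing,
# evaluated in min-max fashion over a perturbation box.
#
# The quantitative value of the top-level operator is bracketed by
# [lambda_min, lambda_max]; nested threshold operators yield a
# three-valued state classification carried as a pair of satisfaction
# sets (sat_min: holds for every point of the box; sat_max: holds for
# some point), and outer path probabilities are bracketed by evaluating
# against the (sat_min, sat_max) completions that give guaranteed outer
# bounds.

# ---- formula constructors -------------------------------------------------

#' Atomic proposition over state populations
#' @param predicate Character predicate over species names (e.g.
#'   `"X >= 15 & X <= 20"`, `"true"`) or a function of the state matrix.
#' @return Formula node.
#' @export
csl_atomic <- function(predicate)
  structure(list(type = "ap", predicate = predicate), class = "stochrob_formula")

#' Boolean connectives
#' @param phi,psi Formula nodes.
#' @return Formula node.
#' @export
csl_not <- function(phi)
  structure(list(type = "not", phi = phi), class = "stochrob_formula")

#' @rdname csl_not
#' @export
csl_and <- function(phi, psi)
  structure(list(type = "and", phi = phi, psi = psi), class = "stochrob_formula")

#' @rdname csl_not
#' @export
csl_or <- function(phi, psi)
  structure(list(type = "or", phi = phi, psi = psi), class = "stochrob_formula")

#' Time-bounded until path formula
#' @param phi,psi State formulas.
#' @param t1,t2 Finite time bounds, `0 <= t1 <= t2`.
#' @return Path-formula node.
#' @export
path_until <- function(phi, psi, t1, t2) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 < 0 || t1 > t2 ||
      !is.finite(t2))
    stop("until needs finite bounds 0 <= t1 <= t2", call. = FALSE)
  structure(list(type = "until", phi = phi, psi = psi, t1 = t1, t2 = t2),
            class = "stochrob_path")
}

#' Time-bounded globally path formula (dual of until)
#' @inheritParams path_until
#' @return Path-formula node.
#' @export
path_globally <- function(phi, t1, t2) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 < 0 || t1 > t2 ||
      !is.finite(t2))
    stop("globally needs finite bounds 0 <= t1 <= t2", call. = FALSE)
  structure(list(type = "globally", phi = phi, t1 = t1, t2 = t2),
            class = "stochrob_path")
}

#' Probability operator
#' @param path A [path_until()] or [path_globally()] node.
#' @param cmp One of `">="`, `"<="`, `">"`, `"<"`, or `"=?"` (query).
#' @param r Probability threshold in `[0, 1]` (ignored for `"=?"`).
#' @return Formula node.
#' @export
prob_op <- function(path, cmp = "=?", r = NULL) {
  stopifnot(inherits(path, "stochrob_path"),
            cmp %in% c(">=", "<=", ">", "<", "=?"))
  if (cmp != "=?" && (is.null(r) || r < 0 || r > 1))
    stop("threshold r must lie in [0, 1]", call. = FALSE)
  structure(list(type = "prob", cmp = cmp, r = r, path = path),
            class = "stochrob_formula")
}

#' Cumulative-reward operator (top level only)
#' @param reward Name of a state-reward structure (resolved against the
#'   `rewards` argument of [check_formula()]) or a numeric reward-rate
#'   vector over states.
#' @param t2 End of the accumulation window.
#' @param t1 Start of the accumulation window (default 0; `C <= t` is
#'   `[0, t]`).
#' @param cmp Comparison or `"=?"`.
#' @param r Threshold (for comparisons).
#' @return Formula node.
#' @export
reward_op <- function(reward, t2, t1 = 0, cmp = "=?", r = NULL) {
  stopifnot(t1 >= 0, t2 >= t1, is.finite(t2),
            cmp %in% c(">=", "<=", ">", "<", "=?"))
  structure(list(type = "reward", reward = reward, t1 = t1, t2 = t2,
                 cmp = cmp, r = r),
            class = "stochrob_formula")
}

#' Post-processing operator: mean quadratic deviation at a time instant
#' @param species Species whose population distribution is summarised.
#' @param t Time instant.
#' @param cmp Comparison or `"=?"`.
#' @param r Threshold (for comparisons).
#' @return Formula node.
#' @export
mqd_op <- function(species, t, cmp = "=?", r = NULL) {
  stopifnot(t >= 0, is.finite(t), cmp %in% c(">=", "<=", ">", "<", "=?"))
  structure(list(type = "mqd", species = species, t = t, cmp = cmp, r = r),
            class = "stochrob_formula")
}

# ---- satisfaction-set machinery -------------------------------------------

# sat pair: list(min = indices, max = indices), sat_min subseteq sat_max
sat_pair <- function(min_idx, max_idx) {
  stopifnot(all(min_idx %in% max_idx))
  list(min = sort(unique(min_idx)), max = sort(unique(max_idx)))
}

sat_complement <- function(pair, n)
  sat_pair(setdiff(seq_len(n), pair$max), setdiff(seq_len(n), pair$min))

sat_intersect <- function(a, b)
  sat_pair(intersect(a$min, b$min), intersect(a$max, b$max))

sat_union <- function(a, b)
  sat_pair(union(a$min, b$min), union(a$max, b$max))

threshold_sets <- function(lo, hi, cmp, r) {
  switch(cmp,
    ">=" = sat_pair(which(lo >= r), which(hi >= r)),
    ">"  = sat_pair(which(lo > r),  which(hi > r)),
    "<=" = sat_pair(which(hi <= r), which(lo <= r)),
    "<"  = sat_pair(which(hi < r),  which(lo < r)),
    stop("threshold comparison required", call. = FALSE))
}

# ---- until ----------------------------------------------------------------

#' Bounded-until probability bounds over a box
#'
#' Standard two-phase reduction to backward transient analysis: during
#' `[0, t1]` states violating phi absorb failure; during `(t1, t2]`
#' states satisfying psi absorb success and states violating phi absorb
#' failure.  Under a box, the lower envelope uses the pessimistic
#' satisfaction sets (sat_min of phi and psi) and the upper envelope the
#' optimistic ones, which brackets the true probability for every
#' parameter point and every start state.
#'
#' @param state_space,box,tol As in [transient_forward_bounded()].
#' @param phi_pair,psi_pair Satisfaction-set pairs `list(min=, max=)` of
#'   the operand state formulas (plain index vectors are treated as exact
#'   sets).
#' @param t1,t2 Time bounds, `0 <= t1 <= t2`.
#' @return List `lower`, `upper`: per-start-state probability bounds.
#' @export
check_until <- function(state_space, box, phi_pair, psi_pair, t1, t2,
                        tol = 1e-8) {
  if (t1 > t2) stop("until needs t1 <= t2", call. = FALSE)
  n <- n_states(state_space)
  as_pair <- function(x) if (is.list(x)) x else sat_pair(x, x)
  phi <- as_pair(phi_pair); psi <- as_pair(psi_pair)

  one_side <- function(phi_set, psi_set, side) {
    # phase 2: duration t2 - t1, absorb psi (success) and not-phi (failure)
    u0 <- numeric(n); u0[psi_set] <- 1
    absorb2 <- union(psi_set, setdiff(seq_len(n), phi_set))
    dt <- t2 - t1
    sigma <- if (dt > 0) {
      r <- backward_pass(state_space, box, u0, u0, dt, tol,
                         absorbing_lo = absorb2, absorbing_hi = absorb2)
      if (side == "lo") r$lo else pmin(r$hi, 1)
    } else u0
    # phase 1: duration t1, absorb not-phi; value 0 outside phi
    if (t1 > 0) {
      v0 <- sigma
      v0[setdiff(seq_len(n), phi_set)] <- 0
      absorb1 <- setdiff(seq_len(n), phi_set)
      r <- backward_pass(state_space, box, v0, v0, t1, tol,
                         absorbing_lo = absorb1, absorbing_hi = absorb1)
      if (side == "lo") r$lo else pmin(r$hi, 1)
    } else sigma
  }
  list(lower = one_side(phi$min, psi$min, "lo"),
       upper = one_side(phi$max, psi$max, "hi"))
}

# ---- rewards --------------------------------------------------------------

#' Expected cumulative reward bounds over a box
#'
#' Bounds on `E[ integral_{t1}^{t2} rho(X_u) du ]` for every parameter
#' point of the box, for every start state, via the uniformisation
#' reward recurrence driven by the bounded backward step vectors.
#'
#' @inheritParams check_until
#' @param state_reward Non-negative reward-rate vector over states.
#' @param t2,t1 Accumulation window (default start 0).
#' @return List `lower`, `upper` over start states.
#' @export
cumulative_reward_bounded <- function(state_space, box, state_reward, t2,
                                      t1 = 0, tol = 1e-8) {
  stopifnot(t2 > 0, t1 >= 0, t1 <= t2)
  rho <- as.numeric(state_reward)
  stopifnot(length(rho) == n_states(state_space))
  if (any(rho < 0)) stop("negative state rewards are not supported", call. = FALSE)
  rmax <- max(rho)
  if (rmax == 0)
    return(list(lower = numeric(n_states(state_space)),
                upper = numeric(n_states(state_space))))
  q <- exit_rate_bound(state_space, box)
  if (q == 0) {
    v <- rho * (t2 - t1)
    return(list(lower = v, upper = v))
  }
  r <- backward_pass(state_space, box, rho, rho, NA, tol,
                     clamp_hi = rmax,
                     reward_window_spec = list(t1 = t1, t2 = t2))
  list(lower = pmax(r$lo, 0), upper = pmin(r$hi, rmax * (t2 - t1)))
}

# ---- mean quadratic deviation ---------------------------------------------

# extremise a linear functional over the transfer polytope
# { l <= p <= u, sum p = 1 } by fractional knapsack
knapsack_moment <- function(coef, l, u, maximise = TRUE) {
  budget <- 1 - sum(l)
  if (budget < -1e-9 || sum(u) < 1 - 1e-9)
    stop("infeasible distribution bounds (sum lower > 1 or sum upper < 1)",
         call. = FALSE)
  budget <- max(budget, 0)
  p <- l
  ord <- order(coef, decreasing = maximise)
  for (i in ord) {
    if (budget <= 0) break
    add <- min(u[i] - l[i], budget)
    p[i] <- p[i] + add
    budget <- budget - add
  }
  sum(coef * p)
}

#' Mean-quadratic-deviation bounds from a bounded distribution
#'
#' Conservative bounds on `sum_s p_s (x_s - mu)^2` with
#' `mu = sum_s p_s x_s`, guaranteed for every distribution compatible
#' with the per-state envelopes and summing to one.  First and second
#' moments are extremised over the feasible polytope (fractional
#' knapsack), then combined as the interval `E[X^2] - mu^2` with `mu`
#' ranging over its own bounds.
#'
#' @param bounded_dist A `stochrob_bounded_distribution` (or a list with
#'   `lower`, `upper`).
#' @param species Species name (populations taken from the state space)
#'   — or supply `populations` directly.
#' @param state_space State space providing populations (optional when
#'   `populations` given).
#' @param populations Numeric vector of per-state values to summarise.
#' @return List `lower`, `upper`.
#' @export
mqd_bounded <- function(bounded_dist, species = NULL, state_space = NULL,
                        populations = NULL) {
  l <- bounded_dist$lower; u <- bounded_dist$upper
  if (is.null(populations)) {
    stopifnot(!is.null(species), !is.null(state_space))
    populations <- as.numeric(state_space$states[, species])
  }
  x <- as.numeric(populations)
  stopifnot(length(x) == length(l))
  m1_lo <- knapsack_moment(x, l, u, maximise = FALSE)
  m1_hi <- knapsack_moment(x, l, u, maximise = TRUE)
  m2_lo <- knapsack_moment(x^2, l, u, maximise = FALSE)
  m2_hi <- knapsack_moment(x^2, l, u, maximise = TRUE)
  # x >= 0 so mu^2 is monotone on [m1_lo, m1_hi]
  list(lower = max(0, m2_lo - m1_hi^2), upper = max(0, m2_hi - m1_lo^2))
}

# ---- formula evaluation ---------------------------------------------------

#' Evaluate a formula over a box: guaranteed value bounds
#'
#' Bottom-up min-max evaluation.  A top-level threshold is ignored for
#' the quantitative value but reported as a three-valued qualitative
#' status.  Reward and post-processing operators are only admitted at
#' the top level.
#'
#' @param state_space A state space from [enumerate_states()].
#' @param box A [perturbation_box()].
#' @param formula A formula node.
#' @param initial_states Indices into the state space rows (defaults to
#'   the network's initial states).
#' @param tol Truncation tolerance.
#' @param rewards Named list of state-reward vectors (for named
#'   [reward_op()] structures); entries may also be character predicates
#'   interpreted as indicator rewards.
#' @return A `stochrob_evaluation`: `lambda_min`, `lambda_max` (vectors
#'   over initial states), `qualitative` (one of `"valid-for-all"`,
#'   `"invalid-for-all"`, `"undecided"`, or `NA` for queries).
#' @export
check_formula <- function(state_space, box, formula,
                          initial_states = state_space$initial,
                          tol = 1e-8, rewards = list()) {
  n <- n_states(state_space)
  stopifnot(all(initial_states >= 1), all(initial_states <= n))

  # recursive: state formulas -> sat pairs
  eval_state <- function(f) {
    switch(f$type,
      ap = {
        idx <- sat_atomic(state_space, f$predicate)
        sat_pair(idx, idx)
      },
      not = sat_complement(eval_state(f$phi), n),
      and = sat_intersect(eval_state(f$phi), eval_state(f$psi)),
      or  = sat_union(eval_state(f$phi), eval_state(f$psi)),
      prob = {
        if (f$cmp == "=?")
          stop("nested probability operators need a threshold", call. = FALSE)
        b <- eval_path(f$path)
        threshold_sets(b$lower, b$upper, f$cmp, f$r)
      },
      reward = ,
      mqd = stop("reward/post-processing operators are only supported at ",
                 "the top level", call. = FALSE),
      stop("unknown formula node '", f$type, "'", call. = FALSE))
  }

  eval_path <- function(p) {
    if (p$type == "until") {
      check_until(state_space, box, eval_state(p$phi), eval_state(p$psi),
                  p$t1, p$t2, tol)
    } else {  # globally: dual of until on the negation
      notphi <- sat_complement(eval_state(p$phi), n)
      alltrue <- sat_pair(seq_len(n), seq_len(n))
      b <- check_until(state_space, box, alltrue, notphi, p$t1, p$t2, tol)
      list(lower = pmax(1 - b$upper, 0), upper = pmin(1 - b$lower, 1))
    }
  }

  resolve_reward <- function(rw) {
    if (is.numeric(rw)) {
      stopifnot(length(rw) == n)
      return(as.numeric(rw))
    }
    if (is.character(rw) && length(rw) == 1L) {
      if (!is.null(rewards[[rw]])) {
        r <- rewards[[rw]]
        if (is.character(r)) {
          v <- numeric(n); v[sat_atomic(state_space, r)] <- 1
          return(v)
        }
        stopifnot(length(r) == n)
        return(as.numeric(r))
      }
      lbl <- state_space$network$labels
      if (!is.null(lbl) && rw %in% names(lbl)) {
        v <- numeric(n); v[sat_atomic(state_space, lbl[[rw]])] <- 1
        return(v)
      }
      stop("unknown reward structure '", rw, "'", call. = FALSE)
    }
    stop("invalid reward specification", call. = FALSE)
  }

  top <- formula
  if (top$type %in% c("ap", "not", "and", "or")) {
    pair <- eval_state(top)
    lo <- as.numeric(initial_states %in% pair$min)
    hi <- as.numeric(initial_states %in% pair$max)
    return(new_evaluation(lo, hi, "=?", NULL, initial_states))
  }
  if (top$type == "prob") {
    b <- eval_path(top$path)
    return(new_evaluation(b$lower[initial_states], b$upper[initial_states],
                          top$cmp, top$r, initial_states))
  }
  if (top$type == "reward") {
    rho <- resolve_reward(top$reward)
    b <- cumulative_reward_bounded(state_space, box, rho, top$t2, top$t1, tol)
    return(new_evaluation(b$lower[initial_states], b$upper[initial_states],
                          top$cmp, top$r, initial_states))
  }
  if (top$type == "mqd") {
    lo <- numeric(length(initial_states)); hi <- numeric(length(initial_states))
    for (i in seq_along(initial_states)) {
      bd <- transient_forward_bounded(state_space, box, initial_states[i],
                                      top$t, tol)
      m <- mqd_bounded(bd, species = top$species, state_space = state_space)
      lo[i] <- m$lower; hi[i] <- m$upper
    }
    return(new_evaluation(lo, hi, top$cmp, top$r, initial_states))
  }
  stop("unknown formula node '", top$type, "'", call. = FALSE)
}

new_evaluation <- function(lo, hi, cmp, r, initial_states) {
  qual <- NA_character_
  if (!is.null(r) && cmp != "=?") {
    ge <- cmp %in% c(">=", ">")
    holds_all <- if (ge) all(lo >= r) else all(hi <= r)
    fails_all <- if (ge) all(hi < r) else all(lo > r)
    qual <- if (holds_all) "valid-for-all" else
      if (fails_all) "invalid-for-all" else "undecided"
  }
  structure(list(lambda_min = lo, lambda_max = hi, cmp = cmp, r = r,
                 qualitative = qual, initial_states = initial_states),
            class = "stochrob_evaluation")
}

#' @export
print.stochrob_evaluation <- function(x, ...) {
  cat("Evaluation bounds over", length(x$lambda_min), "initial state(s):\n")
  cat("  lambda_min:", paste(format(x$lambda_min, digits = 6), collapse = " "), "\n")
  cat("  lambda_max:", paste(format(x$lambda_max, digits = 6), collapse = " "), "\n")
  if (!is.na(x$qualitative))
    cat("  threshold", x$cmp, x$r, "->", x$qualitative, "\n")
  invisible(x)
}
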