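# Transient analysis by (parameterised) uniformisation.
#
# Classical uniformisation writes the transient distribution as a
# Poisson-weighted sum of powers of the uniformised matrix P = I + Q/q.
# The parameterised variant propagates per-state lower/upper envelopes
# valid for every rate-constant point in a perturbation box; the envelopes
# are extremised locally (per state, per step), which is what makes them
# conservative rather than attained by any single chain.

# ---- term groups ----------------------------------------------------------

# Split the transition list of a state space into the structures the C++
# kernels consume: one group per mass-action rate constant (transitions
# sharing that constant, with the combinatorial population term as the
# coefficient) plus per-transition rate intervals for sigmoid laws.
# `drop_src`: states whose outgoing transitions are removed (absorbing).
build_terms <- function(state_space, box, drop_src = NULL) {
  net <- state_space$network
  tr <- state_space$transitions
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(drop_src) && length(drop_src))
    keep <- !(tr$src %in% drop_src)

  ma_kind <- vapply(net$reactions, function(r) r$rate$kind == "mass_action",
                    logical(1))
  groups <- list()
  consts <- unique(vapply(net$reactions[ma_kind], function(r) r$rate$constant,
                          character(1)))
  for (cn in consts) {
    rxns <- which(ma_kind & vapply(net$reactions, function(r)
      r$rate$constant == cn, logical(1)))
    idx <- which(keep & tr$reaction %in% rxns)
    if (!length(idx)) next
    a <- numeric(length(idx))
    for (j in rxns) {
      sel <- tr$reaction[idx] == j
      if (!any(sel)) next
      r <- net$reactions[[j]]
      S <- state_space$states[tr$src[idx[sel]], , drop = FALSE]
      aj <- rep(1, sum(sel))
      for (nm in names(r$reactants)) {
        rc <- r$reactants[[nm]]
        aj <- aj * choose(S[, nm], rc) * factorial(rc)
      }
      a[sel] <- aj
    }
    kiv <- box$intervals[[cn]]
    groups[[length(groups) + 1L]] <-
      list(src = tr$src[idx] - 1L, dst = tr$dst[idx] - 1L, alpha = a,
           klo = kiv[1], khi = kiv[2])
  }

  sig_src <- integer(); sig_dst <- integer()
  sig_rlo <- numeric(); sig_rhi <- numeric()
  for (j in which(!ma_kind)) {
    idx <- which(keep & tr$reaction == j)
    if (!length(idx)) next
    r <- net$reactions[[j]]
    kiv <- box$intervals[[r$rate$constant]]
    niv <- box$intervals[[r$rate$hill]]
    S <- state_space$states[tr$src[idx], , drop = FALSE]
    x <- rowSums(S[, r$rate$total, drop = FALSE])
    s1 <- vapply(x, sigmoid_value, numeric(1), theta = r$rate$midpoint, n = niv[1])
    s2 <- vapply(x, sigmoid_value, numeric(1), theta = r$rate$midpoint, n = niv[2])
    sig_src <- c(sig_src, tr$src[idx] - 1L)
    sig_dst <- c(sig_dst, tr$dst[idx] - 1L)
    sig_rlo <- c(sig_rlo, kiv[1] * pmin(s1, s2))
    sig_rhi <- c(sig_rhi, kiv[2] * pmax(s1, s2))
  }

  # uniformisation constant from the *unmodified* chain is also fine, but
  # the terms carry their own exits; q is supplied separately
  list(groups = groups, sig_src = sig_src, sig_dst = sig_dst,
       sig_rlo = sig_rlo, sig_rhi = sig_rhi)
}

# ---- Poisson windows ------------------------------------------------------

# Truncated Poisson(lambda) weights with total retained mass >= 1 - tol
# (or as close as floating point permits; the retained mass is reported
# and the dropped remainder is charged to the upper envelope).
poisson_window <- function(lambda, tol) {
  if (tol <= 0) stop("truncation tolerance must be > 0", call. = FALSE)
  if (lambda == 0)
    return(list(right = 0L, weights = 1, mass = 1))
  right <- stats::qpois(1 - tol / 2, lambda)
  cap <- as.integer(lambda + 12 * sqrt(lambda) + 1000)
  w <- stats::dpois(0:right, lambda)
  while (sum(w) < 1 - tol && right < cap) {
    right <- min(cap, right + max(10L, as.integer(0.05 * right)))
    w <- stats::dpois(0:right, lambda)
  }
  list(right = right, weights = w, mass = sum(w))
}

# Weights for expected cumulative reward over the window [t1, t2]:
# integral of the step-i occupancy is (P(N_{q t2} > i) - P(N_{q t1} > i))/q.
# Returns weights w[0..right] and an upper bound on the truncated tail.
reward_window <- function(q, t1, t2, tol) {
  if (tol <= 0) stop("truncation tolerance must be > 0", call. = FALSE)
  l2 <- q * t2
  if (l2 == 0) return(list(right = 0L, weights = 0, tail = 0))
  right <- stats::qpois(1 - min(tol, 1e-12), l2) + 10L
  i <- 0:right
  w <- (stats::ppois(i, l2, lower.tail = FALSE) -
        stats::ppois(i, q * t1, lower.tail = FALSE)) / q
  # tail sum_{i > right} P(N_{l2} > i) = E[(N - right - 1)^+]
  m <- right + 1
  tail <- (l2 * stats::ppois(m - 1, l2, lower.tail = FALSE) -
           m * stats::ppois(m, l2, lower.tail = FALSE)) / q
  list(right = right, weights = pmax(w, 0), tail = max(tail, 0))
}

# ---- forward --------------------------------------------------------------

#' Classical transient distribution at a parameter point
#'
#' Standard uniformisation, truncated so the dropped Poisson mass is at
#' most `tol`.
#'
#' @param state_space A state space from [enumerate_states()].
#' @param point Named numeric vector of rate-constant values (see
#'   [box_point()]).
#' @param init_dist Initial distribution: a probability vector over
#'   states, or a single state index.
#' @param t Time horizon (>= 0).
#' @param tol Poisson truncation tolerance.
#' @return A `stochrob_distribution`: `probs`, `time`.
#' @export
transient_forward <- function(state_space, point, init_dist, t, tol = 1e-8) {
  box <- point_as_box(state_space$network, point)
  bd <- transient_forward_bounded(state_space, box, init_dist, t, tol)
  structure(list(probs = bd$lower, time = t), class = "stochrob_distribution")
}

point_as_box <- function(network, point) {
  iv <- lapply(names(point), function(nm) c(point[[nm]], point[[nm]]))
  names(iv) <- names(point)
  b <- perturbation_box(network)
  for (nm in names(iv)) {
    if (!nm %in% names(b$intervals))
      stop("unknown constant '", nm, "'", call. = FALSE)
    b$intervals[[nm]] <- iv[[nm]]
  }
  if (!box_is_point(b))
    stop("point must fix every uncertain constant", call. = FALSE)
  b
}

as_init_vector <- function(state_space, init_dist) {
  n <- n_states(state_space)
  if (length(init_dist) == 1L && init_dist == floor(init_dist) &&
      init_dist >= 1 && init_dist <= n && is.null(names(init_dist))) {
    v <- numeric(n); v[init_dist] <- 1
    return(v)
  }
  stopifnot(length(init_dist) == n, all(init_dist >= 0))
  as.numeric(init_dist)
}

#' Guaranteed transient envelopes over a perturbation box
#'
#' Per-state lower and upper bounds on the transient distribution valid
#' simultaneously for every rate-constant point in `box`.
#'
#' @inheritParams transient_forward
#' @param box A [perturbation_box()].
#' @return A `stochrob_bounded_distribution`: `lower`, `upper`, `time`,
#'   `box`.
#' @export
transient_forward_bounded <- function(state_space, box, init_dist, t,
                                      tol = 1e-8) {
  stopifnot(t >= 0)
  if (tol <= 0) stop("truncation tolerance must be > 0", call. = FALSE)
  v0 <- as_init_vector(state_space, init_dist)
  n <- n_states(state_space)
  if (t == 0 || nrow(state_space$transitions) == 0L)
    return(structure(list(lower = v0, upper = v0, time = t, box = box),
                     class = "stochrob_bounded_distribution"))
  q <- exit_rate_bound(state_space, box)
  if (q == 0)
    return(structure(list(lower = v0, upper = v0, time = t, box = box),
                     class = "stochrob_bounded_distribution"))
  terms <- build_terms(state_space, box)
  # the truncated mass is charged to every state's upper bound, so the
  # window is tightened by the state count to keep the summed surplus
  # within the requested tolerance
  pw <- poisson_window(q * t, max(tol / n, 1e-12))
  res <- .fwd_bounded(n, terms$groups, terms$sig_src, terms$sig_dst,
                      terms$sig_rlo, terms$sig_rhi, q, pw$right,
                      pw$weights, v0, v0, 1.0)
  upper <- pmin(res$acc_hi + (1 - pw$mass), 1)
  structure(list(lower = res$acc_lo, upper = upper, time = t, box = box),
            class = "stochrob_bounded_distribution")
}

#' @export
print.stochrob_bounded_distribution <- function(x, ...) {
  cat("Bounded transient distribution at t =", x$time, "\n")
  cat("  sum(lower) =", format(sum(x$lower)),
      " sum(upper) =", format(sum(x$upper)), "\n")
  cat("  max width  =", format(max(x$upper - x$lower)), "\n")
  invisible(x)
}

# ---- backward -------------------------------------------------------------

# Core backward pass: value vectors (ulo, uhi) propagated through the
# chain for `t` time units, with states in `absorbing_lo` / `absorbing_hi`
# made absorbing in the respective envelope.  Accumulates the Poisson mix
# (transient semantics) when `weights_kind = "transient"`, or the reward
# window when a list(t1, t2) is supplied.
backward_pass <- function(state_space, box, ulo, uhi, t, tol,
                          absorbing_lo = NULL, absorbing_hi = NULL,
                          clamp_hi = 1, reward_window_spec = NULL) {
  n <- n_states(state_space)
  q <- exit_rate_bound(state_space, box)  # q of the full chain dominates the modified one
  if (q == 0 || nrow(state_space$transitions) == 0L) {
    if (is.null(reward_window_spec)) {
      return(list(lo = ulo, hi = uhi))
    } else {
      dt <- reward_window_spec$t2 - reward_window_spec$t1
      return(list(lo = ulo * dt, hi = uhi * dt))
    }
  }
  terms_lo <- build_terms(state_space, box, drop_src = absorbing_lo)
  terms_hi <- if (identical(absorbing_lo, absorbing_hi)) terms_lo else
    build_terms(state_space, box, drop_src = absorbing_hi)

  if (is.null(reward_window_spec)) {
    pw <- poisson_window(q * t, tol)
    wts <- pw$weights; nst <- pw$right
    extra_hi <- (1 - pw$mass) * clamp_hi
  } else {
    rw <- reward_window(q, reward_window_spec$t1, reward_window_spec$t2, tol)
    wts <- rw$weights; nst <- rw$right
    extra_hi <- rw$tail * clamp_hi
  }

  res_lo <- .bwd_bounded(n, terms_lo$groups, terms_lo$sig_src, terms_lo$sig_dst,
                         terms_lo$sig_rlo, terms_lo$sig_rhi, q, nst, wts,
                         ulo, ulo, clamp_hi)
  res_hi <- .bwd_bounded(n, terms_hi$groups, terms_hi$sig_src, terms_hi$sig_dst,
                         terms_hi$sig_rlo, terms_hi$sig_rhi, q, nst, wts,
                         uhi, uhi, clamp_hi)
  lo <- res_lo$acc_lo
  hi <- res_hi$acc_hi + extra_hi
  if (is.null(reward_window_spec)) hi <- pmin(hi, clamp_hi)
  list(lo = lo, hi = hi)
}

#' Backward transient bounds: probability of a target set at time t
#'
#' One backward pass yields, for every possible start state, guaranteed
#' bounds on the probability of occupying the target set at time `t`,
#' for every parameter point in the box.
#'
#' @inheritParams transient_forward_bounded
#' @param target_indicator 0/1 vector over states (or indices of target
#'   states).
#' @return List with `lower` and `upper` vectors over start states.
#' @export
transient_backward_bounded <- function(state_space, box, target_indicator, t,
                                       tol = 1e-8) {
  stopifnot(t >= 0)
  n <- n_states(state_space)
  u0 <- if (is.numeric(target_indicator) &&
            length(target_indicator) != n) {
    v <- numeric(n); v[as.integer(target_indicator)] <- 1; v
  } else {
    stopifnot(length(target_indicator) == n)
    as.numeric(target_indicator)
  }
  if (any(u0 < 0 | u0 > 1)) stop("target must be a 0/1 indicator", call. = FALSE)
  r <- backward_pass(state_space, box, u0, u0, t, tol)
  list(lower = r$lo, upper = pmin(r$hi, 1))
}
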