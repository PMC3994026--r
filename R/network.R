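# Bounded-population stochastic reaction networks.
#
# A network is a set of species with hard population bounds, a set of
# reactions with integer stoichiometry and a rate law, a table of rate
# constants (points or uncertainty intervals) and one or more initial
# states.  The continuous-time Markov chain semantics is the usual
# chemical-master-equation one: a reaction fires in a state with an
# exponential rate given by its propensity, and firings that would push
# any species past its bound are disabled, not clipped.

#' Declare a species with a hard population bound
#'
#' @param name Species name (unique within a network).
#' @param bound Maximal population (non-negative integer). States in which
#'   the species would exceed this bound are excluded from the chain.
#' @return A `stochrob_species` object.
#' @export
species <- function(name, bound) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(bound) || length(bound) != 1L || is.na(bound) ||
      bound < 0 || bound != floor(bound)) {
    stop("species '", name, "': bound must be a non-negative integer", call. = FALSE)
  }
  structure(list(name = name, bound = as.integer(bound)),
            class = "stochrob_species")
}

#' Mass-action rate law
#'
#' Propensity k * alpha(s) with the combinatorial population term
#' alpha(s) = prod_l choose(x_l, r_l) * r_l!  (equal to x, x(x-1), ... for
#' reaction orders 1, 2, ...), the standard stochastic mass-action form.
#'
#' @param constant Name of the rate constant (resolved in the network's
#'   constant table).
#' @return A rate-law object.
#' @export
mass_action <- function(constant) {
  stopifnot(is.character(constant), length(constant) == 1L)
  structure(list(kind = "mass_action", constant = constant),
            class = "stochrob_rate_law")
}

#' Sigmoid (Hill-repression) production rate law
#'
#' Propensity k_max * theta^n / (theta^n + x^n) where x is the summed
#' population of `total`.  Production is enabled below the midpoint
#' `theta` and repressed above it; n = 0 gives the unregulated constant
#' rate k_max / 2.  The law abstracts an autoregulatory negative feedback
#' without modelling the gene copies explicitly.
#'
#' @param constant Name of the maximal-rate constant k_max.
#' @param total Character vector of species whose summed population is the
#'   regulator argument x.
#' @param midpoint Population theta at which the propensity is k_max / 2.
#' @param hill Name of the Hill-coefficient parameter n (may be perturbed).
#' @return A rate-law object.
#' @export
sigmoid_production <- function(constant, total, midpoint, hill) {
  stopifnot(is.character(constant), length(constant) == 1L,
            is.character(total), length(total) >= 1L,
            is.numeric(midpoint), midpoint > 0,
            is.character(hill), length(hill) == 1L)
  structure(list(kind = "sigmoid_production", constant = constant,
                 total = total, midpoint = midpoint, hill = hill),
            class = "stochrob_rate_law")
}

#' Declare a reaction
#'
#' @param reactants Named integer vector of stoichiometric coefficients
#'   (may be empty for pure production).
#' @param products Named integer vector of stoichiometric coefficients.
#' @param rate A rate law from [mass_action()] or [sigmoid_production()].
#' @param name Optional reaction label.
#' @return A `stochrob_reaction` object.
#' @export
reaction <- function(reactants = integer(), products = integer(), rate,
                     name = NULL) {
  as_stoich <- function(x, what) {
    if (length(x) == 0L) return(integer())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " must be a named vector", call. = FALSE)
    if (any(x < 0) || any(x != floor(x)))
      stop(what, " coefficients must be non-negative integers", call. = FALSE)
    stats::setNames(as.integer(x), names(x))
  }
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("a reaction needs at least one reactant or product", call. = FALSE)
  stopifnot(inherits(rate, "stochrob_rate_law"))
  structure(list(reactants = reactants, products = products, rate = rate,
                 name = name),
            class = "stochrob_reaction")
}

#' Assemble a reaction network
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param constants Named list; each entry a single value (point) or a
#'   length-2 numeric `c(lo, hi)` uncertainty interval.
#' @param initial_states A single named vector, or a list of named vectors,
#'   of initial populations (unnamed species default to 0).
#' @param total_bounds Optional list of `list(species = c(...), max = m)`
#'   caps on summed populations (state-space truncation of conserved-ish
#'   totals); successors violating a cap are dropped like species bounds.
#' @param labels Optional named character vector of atomic-proposition
#'   macros usable in property texts (e.g. `c(low = "B <= 2")`).
#' @return A `stochrob_network` object.
#' @export
reaction_network <- function(species, reactions, constants, initial_states,
                             total_bounds = NULL, labels = NULL) {
  stopifnot(is.list(species), length(species) >= 1L, is.list(reactions))
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names))
    stop("duplicate species names", call. = FALSE)
  bounds <- vapply(species, function(s) s$bound, integer(1))
  names(bounds) <- sp_names
  if (any(is.na(bounds)))
    stop("every species needs a population bound", call. = FALSE)

  constants <- lapply(constants, function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      stop("constants must be points or [lo, hi] intervals with lo <= hi",
           call. = FALSE)
    if (v[1] < 0)
      stop("rate constants must be non-negative", call. = FALSE)
    v
  })

  for (r in reactions) {
    for (nm in names(c(r$reactants, r$products)))
      if (!nm %in% sp_names)
        stop("reaction references unknown species '", nm, "'", call. = FALSE)
    refs <- r$rate$constant
    if (r$rate$kind == "sigmoid_production") {
      refs <- c(refs, r$rate$hill)
      if (!all(r$rate$total %in% sp_names))
        stop("sigmoid regulator references unknown species", call. = FALSE)
    }
    for (cn in refs)
      if (!cn %in% names(constants))
        stop("rate law references undeclared constant '", cn, "'", call. = FALSE)
  }

  canon_state <- function(x) {
    s <- stats::setNames(integer(length(sp_names)), sp_names)
    if (length(x)) {
      if (is.null(names(x))) {
        if (length(x) != length(sp_names))
          stop("unnamed initial state must list every species", call. = FALSE)
        s[] <- as.integer(x)
      } else {
        if (!all(names(x) %in% sp_names))
          stop("initial state names unknown species", call. = FALSE)
        s[names(x)] <- as.integer(x)
      }
    }
    if (any(s < 0) || any(s > bounds))
      stop("initial state violates species bounds", call. = FALSE)
    s
  }
  if (!is.list(initial_states)) initial_states <- list(initial_states)
  initial_states <- lapply(initial_states, canon_state)
  if (length(initial_states) == 0L)
    stop("at least one initial state is required", call. = FALSE)

  if (!is.null(total_bounds)) {
    for (tb in total_bounds) {
      if (!all(tb$species %in% sp_names) || !is.numeric(tb$max))
        stop("invalid total bound", call. = FALSE)
    }
    for (s in initial_states)
      for (tb in total_bounds)
        if (sum(s[tb$species]) > tb$max)
          stop("initial state violates a total bound", call. = FALSE)
  }

  structure(list(species = sp_names, bounds = bounds, reactions = reactions,
                 constants = constants, initial_states = initial_states,
                 total_bounds = total_bounds, labels = labels),
            class = "stochrob_network")
}

#' @export
print.stochrob_network <- function(x, ...) {
  cat("Stochastic reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  species:", paste0(x$species, " (<=", x$bounds, ")", collapse = ", "), "\n")
  pert <- names(x$constants)[vapply(x$constants, function(v) v[1] < v[2], logical(1))]
  cat("  constants:", length(x$constants),
      if (length(pert)) paste0("(uncertain: ", paste(pert, collapse = ", "), ")")
      else "(all points)", "\n")
  cat("  initial states:", length(x$initial_states), "\n")
  invisible(x)
}

#' A box of rate-constant perturbations
#'
#' The Cartesian product of per-constant intervals.  Constants not listed
#' keep the interval (or point) declared in the network; a point value is
#' a degenerate interval.  Optionally restricted to a subset of the
#' network's initial states.
#'
#' @param network A [reaction_network()].
#' @param intervals Named list of `c(lo, hi)` overrides.
#' @param initial_states Optional integer indices into the network's
#'   initial-state list.
#' @return A `stochrob_box` object: named list of intervals.
#' @export
perturbation_box <- function(network, intervals = list(), initial_states = NULL) {
  box <- network$constants
  for (nm in names(intervals)) {
    if (!nm %in% names(box))
      stop("unknown constant '", nm, "' in perturbation box", call. = FALSE)
    v <- as.numeric(intervals[[nm]])
    if (length(v) == 1L) v <- c(v, v)
    if (v[1] > v[2] || v[1] < 0) stop("invalid interval for '", nm, "'", call. = FALSE)
    box[[nm]] <- v
  }
  structure(list(intervals = box, initial_states = initial_states),
            class = "stochrob_box")
}

box_is_point <- function(box) {
  all(vapply(box$intervals, function(v) v[1] == v[2], logical(1)))
}

#' Midpoint of a perturbation box
#' @param box A `stochrob_box`.
#' @return Named numeric vector of interval midpoints.
#' @export
box_midpoint <- function(box) {
  vapply(box$intervals, function(v) (v[1] + v[2]) / 2, numeric(1))
}

#' A parameter point of a box (all constants at single values)
#' @param box A `stochrob_box`.
#' @param values Named numeric vector; unnamed constants take their
#'   declared point value (degenerate intervals).
#' @return Named numeric vector covering every constant.
#' @export
box_point <- function(box, values = numeric()) {
  p <- box_midpoint(box)
  if (length(values)) {
    stopifnot(all(names(values) %in% names(p)))
    p[names(values)] <- values
  }
  iv <- box$intervals
  for (nm in names(p)) {
    if (p[nm] < iv[[nm]][1] - 1e-12 || p[nm] > iv[[nm]][2] + 1e-12)
      stop("point leaves the box for constant '", nm, "'", call. = FALSE)
  }
  p
}

# combinatorial population term prod choose(x, r) * r!
mass_action_alpha <- function(x, stoich) {
  if (length(stoich) == 0L) return(1)
  xs <- x[names(stoich)]
  if (any(xs < stoich)) return(0)
  prod(choose(xs, stoich) * factorial(stoich))
}

# theta^n / (theta^n + x^n), with the 0^0 = 1 convention so that n = 0
# yields exactly 1/2 for every population
sigmoid_value <- function(x, theta, n) {
  if (n == 0) return(0.5)
  if (x == 0) return(1)
  1 / (1 + (x / theta)^n)
}

# successor state of reaction r in state s, or NULL if disabled
reaction_successor <- function(network, r, s) {
  if (length(r$reactants) && any(s[names(r$reactants)] < r$reactants))
    return(NULL)
  t <- s
  if (length(r$reactants)) t[names(r$reactants)] <- t[names(r$reactants)] - r$reactants
  if (length(r$products))  t[names(r$products)]  <- t[names(r$products)] + r$products
  if (any(t > network$bounds)) return(NULL)
  if (!is.null(network$total_bounds)) {
    for (tb in network$total_bounds)
      if (sum(t[tb$species]) > tb$max) return(NULL)
  }
  t
}

#' Propensity of a reaction in a state at a parameter point
#'
#' Returns 0 when reactants are insufficient or the successor state would
#' violate a species (or total) bound.
#'
#' @param network A [reaction_network()].
#' @param i Reaction index.
#' @param state Named (or network-ordered) population vector.
#' @param point Named numeric vector assigning a value to every constant
#'   the rate law references.
#' @return Firing rate (1/time).
#' @export
propensity <- function(network, i, state, point) {
  r <- network$reactions[[i]]
  s <- canonical_state(network, state)
  if (is.null(reaction_successor(network, r, s))) return(0)
  k <- point[[r$rate$constant]]
  if (is.null(k) || is.na(k)) stop("point misses constant '", r$rate$constant, "'")
  if (k < 0) stop("negative rate constant", call. = FALSE)
  if (r$rate$kind == "mass_action") {
    k * mass_action_alpha(s, r$reactants)
  } else {
    n <- point[[r$rate$hill]]
    if (is.null(n) || is.na(n)) stop("point misses constant '", r$rate$hill, "'")
    x <- sum(s[r$rate$total])
    k * sigmoid_value(x, r$rate$midpoint, n)
  }
}

#' Guaranteed propensity bounds over a perturbation box
#'
#' Mass action is linear in its constant, so the bounds are the interval
#' endpoints times the population term.  The sigmoid law is monotone in
#' the Hill coefficient for fixed regulator population (increasing below
#' the midpoint, decreasing above it), so endpoints again suffice.
#'
#' @inheritParams propensity
#' @param box A [perturbation_box()].
#' @return `c(lo, hi)` with `lo <= propensity(...) <= hi` for every point
#'   in the box.
#' @export
propensity_bounds <- function(network, i, state, box) {
  r <- network$reactions[[i]]
  s <- canonical_state(network, state)
  if (is.null(reaction_successor(network, r, s))) return(c(0, 0))
  kiv <- box$intervals[[r$rate$constant]]
  if (r$rate$kind == "mass_action") {
    a <- mass_action_alpha(s, r$reactants)
    c(kiv[1] * a, kiv[2] * a)
  } else {
    niv <- box$intervals[[r$rate$hill]]
    x <- sum(s[r$rate$total])
    th <- r$rate$midpoint
    vals <- c(sigmoid_value(x, th, niv[1]), sigmoid_value(x, th, niv[2]))
    c(kiv[1] * min(vals), kiv[2] * max(vals))
  }
}

canonical_state <- function(network, state) {
  if (is.null(names(state))) {
    stopifnot(length(state) == length(network$species))
    stats::setNames(as.integer(state), network$species)
  } else {
    s <- stats::setNames(integer(length(network$species)), network$species)
    s[names(state)] <- as.integer(state)
    s
  }
}
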