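# Small networks and exact oracles shared across the suite.

# Two-state chain: X in {0, 1}; 0 -> 1 at rate a, 1 -> 0 at rate b.
# Closed form for P(X = 0 at t | X0 = 0): b/(a+b) + a/(a+b) exp(-(a+b) t).
two_state_network <- function(a, b) {
  reaction_network(
    species = list(species("X", 1)),
    reactions = list(
      reaction(products = c(X = 1), rate = mass_action("a")),
      reaction(reactants = c(X = 1), rate = mass_action("b"))),
    constants = list(a = a, b = b),
    initial_states = list(c(X = 0)))
}

# Random small mass-action network: one or two species with small bounds,
# production / degradation / conversion reactions, one or two constants
# uncertain.  State spaces stay below ~50 states.
random_network <- function(seed) {
  set.seed(seed)
  nsp <- sample(1:2, 1)
  nms <- c("X", "Y")[seq_len(nsp)]
  bounds <- sample(3:6, nsp, replace = TRUE)
  if (nsp == 2) bounds <- pmin(bounds, c(6, 5))
  sp <- Map(species, nms, bounds)
  consts <- list()
  rxns <- list()
  kidx <- 0L
  new_const <- function(uncertain = FALSE) {
    kidx <<- kidx + 1L
    nm <- paste0("k", kidx)
    v <- round(stats::runif(1, 0.2, 2), 3)
    consts[[nm]] <<- if (uncertain) c(v, round(v * stats::runif(1, 1.2, 2), 3)) else v
    nm
  }
  uncertain_slots <- sample(1:3, 1)
  for (i in seq_len(nsp)) {
    rxns[[length(rxns) + 1L]] <- reaction(
      products = stats::setNames(1L, nms[i]),
      rate = mass_action(new_const(uncertain_slots > 0)))
    uncertain_slots <- uncertain_slots - 1L
    rxns[[length(rxns) + 1L]] <- reaction(
      reactants = stats::setNames(1L, nms[i]),
      rate = mass_action(new_const(uncertain_slots > 0)))
    uncertain_slots <- uncertain_slots - 1L
  }
  if (nsp == 2 && stats::runif(1) < 0.7) {
    rxns[[length(rxns) + 1L]] <- reaction(
      reactants = c(X = 1), products = c(Y = 1),
      rate = mass_action(new_const()))
  }
  init <- stats::setNames(pmin(sample(0:3, nsp, replace = TRUE), bounds), nms)
  reaction_network(sp, rxns, consts, list(init))
}

# Dense generator matrix at a parameter point (exact oracle input).
dense_generator <- function(state_space, point) {
  n <- n_states(state_space)
  Q <- matrix(0, n, n)
  tr <- state_space$transitions
  for (i in seq_len(nrow(tr))) {
    r <- propensity(state_space$network, tr$reaction[i],
                    state_space$states[tr$src[i], ], point)
    Q[tr$src[i], tr$dst[i]] <- Q[tr$src[i], tr$dst[i]] + r
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# Exact transient distribution via the matrix exponential.
expm_transient <- function(state_space, point, init_idx, t) {
  Q <- dense_generator(state_space, point)
  n <- nrow(Q)
  v0 <- numeric(n); v0[init_idx] <- 1
  as.numeric(v0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
}

# Exact bounded-until probability per start state via matrix exponentials
# of the phase-absorbed generators.
expm_until <- function(state_space, point, phi_idx, psi_idx, t1, t2) {
  Q <- dense_generator(state_space, point)
  n <- nrow(Q)
  absorb <- function(Q, idx) { Q[idx, ] <- 0; Q }
  notphi <- setdiff(seq_len(n), phi_idx)
  u <- as.numeric(seq_len(n) %in% psi_idx)
  if (t2 > t1) {
    Q2 <- absorb(Q, union(psi_idx, notphi))
    u <- as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(Q2 * (t2 - t1)))) %*% u)
  }
  if (t1 > 0) {
    u[notphi] <- 0
    Q1 <- absorb(Q, notphi)
    u <- as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(Q1 * t1))) %*% u)
  }
  u
}

# Random feasible distributions compatible with per-state envelopes
# (water-filling of the slack budget in random order).
sample_feasible <- function(l, u, nsamp, seed = 1) {
  set.seed(seed)
  n <- length(l)
  out <- matrix(0, nsamp, n)
  for (k in seq_len(nsamp)) {
    p <- l
    budget <- 1 - sum(l)
    for (i in sample.int(n)) {
      if (budget <= 0) break
      add <- min(u[i] - l[i], budget * stats::runif(1))
      p[i] <- p[i] + add
      budget <- budget - add
    }
    # dump any remainder greedily
    for (i in sample.int(n)) {
      if (budget <= 1e-12) break
      add <- min(u[i] - p[i], budget)
      p[i] <- p[i] + add
      budget <- budget - add
    }
    out[k, ] <- p / sum(p)
  }
  out
}

bd_fixture <- function() {
  fx <- birth_death()
  list(fx = fx, ss = enumerate_states(fx$network))
}
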