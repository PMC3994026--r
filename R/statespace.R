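# Reachable state-space enumeration and the uniformisation constant.

#' Enumerate the reachable state space of a bounded network
#'
#' Breadth-first closure from all initial states.  A reaction fires in a
#' state only if all reactants are present in sufficient numbers and the
#' successor respects every species (and total) bound; firings that would
#' leave the bounded box are dropped.  Each (source, target, reaction)
#' transition is recorded once.
#'
#' @param network A [reaction_network()].
#' @return A `stochrob_state_space`: `states` (n x n_species integer
#'   matrix), `transitions` (data.frame `src`, `dst`, `reaction`, 1-based),
#'   `initial` (indices of the initial states), and the network itself.
#' @export
enumerate_states <- function(network) {
  stopifnot(inherits(network, "stochrob_network"))
  nsp <- length(network$species)
  key <- function(s) paste(s, collapse = ",")

  index <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", 256L)
  nstates <- 0L
  add_state <- function(s) {
    k <- key(s)
    i <- index[[k]]
    if (!is.null(i)) return(i)
    nstates <<- nstates + 1L
    if (nstates > length(states)) states[[2L * nstates]] <<- NULL
    states[[nstates]] <<- s
    index[[k]] <- nstates
    nstates
  }

  frontier <- integer()
  for (s0 in network$initial_states) frontier <- c(frontier, add_state(s0))
  frontier <- unique(frontier)
  initial <- frontier

  chunks <- list()
  nrx <- length(network$reactions)
  while (length(frontier)) {
    nxt <- integer(length(frontier) * nrx); nnxt <- 0L
    csrc <- integer(length(frontier) * nrx)
    cdst <- integer(length(frontier) * nrx)
    crxn <- integer(length(frontier) * nrx)
    ntr <- 0L
    for (si in frontier) {
      s <- states[[si]]
      for (j in seq_len(nrx)) {
        t <- reaction_successor(network, network$reactions[[j]], s)
        if (is.null(t) || identical(t, s)) next
        known <- !is.null(index[[key(t)]])
        ti <- add_state(t)
        ntr <- ntr + 1L
        csrc[ntr] <- si; cdst[ntr] <- ti; crxn[ntr] <- j
        if (!known) { nnxt <- nnxt + 1L; nxt[nnxt] <- ti }
      }
    }
    chunks[[length(chunks) + 1L]] <-
      list(src = csrc[seq_len(ntr)], dst = cdst[seq_len(ntr)],
           rxn = crxn[seq_len(ntr)])
    frontier <- nxt[seq_len(nnxt)]
  }
  tr_src <- unlist(lapply(chunks, `[[`, "src"))
  tr_dst <- unlist(lapply(chunks, `[[`, "dst"))
  tr_rxn <- unlist(lapply(chunks, `[[`, "rxn"))
  if (is.null(tr_src)) tr_src <- tr_dst <- tr_rxn <- integer()

  mat <- if (nstates) do.call(rbind, states[seq_len(nstates)]) else
    matrix(0L, 0L, nsp)
  colnames(mat) <- network$species
  structure(list(states = mat,
                 transitions = data.frame(src = tr_src, dst = tr_dst,
                                          reaction = tr_rxn),
                 initial = initial,
                 network = network),
            class = "stochrob_state_space")
}

#' @export
print.stochrob_state_space <- function(x, ...) {
  cat("State space:", nrow(x$states), "states,", nrow(x$transitions),
      "transitions\n")
  invisible(x)
}

#' Number of states / transitions
#' @param state_space A state space from [enumerate_states()].
#' @return Integer count.
#' @export
n_states <- function(state_space) nrow(state_space$states)

#' @rdname n_states
#' @export
n_transitions <- function(state_space) nrow(state_space$transitions)

# Per-transition rate interval table over a box: list with vectors
# lo, hi aligned with state_space$transitions, plus per-reaction metadata
transition_rate_bounds <- function(state_space, box) {
  net <- state_space$network
  tr <- state_space$transitions
  n <- nrow(tr)
  lo <- numeric(n); hi <- numeric(n)
  # vectorised per reaction for speed
  for (j in seq_along(net$reactions)) {
    idx <- which(tr$reaction == j)
    if (!length(idx)) next
    r <- net$reactions[[j]]
    kiv <- box$intervals[[r$rate$constant]]
    S <- state_space$states[tr$src[idx], , drop = FALSE]
    if (r$rate$kind == "mass_action") {
      a <- rep(1, length(idx))
      for (nm in names(r$reactants)) {
        rc <- r$reactants[[nm]]
        a <- a * choose(S[, nm], rc) * factorial(rc)
      }
      lo[idx] <- kiv[1] * a
      hi[idx] <- kiv[2] * a
    } else {
      niv <- box$intervals[[r$rate$hill]]
      x <- rowSums(S[, r$rate$total, drop = FALSE])
      s1 <- vapply(x, sigmoid_value, numeric(1), theta = r$rate$midpoint, n = niv[1])
      s2 <- vapply(x, sigmoid_value, numeric(1), theta = r$rate$midpoint, n = niv[2])
      lo[idx] <- kiv[1] * pmin(s1, s2)
      hi[idx] <- kiv[2] * pmax(s1, s2)
    }
  }
  list(lo = lo, hi = hi)
}

#' Uniformisation constant: upper bound on the exit rate over a box
#'
#' The maximum over states of the summed per-transition upper rate
#' bounds; for a degenerate box this is the classical maximal exit rate.
#'
#' @param state_space A state space from [enumerate_states()].
#' @param box A [perturbation_box()]; defaults to the network's declared
#'   constant intervals.
#' @return A rate `q >= max_{s, p in box} E(s, p)`; 0 for a chain without
#'   transitions.
#' @export
exit_rate_bound <- function(state_space, box = NULL) {
  if (is.null(box)) box <- perturbation_box(state_space$network)
  if (nrow(state_space$transitions) == 0L) return(0)
  rb <- transition_rate_bounds(state_space, box)
  exits <- tapply(rb$hi, state_space$transitions$src, sum)
  max(exits)
}

#' Label states satisfying a population predicate
#'
#' @param state_space A state space.
#' @param proposition Either a function `f(states_matrix) -> logical`, or
#'   a character predicate over species names, e.g. `"X >= 15 & X <= 20"`
#'   (evaluated columnwise; `"true"` matches every state).
#' @return Integer vector of state indices.
#' @export
sat_atomic <- function(state_space, proposition) {
  S <- state_space$states
  if (is.function(proposition)) {
    keep <- proposition(S)
  } else {
    txt <- trimws(proposition)
    lbl <- state_space$network$labels
    if (!is.null(lbl) && txt %in% names(lbl)) txt <- lbl[[txt]]
    if (identical(tolower(txt), "true")) return(seq_len(nrow(S)))
    if (identical(tolower(txt), "false")) return(integer())
    env <- as.data.frame(S)
    keep <- eval(parse(text = txt)[[1]], envir = env, enclos = baseenv())
    if (!is.logical(keep))
      stop("proposition did not evaluate to a logical vector", call. = FALSE)
    if (length(keep) == 1L) keep <- rep(keep, nrow(S))
  }
  which(keep)
}
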