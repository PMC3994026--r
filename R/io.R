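# Model schema (YAML/JSON) and analysis configuration.

#' Write a reaction network to the model schema
#'
#' YAML (default) or JSON schema with species (name, bound), constants
#' (point or [lo, hi]), reactions (reactants, products, rate law),
#' initial states, optional total bounds and proposition labels.  The
#' schema round-trips exactly through [read_model()].
#'
#' @param network A [reaction_network()].
#' @param path Output file; `.json` selects JSON.
#' @return Invisibly, the schema list.
#' @export
write_model <- function(network, path) {
  doc <- list(
    species = lapply(seq_along(network$species), function(i)
      list(name = network$species[i], bound = unname(network$bounds[i]))),
    constants = lapply(network$constants, function(v)
      if (v[1] == v[2]) v[1] else as.list(v)),
    reactions = lapply(network$reactions, function(r) {
      rl <- r$rate
      rate <- if (rl$kind == "mass_action")
        list(kind = "mass_action", constant = rl$constant)
      else
        list(kind = "sigmoid_production", constant = rl$constant,
             total = as.list(rl$total), midpoint = rl$midpoint,
             hill = rl$hill)
      out <- list(reactants = as.list(r$reactants),
                  products = as.list(r$products), rate = rate)
      if (!is.null(r$name)) out$name <- r$name
      out
    }),
    initial_states = lapply(network$initial_states, as.list))
  if (!is.null(network$total_bounds))
    doc$total_bounds <- lapply(network$total_bounds, function(tb)
      list(species = as.list(tb$species), max = tb$max))
  if (!is.null(network$labels))
    doc$labels <- as.list(network$labels)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(doc)
}

#' Read a reaction network from the model schema
#'
#' @param path A YAML or JSON model file.
#' @return A [reaction_network()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  fail <- function(...) stop("model schema: ", ..., call. = FALSE)
  if (is.null(doc$species)) fail("missing 'species'")
  sp <- lapply(doc$species, function(s) {
    if (is.null(s$name)) fail("species entry without a name")
    if (is.null(s$bound)) fail("species '", s$name, "' has no bound")
    species(s$name, s$bound)
  })
  if (is.null(doc$constants)) fail("missing 'constants'")
  consts <- lapply(doc$constants, function(v) unlist(v))
  if (is.null(doc$reactions)) fail("missing 'reactions'")
  rxns <- lapply(doc$reactions, function(r) {
    rl <- r$rate
    if (is.null(rl$kind)) fail("reaction without a rate-law kind")
    rate <- if (rl$kind == "mass_action") mass_action(rl$constant)
    else if (rl$kind == "sigmoid_production")
      sigmoid_production(rl$constant, unlist(rl$total), rl$midpoint, rl$hill)
    else fail("unknown rate-law kind '", rl$kind, "'")
    reaction(reactants = unlist(r$reactants) %||% integer(),
             products = unlist(r$products) %||% integer(),
             rate = rate, name = r$name)
  })
  inits <- lapply(doc$initial_states, function(s) unlist(s))
  tb <- if (!is.null(doc$total_bounds))
    lapply(doc$total_bounds, function(x)
      list(species = unlist(x$species), max = x$max)) else NULL
  labels <- if (!is.null(doc$labels)) unlist(doc$labels) else NULL
  reaction_network(sp, rxns, consts, inits, total_bounds = tb,
                   labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis configuration
#'
#' @param err_bound Absolute error bound for landscape refinement.
#' @param max_depth Maximum bisection depth.
#' @param tol Poisson truncation tolerance.
#' @param definition Robustness definition (`"1a"`-`"1d"`).
#' @param r Optional threshold for `"1a"`/`"1b"`.
#' @param workers Worker count for independent-subspace evaluation
#'   (scheduling contract only; evaluation is sequential here).
#' @param seed Random seed (used only by sampling-based diagnostics).
#' @return A validated `stochrob_config` list.
#' @export
analysis_config <- function(err_bound = 0.01, max_depth = 12L, tol = 1e-8,
                            definition = "1c", r = NULL, workers = 1L,
                            seed = NULL) {
  if (err_bound <= 0) stop("err_bound must be > 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  stopifnot(definition %in% c("1a", "1b", "1c", "1d"), max_depth >= 0)
  if (definition %in% c("1a", "1b") && is.null(r))
    stop("definitions 1a/1b need a threshold r", call. = FALSE)
  structure(list(err_bound = err_bound, max_depth = as.integer(max_depth),
                 tol = tol, definition = definition, r = r,
                 workers = as.integer(workers), seed = seed),
            class = "stochrob_config")
}
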