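# Evaluation-function landscapes over an adaptively decomposed
# perturbation space, and robustness degrees as integrals of the
# evaluation function under a uniform perturbation density.

box_volume <- function(box, dims) {
  prod(vapply(dims, function(nm) {
    v <- box$intervals[[nm]]; max(v[2] - v[1], 0)
  }, numeric(1)))
}

# dimensions that are actually uncertain in the root box
uncertain_dims <- function(box) {
  nms <- names(box$intervals)
  nms[vapply(box$intervals, function(v) v[2] > v[1], logical(1))]
}

#' Adaptive decomposition of a perturbation box
#'
#' Worklist refinement: each box is evaluated with [check_formula()]; a
#' box whose bound width exceeds `err_bound` is bisected at the midpoint
#' of its widest dimension (relative to the root box; ties broken by
#' lowest dimension index) until the width criterion or `max_depth` is
#' reached.  `max_depth` is the supplementary termination criterion that
#' keeps discontinuous evaluation functions from refining forever.
#' Subspace evaluations are independent of each other.
#'
#' @param state_space A state space (or a [reaction_network()], which is
#'   enumerated first).
#' @param formula Formula node.
#' @param root_box Root [perturbation_box()].
#' @param err_bound Requested absolute error (> 0; the volume-weighted
#'   mean bound width of the returned landscape is the achieved error).
#' @param max_depth Maximum bisection depth (>= 0).
#' @param initial_states Initial-state indices (default: the network's).
#' @param tol Truncation tolerance.
#' @param rewards Named state-reward list, as in [check_formula()].
#' @return A `stochrob_landscape`: data frame `subspaces` with one row
#'   per leaf box (`<dim>_lo`/`<dim>_hi`, `lambda_min`, `lambda_max`,
#'   `depth`, `volume`), plus `err_bound`, `achieved_err`, `dims`,
#'   `evaluations` (list of per-initial-state bound matrices).
#' @export
refine_landscape <- function(state_space, formula, root_box, err_bound,
                             max_depth = 12L,
                             initial_states = NULL, tol = 1e-8,
                             rewards = list()) {
  if (inherits(state_space, "stochrob_network"))
    state_space <- enumerate_states(state_space)
  if (err_bound <= 0) stop("err_bound must be > 0", call. = FALSE)
  if (max_depth < 0) stop("max_depth must be >= 0", call. = FALSE)
  dims <- uncertain_dims(root_box)
  if (!length(dims))
    stop("root box has zero volume: no uncertain constant to refine",
         call. = FALSE)
  if (is.null(initial_states)) initial_states <- state_space$initial
  root_width <- vapply(dims, function(nm) diff(root_box$intervals[[nm]]),
                       numeric(1))

  evaluate <- function(box) {
    ev <- check_formula(state_space, box, formula, initial_states, tol,
                        rewards)
    cbind(lo = ev$lambda_min, hi = ev$lambda_max)
  }
  split_box <- function(box) {
    rel <- vapply(dims, function(nm) diff(box$intervals[[nm]]), numeric(1)) /
      root_width
    d <- dims[which.max(rel)]
    v <- box$intervals[[d]]
    mid <- (v[1] + v[2]) / 2
    b1 <- box; b1$intervals[[d]] <- c(v[1], mid)
    b2 <- box; b2$intervals[[d]] <- c(mid, v[2])
    list(b1, b2)
  }

  leaves <- list()
  work <- list(list(box = root_box, depth = 0L))
  warned <- FALSE
  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    bounds <- evaluate(item$box)
    width <- max(bounds[, "hi"] - bounds[, "lo"])
    if (width > err_bound && item$depth < max_depth) {
      halves <- split_box(item$box)
      work <- c(work, list(list(box = halves[[2]], depth = item$depth + 1L),
                           list(box = halves[[1]], depth = item$depth + 1L)))
    } else {
      if (width > err_bound && !warned) {
        warning("max_depth reached before err_bound; achieved error ",
                "exceeds the request (possible discontinuity)", call. = FALSE)
        warned <- TRUE
      }
      leaves[[length(leaves) + 1L]] <-
        list(box = item$box, depth = item$depth, bounds = bounds)
    }
  }

  # deterministic order: sort leaves by their lower corners
  corner <- t(vapply(leaves, function(l)
    vapply(dims, function(nm) l$box$intervals[[nm]][1], numeric(1)),
    numeric(length(dims))))
  if (length(dims) == 1L) corner <- matrix(corner, ncol = 1L)
  ord <- do.call(order, as.data.frame(corner))
  leaves <- leaves[ord]

  rows <- lapply(leaves, function(l) {
    out <- list()
    for (nm in dims) {
      out[[paste0(nm, "_lo")]] <- l$box$intervals[[nm]][1]
      out[[paste0(nm, "_hi")]] <- l$box$intervals[[nm]][2]
    }
    out$lambda_min <- min(l$bounds[, "lo"])
    out$lambda_max <- max(l$bounds[, "hi"])
    out$depth <- l$depth
    out$volume <- box_volume(l$box, dims)
    as.data.frame(out)
  })
  sub <- do.call(rbind, rows)
  vol <- box_volume(root_box, dims)
  widths <- vapply(leaves, function(l) max(l$bounds[, "hi"] - l$bounds[, "lo"]),
                   numeric(1))
  achieved <- sum(sub$volume / vol * widths)
  structure(list(subspaces = sub, dims = dims, err_bound = err_bound,
                 achieved_err = achieved, root_box = root_box,
                 initial_states = initial_states,
                 evaluations = lapply(leaves, `[[`, "bounds")),
            class = "stochrob_landscape")
}

#' @export
print.stochrob_landscape <- function(x, ...) {
  cat("Evaluation landscape over", paste(x$dims, collapse = " x "), ":",
      nrow(x$subspaces), "subspaces\n")
  cat("  requested err:", x$err_bound, " achieved err:",
      format(x$achieved_err, digits = 4), "\n")
  invisible(x)
}

#' Robustness degree from a landscape
#'
#' Integral of the evaluation function over the perturbation space under
#' a uniform perturbation density, bracketed by the landscape bounds.
#' Definitions: `"1a"` qualitative volume fraction where a threshold
#' comparison holds (undecided subspaces count into the upper bound
#' only); `"1b"` threshold-relative mean (`1c` divided by `r`,
#' uncapped); `"1c"` absolute mean of the evaluation function; `"1d"`
#' mean as `1c` plus a midpoint-variance estimate (approximate, not
#' bound-guaranteed).
#'
#' @param landscape A `stochrob_landscape`.
#' @param definition One of `"1a"`, `"1b"`, `"1c"`, `"1d"`.
#' @param r Threshold in `(0, 1]` (required for `"1a"`/`"1b"`).
#' @param cmp Comparison direction for `"1a"` (`">="` or `"<="`).
#' @return A `stochrob_robustness`: `r_min`, `r_max`, `definition`, `r`,
#'   `achieved_err`, and `variance_estimate` for `"1d"`.
#' @export
robustness_degree <- function(landscape, definition = "1c", r = NULL,
                              cmp = ">=") {
  stopifnot(definition %in% c("1a", "1b", "1c", "1d"))
  sub <- landscape$subspaces
  w <- sub$volume / sum(sub$volume)
  if (definition %in% c("1a", "1b")) {
    if (is.null(r) || r <= 0 || r > 1)
      stop("definitions 1a/1b need a threshold r in (0, 1]", call. = FALSE)
  }
  variance <- NULL
  if (definition == "1a") {
    stopifnot(cmp %in% c(">=", "<="))
    if (cmp == ">=") {
      r_min <- sum(w[sub$lambda_min >= r])
      r_max <- sum(w[sub$lambda_max >= r])
    } else {
      r_min <- sum(w[sub$lambda_max <= r])
      r_max <- sum(w[sub$lambda_min <= r])
    }
  } else {
    m_lo <- sum(w * sub$lambda_min)
    m_hi <- sum(w * sub$lambda_max)
    if (definition == "1b") {
      r_min <- m_lo / r; r_max <- m_hi / r
    } else {
      r_min <- m_lo; r_max <- m_hi
      if (definition == "1d") {
        mid <- (sub$lambda_min + sub$lambda_max) / 2
        mbar <- sum(w * mid)
        variance <- sum(w * (mid - mbar)^2)
      }
    }
  }
  structure(list(r_min = r_min, r_max = r_max, definition = definition,
                 r = r, achieved_err = landscape$achieved_err,
                 variance_estimate = variance,
                 approximate = identical(definition, "1d")),
            class = "stochrob_robustness")
}

#' @export
print.stochrob_robustness <- function(x, ...) {
  cat("Robustness degree (definition ", x$definition, "): [",
      format(x$r_min, digits = 6), ", ", format(x$r_max, digits = 6), "]\n",
      sep = "")
  if (!is.null(x$variance_estimate))
    cat("  midpoint variance (approximate):",
        format(x$variance_estimate, digits = 4), "\n")
  invisible(x)
}

#' Robustness averaged over a finite set of initial states
#'
#' The robustness integral over a perturbation space extended with a
#' finite initial-state set is the uniform average of the per-state
#' integrals.  All initial states share each backward-analysis pass, so
#' the cost matches the single-state analysis (post-processing formulas
#' fall back to one forward pass per state).
#'
#' @inheritParams refine_landscape
#' @param init_set Initial-state indices.
#' @param definition,r,cmp As in [robustness_degree()].
#' @return A `stochrob_robustness` with the averaged bounds, plus
#'   `per_state`: the per-initial-state robustness bounds.
#' @export
robustness_over_initial_states <- function(state_space, formula, root_box,
                                           init_set, definition = "1c",
                                           r = NULL, cmp = ">=",
                                           err_bound = 0.01, max_depth = 12L,
                                           tol = 1e-8, rewards = list()) {
  if (inherits(state_space, "stochrob_network"))
    state_space <- enumerate_states(state_space)
  stopifnot(length(init_set) >= 1,
            all(init_set >= 1), all(init_set <= n_states(state_space)))
  ls <- refine_landscape(state_space, formula, root_box, err_bound, max_depth,
                         initial_states = init_set, tol = tol,
                         rewards = rewards)
  w <- ls$subspaces$volume / sum(ls$subspaces$volume)
  per_state <- t(vapply(seq_along(init_set), function(i) {
    lo <- vapply(ls$evaluations, function(b) b[i, "lo"], numeric(1))
    hi <- vapply(ls$evaluations, function(b) b[i, "hi"], numeric(1))
    sub_i <- ls$subspaces
    sub_i$lambda_min <- lo; sub_i$lambda_max <- hi
    ls_i <- ls; ls_i$subspaces <- sub_i
    rd <- robustness_degree(ls_i, definition, r, cmp)
    c(r_min = rd$r_min, r_max = rd$r_max)
  }, numeric(2)))
  out <- structure(list(r_min = mean(per_state[, "r_min"]),
                        r_max = mean(per_state[, "r_max"]),
                        definition = definition, r = r,
                        achieved_err = ls$achieved_err,
                        variance_estimate = NULL,
                        approximate = identical(definition, "1d"),
                        per_state = per_state, landscape = ls),
                   class = "stochrob_robustness")
  out
}

#' Piece-wise linear refinement of a landscape
#'
#' At every grid point shared by adjacent subspaces the value interval is
#' the intersection of all incident bound intervals; between grid points
#' the interval endpoints are interpolated linearly.  The result is
#' usually tighter than the step-shaped min-max landscape but carries no
#' conservative guarantee.  Disjoint incident intervals would contradict
#' bound soundness and raise an error.
#'
#' @param landscape A `stochrob_landscape` (currently one-dimensional).
#' @return A `stochrob_pla`: data frame `grid` (`point`, `lo`, `hi`,
#'   `mid`) and interpolation helpers.
#' @export
pla_refine <- function(landscape) {
  if (length(landscape$dims) != 1L)
    stop("piece-wise linear refinement is implemented for one-dimensional ",
         "landscapes", call. = FALSE)
  d <- landscape$dims
  sub <- landscape$subspaces
  lo_col <- paste0(d, "_lo"); hi_col <- paste0(d, "_hi")
  pts <- sort(unique(c(sub[[lo_col]], sub[[hi_col]])))
  eps <- 1e-12 * max(abs(pts), 1)
  grid <- lapply(pts, function(p) {
    inc <- which(sub[[lo_col]] <= p + eps & sub[[hi_col]] >= p - eps)
    lo <- max(sub$lambda_min[inc])
    hi <- min(sub$lambda_max[inc])
    if (lo > hi + 1e-9)
      stop("disjoint bound intervals at a shared grid point: ",
           "bounds are unsound", call. = FALSE)
    data.frame(point = p, lo = lo, hi = min(lo, hi) + max(hi - lo, 0))
  })
  grid <- do.call(rbind, grid)
  grid$hi <- pmax(grid$hi, grid$lo)
  grid$mid <- (grid$lo + grid$hi) / 2
  structure(list(grid = grid, dim = d,
                 interpolate = function(x, which = "mid")
                   stats::approx(grid$point, grid[[which]], xout = x)$y),
            class = "stochrob_pla")
}

#' @export
print.stochrob_pla <- function(x, ...) {
  cat("Piece-wise linear refinement over", x$dim, ":", nrow(x$grid),
      "grid points (non-conservative)\n")
  invisible(x)
}

#' Write a landscape as CSV
#' @param landscape A `stochrob_landscape`.
#' @param path Output file.
#' @return Invisibly, the data frame written.
#' @export
write_landscape_csv <- function(landscape, path) {
  utils::write.csv(landscape$subspaces, path, row.names = FALSE)
  invisible(landscape$subspaces)
}

#' Write a robustness result as JSON
#' @param robustness A `stochrob_robustness`.
#' @param path Output file.
#' @return Invisibly, the list written.
#' @export
write_robustness_json <- function(robustness, path) {
  out <- list(definition = robustness$definition, r = robustness$r,
              r_min = robustness$r_min, r_max = robustness$r_max,
              achieved_err = robustness$achieved_err,
              approximate = isTRUE(robustness$approximate))
  if (!is.null(robustness$variance_estimate))
    out$variance_estimate <- robustness$variance_estimate
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out)
}

#' Plot a one-dimensional landscape (step bands with optional PLA overlay)
#'
#' @param landscape A `stochrob_landscape` with one uncertain dimension.
#' @param pla Optional `stochrob_pla` overlay.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_landscape <- function(landscape, pla = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_landscape needs the ggplot2 package", call. = FALSE)
  stopifnot(length(landscape$dims) == 1L)
  d <- landscape$dims
  sub <- landscape$subspaces
  g <- ggplot2::ggplot(sub) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data[[paste0(d, "_lo")]], xmax = .data[[paste0(d, "_hi")]],
      ymin = .data$lambda_min, ymax = .data$lambda_max),
      fill = "grey70", colour = "grey40", linewidth = 0.2) +
    ggplot2::labs(x = d, y = "evaluation function bounds") +
    ggplot2::theme_minimal()
  if (!is.null(pla))
    g <- g + ggplot2::geom_ribbon(
      data = pla$grid,
      ggplot2::aes(x = .data$point, ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.4) +
      ggplot2::geom_line(data = pla$grid,
                         ggplot2::aes(x = .data$point, y = .data$mid),
                         colour = "steelblue")
  g
}
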