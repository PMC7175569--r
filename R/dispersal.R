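#' Movement syndromes on the shy-bold axis
#'
#' A movement syndrome bundles the three dispersal parameters that define an
#' individual's position on the shy-bold continuum with the parameters of
#' the intraday step distribution:
#'
#' * `p_matrix`: probability of admitting an adjacent matrix-habitat cell as
#'   a step candidate while dispersal/breeding habitat is also available;
#' * `p_corr`: probability that the daily movement direction is maintained
#'   at a given step (0 = uncorrelated, 1 = straight-line);
#' * `max_matrix_run`: maximum number of consecutive matrix cells an
#'   individual travels before aborting the foray and returning to the last
#'   non-matrix cell it occupied;
#' * `s_max`, `exponent_x`: maximum intraday steps and steepness of the
#'   step-count distribution (see [build_step_distribution()]).
#'
#' The presets are shy `(0.03, 0.5, 10)`, intermediate `(0.06, 0.5, 20)` and
#' bold `(0.12, 0.5, 40)` for `(p_matrix, p_corr, max_matrix_run)`; the step
#' distribution defaults (`s_max = 45`, `exponent_x = 11`) are shared by all
#' syndromes, giving a mean of about 4 steps (km) per dispersal day.
#'
#' @param label `"shy"`, `"intermediate"` or `"bold"` for a preset, or
#'   `"custom"` with explicit parameters.
#' @param p_matrix,p_corr,max_matrix_run,s_max,exponent_x override any
#'   preset value.
#' @return An object of class `movement_syndrome`.
#' @export
movement_syndrome <- function(label = c("shy", "intermediate", "bold",
                                        "custom"),
                              p_matrix = NULL, p_corr = NULL,
                              max_matrix_run = NULL,
                              s_max = 45L, exponent_x = 11) {
  label <- match.arg(label)
  presets <- list(shy          = c(0.03, 0.5, 10),
                  intermediate = c(0.06, 0.5, 20),
                  bold         = c(0.12, 0.5, 40))
  if (label != "custom") {
    p <- presets[[label]]
    if (is.null(p_matrix)) p_matrix <- p[1]
    if (is.null(p_corr)) p_corr <- p[2]
    if (is.null(max_matrix_run)) max_matrix_run <- p[3]
  }
  stopifnot(is.numeric(p_matrix), p_matrix >= 0, p_matrix <= 1,
            is.numeric(p_corr), p_corr >= 0, p_corr <= 1,
            max_matrix_run >= 1, s_max >= 1, exponent_x >= 0)
  structure(list(p_matrix = p_matrix, p_corr = p_corr,
                 max_matrix_run = as.integer(max_matrix_run),
                 s_max = as.integer(s_max), exponent_x = exponent_x,
                 label = label),
            class = "movement_syndrome")
}

#' @export
print.movement_syndrome <- function(x, ...) {
  cat(sprintf(
    "<movement_syndrome> %s: p_matrix=%.3g p_corr=%.2g max_matrix_run=%d s_max=%d x=%.3g\n",
    x$label, x$p_matrix, x$p_corr, x$max_matrix_run, x$s_max, x$exponent_x))
  invisible(x)
}

#' Intraday step-count distribution
#'
#' The number of 1-km steps an individual takes per dispersal day is drawn
#' from the power-function distribution
#' `P(s) = phi * (1 - (s - 1) / (s_max - 1))^x` for `s = 1, ..., s_max`. The
#' normalisation factor `phi` scales the weights so the maximum is 1 (the
#' weight at `s = 1` is already 1, so `phi = 1`); the sampling distribution
#' is the weights rescaled to sum to one. Larger `x` makes long daily
#' distances rarer.
#'
#' @param s_max maximum steps per day (>= 2).
#' @param exponent_x steepness exponent (>= 0).
#' @return An object of class `step_distribution` with elements `s`,
#'   `weights` (max 1), `phi`, `probs` (sum 1) and `mean_steps`.
#' @export
build_step_distribution <- function(s_max, exponent_x) {
  if (s_max < 2) stop("s_max must be >= 2")
  stopifnot(is.finite(exponent_x), exponent_x >= 0)
  s <- seq_len(s_max)
  w <- (1 - (s - 1) / (s_max - 1))^exponent_x
  phi <- 1 / max(w)
  probs <- w / sum(w)
  structure(list(s = s, weights = w * phi, phi = phi, probs = probs,
                 mean_steps = sum(s * probs)),
            class = "step_distribution")
}

#' Draw daily step counts
#'
#' @param dist a [build_step_distribution()] object.
#' @param n number of draws.
#' @return Integer vector of step counts.
#' @export
draw_steps <- function(dist, n = 1) {
  stopifnot(inherits(dist, "step_distribution"))
  sample.int(length(dist$probs), n, replace = TRUE, prob = dist$probs)
}

ms_of <- function(ms) {
  if (is.character(ms)) ms <- movement_syndrome(ms)
  stopifnot(inherits(ms, "movement_syndrome"))
  ms
}

#' One movement decision of the habitat-dependent correlated walk
#'
#' The candidate set is the 9-cell Moore neighbourhood of `cell` (including
#' staying put), minus barrier cells and cells outside the grid (reflective
#' boundary). Habitat preference is decided first: if any candidate is
#' dispersal or breeding habitat, those candidates are always admitted and
#' each matrix candidate is admitted independently with probability
#' `p_matrix`; if only matrix habitat is available, all candidates stand and
#' the choice is uniform. Then, with probability `p_corr` (and only when a
#' previous direction exists), the choice is restricted to the moving
#' candidates that minimise angular deviation from the previous direction,
#' ties broken uniformly; otherwise the choice is uniform over the admitted
#' set.
#'
#' @param cell integer vector `c(row, col)`, not on a barrier cell.
#' @param prev_direction previous direction, 0-7 clockwise from north, or
#'   `NA` for none (e.g. before the first step of a day).
#' @param grid a [habitat_grid()].
#' @param ms a [movement_syndrome()] or preset name.
#' @return List with `row`, `col`, `direction` (updated only if the agent
#'   moved) and `moved`.
#' @export
choose_step <- function(cell, prev_direction, grid, ms) {
  ms <- ms_of(ms)
  stopifnot(inherits(grid, "habitat_grid"), length(cell) == 2)
  pd <- if (is.na(prev_direction)) -1L else as.integer(prev_direction)
  cpp_choose_step(cell[1], cell[2], pd, grid$classes, ms$p_matrix, ms$p_corr)
}

#' Simulate one dispersal day
#'
#' Draws a step count from the syndrome's step distribution (unless
#' `n_steps` is given), assigns the day's initial direction uniformly at
#' random, and walks step by step with [choose_step()] semantics. The
#' consecutive-matrix counter carried in `state` increments on every step
#' ending in matrix habitat and resets on dispersal/breeding habitat; when it
#' would exceed `max_matrix_run` the agent is returned to the last non-matrix
#' cell it occupied and the counter resets.
#'
#' @param cell integer `c(row, col)` start location.
#' @param grid a [habitat_grid()].
#' @param ms a [movement_syndrome()] or preset name.
#' @param n_steps optional fixed number of steps (otherwise drawn).
#' @param state matrix-run state carried across days: list with `run`,
#'   `last_row`, `last_col`; defaults to a fresh state at `cell`.
#' @return List with `trajectory` (matrix of row/col per step), final `row`,
#'   `col`, and the updated `state`.
#' @export
walk_one_day <- function(cell, grid, ms, n_steps = NULL, state = NULL) {
  ms <- ms_of(ms)
  stopifnot(inherits(grid, "habitat_grid"))
  if (is.null(state))
    state <- list(run = 0L, last_row = cell[1], last_col = cell[2])
  if (is.null(n_steps)) {
    dist <- build_step_distribution(ms$s_max, ms$exponent_x)
    n_steps <- draw_steps(dist, 1)
  }
  res <- cpp_walk_one_day(cell[1], cell[2], n_steps, grid$classes,
                          ms$p_matrix, ms$p_corr, ms$max_matrix_run,
                          state$run, state$last_row, state$last_col)
  list(trajectory = res$trajectory, row = res$row, col = res$col,
       state = list(run = res$run, last_row = res$last_row,
                    last_col = res$last_col))
}
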