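# Steepest-descent / conjugate-gradient minimizer with an adaptive line
# search.  The initial trial step scales the search direction so that no
# atom moves more than `max_disp` Angstrom; on failure the step halves
# until the energy decreases, on success it doubles while the energy
# keeps decreasing (steep clash relaxation would otherwise crawl at the
# displacement cap).  Steps are only ever accepted on a decrease, so the
# energy trace is non-increasing by construction.

minimize_core <- function(engine, x, max_steps, tol, switch_step,
                          fixed_steps, max_disp = 0.01, max_halvings = 40L,
                          expand_gain = 0.5) {
  stopifnot(is_energy_model(engine))
  x <- as.matrix(x)
  e <- engine$energy(x)
  if (!is.finite(e)) stop("instability error: non-finite starting energy")
  trace <- numeric(max_steps + 1L); trace[1L] <- e
  g <- engine$gradient(x)
  grms <- sqrt(mean(g^2))
  dir_prev <- NULL; g_prev <- NULL
  steps <- 0L
  method_switch_step <- NA_integer_
  while (steps < max_steps) {
    if (!fixed_steps && grms < tol) break
    if (fixed_steps && grms < 1e-12) break
    use_cg <- steps >= switch_step
    if (use_cg && is.na(method_switch_step)) method_switch_step <- steps
    if (use_cg && !is.null(g_prev)) {
      beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev * g_prev))
      dir <- -g + beta * dir_prev
      if (sum(dir * g) >= 0) dir <- -g      # ensure descent direction
    } else {
      dir <- -g
    }
    amax <- max(sqrt(rowSums(dir^2)))
    if (amax < 1e-14) break
    alpha <- max_disp / amax
    accepted <- FALSE
    slope <- sum(g * dir)
    for (h in seq_len(max_halvings)) {
      xn <- x + alpha * dir
      en <- engine$energy(xn)
      if (!is.finite(en))
        stop("instability error: non-finite energy during line search at step ",
             steps + 1L)
      if (en < e) { accepted <- TRUE; break }
      # quadratic-interpolation backtrack (continuous in the energies,
      # which keeps minimization paths of near-identical conformations
      # close); falls toward halving via the clip bounds
      denom <- en - e - slope * alpha
      astar <- if (denom > 0) -slope * alpha^2 / (2 * denom) else alpha / 2
      alpha <- min(max(astar, 0.1 * alpha), 0.5 * alpha)
    }
    if (!accepted) break                     # converged to line-search resolution
    if (h == 1L) {
      # expand only while doubling still pays off substantially: steep
      # clash relaxation escapes the displacement cap, while gentle
      # drift (e.g. slow surface adsorption) stays at small steps so
      # that replicate lineages across shells remain comparable
      for (grow in 1:20) {
        xg <- x + (2 * alpha) * dir
        eg <- engine$energy(xg)
        if (!is.finite(eg) || en - eg < expand_gain) break
        alpha <- 2 * alpha; xn <- xg; en <- eg
      }
    }
    x <- xn; e <- en
    g_prev <- g; dir_prev <- dir
    g <- engine$gradient(x)
    grms <- sqrt(mean(g^2))
    steps <- steps + 1L
    trace[steps + 1L] <- e
  }
  structure(list(final_coordinates = x, final_energy = e,
                 energy_trace = trace[seq_len(steps + 1L)],
                 gradient_rms_final = grms, steps_taken = steps,
                 method_switch_step = method_switch_step),
            class = "minimization_result")
}

#' @export
print.minimization_result <- function(x, ...) {
  cat(sprintf("<minimization: %d steps, E=%.4f kcal/mol, |g|rms=%.3g>\n",
              x$steps_taken, x$final_energy, x$gradient_rms_final))
  invisible(x)
}

#' Minimize a template structure to a gradient tolerance
#'
#' Reference-complex preparation: minimize until the root-mean-square of
#' the Cartesian gradient components falls below `tol` (default
#' 0.1 kcal mol^-1 A^-1), switching from steepest descent to conjugate
#' gradient after `switch_step` steps (default 100).
#'
#' @param engine An energy model (see [toy_engine()]).
#' @param x N x 3 starting coordinates.
#' @param tol Gradient RMS convergence threshold, kcal mol^-1 A^-1.
#' @param switch_step Step at which the optimizer switches SD -> CG.
#' @param max_steps Iteration cap.
#' @return A `minimization_result` with fields `final_coordinates`,
#'   `final_energy`, `energy_trace`, `gradient_rms_final`, `steps_taken`,
#'   `method_switch_step`.
#' @export
minimize_template <- function(engine, x, tol = 0.1, switch_step = 100L,
                              max_steps = 5000L) {
  minimize_core(engine, x, max_steps = max_steps, tol = tol,
                switch_step = switch_step, fixed_steps = FALSE)
}

#' Minimize a generated conformation for a fixed number of steps
#'
#' Shell conformations are relaxed for exactly `n_min` steps (default
#' 100, switching SD -> CG after 10) unless the gradient vanishes or the
#' line search bottoms out earlier; the energy at the final step is the
#' sampled potential energy U entering the score.
#'
#' @inheritParams minimize_template
#' @param n_min Number of minimization steps.
#' @return A `minimization_result`.
#' @export
minimize_conformation <- function(engine, x, n_min = 100L, switch_step = 10L) {
  if (n_min == 0L) {
    e <- engine$energy(as.matrix(x))
    return(structure(list(final_coordinates = as.matrix(x), final_energy = e,
                          energy_trace = e,
                          gradient_rms_final = sqrt(mean(engine$gradient(x)^2)),
                          steps_taken = 0L, method_switch_step = NA_integer_),
                     class = "minimization_result"))
  }
  minimize_core(engine, x, max_steps = n_min, tol = 0,
                switch_step = switch_step, fixed_steps = TRUE)
}
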