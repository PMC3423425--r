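#' Langevin dynamics trajectory
#'
#' Thermostatted dynamics with the BAOAB splitting: a velocity-Verlet
#' kick/drift wrapped around an Ornstein-Uhlenbeck velocity update.  Used
#' to sample the ligand-bound state at 300 K.  Working units are
#' kcal/mol, Angstrom, amu and femtoseconds.  At `temperature = 0` the
#' noise vanishes and the integrator performs damped descent.
#'
#' The 1 fs default time step is far below the stability bound of the
#' stiffest default bond (k = 300 kcal mol^-1 A^-2 on a 12 amu atom:
#' period about 43 fs), so no constraint algorithm is needed.
#'
#' @param engine An energy model (see [toy_engine()]).
#' @param x N x 3 starting coordinates.
#' @param n_steps Number of integration steps.
#' @param temperature Kelvin (default 300).
#' @param friction Langevin collision frequency in ps^-1 (default 2.0).
#' @param dt Time step in fs (default 1.0).
#' @param seed RNG seed; a fixed seed replays the identical trajectory.
#' @param save_every Save a frame every this many steps (frames at steps
#'   `save_every, 2*save_every, ...`).
#' @return List with `frames` (list of saved N x 3 matrices), `final`
#'   (final coordinates), `saved_steps`, and `potential` (energy at each
#'   saved frame).
#' @export
run_langevin <- function(engine, x, n_steps, temperature = 300,
                         friction = 2.0, dt = 1.0, seed = 1L,
                         save_every = n_steps) {
  stopifnot(is_energy_model(engine), n_steps >= 1L, save_every >= 1L,
            temperature >= 0, friction >= 0, dt > 0)
  x <- as.matrix(x)
  n <- nrow(x)
  m <- engine$masses
  kT_int <- .kB * temperature * .KCAL_TO_INTERNAL   # amu A^2 fs^-2
  gam <- friction / 1000                            # ps^-1 -> fs^-1
  c1 <- exp(-gam * dt)
  sig_v <- sqrt(kT_int / m)                         # per-atom, A/fs
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  v <- matrix(rnorm(3 * n), n, 3) * sig_v
  if (temperature == 0) v[] <- 0
  f <- -engine$gradient(x) * .KCAL_TO_INTERNAL      # amu A fs^-2
  frames <- list(); saved_steps <- integer(); potential <- numeric()
  for (step in seq_len(n_steps)) {
    v <- v + (0.5 * dt) * f / m
    x <- x + (0.5 * dt) * v
    if (temperature > 0) {
      v <- c1 * v + sqrt(1 - c1^2) * sig_v * matrix(rnorm(3 * n), n, 3)
    } else {
      v <- c1 * v
    }
    x <- x + (0.5 * dt) * v
    f <- -engine$gradient(x) * .KCAL_TO_INTERNAL
    if (!all(is.finite(f)))
      stop("instability error: non-finite forces at step ", step)
    v <- v + (0.5 * dt) * f / m
    if (step %% save_every == 0L) {
      frames[[length(frames) + 1L]] <- x
      saved_steps <- c(saved_steps, step)
      e <- engine$energy(x)
      if (!is.finite(e))
        stop("instability error: non-finite energy at step ", step)
      potential <- c(potential, e)
    }
  }
  list(frames = frames, final = x, saved_steps = saved_steps,
       potential = potential)
}
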