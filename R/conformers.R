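#' Protein-ligand distance schedule
#'
#' Ordered ladder of protein-ligand distances r (Angstrom); the first
#' entry is always 0 (the bound state) and entries increase strictly.
#'
#' @param distances Numeric vector of r values.
#' @return An `r_schedule` object.
#' @export
r_schedule <- function(distances) {
  distances <- as.numeric(distances)
  if (!length(distances) || distances[1] != 0)
    stop("the first schedule entry must be exactly 0 (bound state)")
  if (any(!is.finite(distances)) || any(diff(distances) <= 0))
    stop("schedule distances must be finite and strictly increasing")
  structure(list(distances = distances), class = "r_schedule")
}

#' Default distance schedules
#'
#' `"r1"` is the default 12-point ladder
#' \{0, 0.5, 1, 2, 3, ..., 10\} Angstrom; `"r2"` is the fine 19-point
#' ladder adding 0.1/0.25 near the bound state and extending to 15.
#'
#' @param preset `"r1"` or `"r2"`.
#' @return An `r_schedule`.
#' @export
default_r_schedule <- function(preset = c("r1", "r2")) {
  preset <- match.arg(preset)
  d <- switch(preset,
    r1 = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    r2 = c(0, 0.1, 0.25, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15))
  r_schedule(d)
}

#' @export
print.r_schedule <- function(x, ...) {
  cat("<r_schedule:", paste(x$distances, collapse = ", "), "A>\n")
  invisible(x)
}

# deterministic per-(replicate, shell) RNG substream seed
substream_seed <- function(seed, j, i) {
  as.integer((abs(as.numeric(seed)) * 48271 + j * 97561 + i * 51407) %%
               2147483587) + 1L
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

rot_from_euler <- function(theta) rot_z(theta[3]) %*% rot_y(theta[2]) %*% rot_x(theta[1])

euler_from_rot <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(R[3, 2], R[3, 3]); c <- atan2(R[2, 1], R[1, 1])
  } else {   # gimbal-locked: fold everything into the x angle
    a <- atan2(-R[2, 3], R[2, 2]); c <- 0
  }
  c(a, b, c)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Draw a random rigid-body placement at distance r
#'
#' Generates the six numbers defining one random ligand placement: three
#' rotation angles (theta_x, theta_y, theta_z) and a displacement vector
#' (r_x, r_y, r_z) with `r_x^2 + r_y^2 + r_z^2 = r^2` exactly.  The
#' displacement direction is uniform on the sphere.  By default the
#' orientation is uniform over the rotation group (random unit
#' quaternion, re-expressed as Euler angles); `mode = "euler-naive"`
#' draws the three angles independently and uniformly on `[0, 2*pi)`
#' instead, which is not uniform over orientations but matches the
#' simplest literal reading of a three-angle protocol.
#'
#' @param r Target protein-ligand distance (> 0), Angstrom.
#' @param mode `"quaternion"` (default) or `"euler-naive"`.
#' @param seed Optional seed; when supplied the draw is a pure function
#'   of `(r, mode, seed)`.
#' @return A `placement_draw` list: `theta` (radians), `displacement`
#'   (length 3, Angstrom), `rotation` (3 x 3), `r`.
#' @export
random_placement_draw <- function(r, mode = c("quaternion", "euler-naive"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("r must be a single positive distance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (mode == "quaternion") {
    R <- quat_to_rot(rnorm(4))
    theta <- euler_from_rot(R)
    R <- rot_from_euler(theta)   # keep angles and matrix exactly consistent
  } else {
    theta <- runif(3, 0, 2 * pi)
    R <- rot_from_euler(theta)
  }
  u <- rnorm(3)
  while (sum(u^2) < 1e-12) u <- rnorm(3)
  disp <- u / sqrt(sum(u^2)) * r
  structure(list(theta = theta, displacement = disp, rotation = R, r = r),
            class = "placement_draw")
}

#' Apply a rigid-body placement to a complex conformation
#'
#' Rotates the ligand rigidly about its center of mass by the draw's
#' rotation, then displaces its center of mass by the draw's displacement
#' vector.  Receptor coordinates are untouched and all ligand internal
#' distances are preserved exactly.
#'
#' @param xyz Full-complex N x 3 coordinate matrix (receptor atoms first).
#' @param ligand_idx Row indices of the ligand atoms.
#' @param masses Per-atom masses for the ligand COM (full-length or
#'   ligand-length vector).
#' @param draw A `placement_draw`.
#' @return The transformed coordinate matrix.
#' @export
apply_placement <- function(xyz, ligand_idx, masses, draw) {
  xyz <- as.matrix(xyz)
  m <- if (length(masses) == nrow(xyz)) masses[ligand_idx] else masses
  lig <- xyz[ligand_idx, , drop = FALSE]
  com <- drop(crossprod(lig, m)) / sum(m)
  centered <- sweep(lig, 2, com)
  moved <- centered %*% t(draw$rotation)
  xyz[ligand_idx, ] <- sweep(moved, 2, com + draw$displacement, FUN = "+")
  xyz
}

#' Choose the receptor conformation for a shell
#'
#' Flexible targets that close around the ligand are handled with two
#' receptor conformations: the holo (closed) receptor is only valid with
#' the ligand bound, so it is used at r = 0, and the apo (open) receptor
#' at every r > 0.  Without an apo structure the single receptor is used
#' everywhere.
#'
#' @param shell_r Shell distance (Angstrom).
#' @param system A `complex_system`.
#' @return List with `receptor` (a `molecular_structure`) and `label`
#'   (`"holo"`, `"apo"`, or `"receptor"`).
#' @export
select_receptor_variant <- function(shell_r, system) {
  stopifnot(inherits(system, "complex_system"))
  if (is.null(system$receptor_apo))
    return(list(receptor = system$receptor, label = "receptor"))
  if (shell_r == 0)
    list(receptor = system$receptor, label = "holo")
  else
    list(receptor = system$receptor_apo, label = "apo")
}

#' Sample the ligand-bound state
#'
#' Short thermostatted Langevin trajectory of the (already minimized)
#' complex at `temperature`, saving `n_snapshots` frames at uniform time
#' intervals; the defaults (10 ps, 0.1 ps cadence) yield 100 bound-state
#' conformations.
#'
#' @param system A `complex_system`.
#' @param engine Energy model for the holo complex.
#' @param x0 Starting (minimized template) coordinates.
#' @param n_snapshots Number of frames to return.
#' @param t_ps Trajectory length in ps.
#' @param dt Time step in fs.
#' @param temperature Kelvin.
#' @param friction Collision frequency, ps^-1.
#' @param seed RNG seed.
#' @return List of N x 3 coordinate matrices of length `n_snapshots`.
#' @export
sample_bound_state <- function(system, engine, x0, n_snapshots = 100L,
                               t_ps = 10, dt = 1.0, temperature = 300,
                               friction = 2.0, seed = 1L) {
  stopifnot(n_snapshots >= 1L)
  cadence <- max(1L, as.integer(round(t_ps * 1000 / dt / n_snapshots)))
  n_steps <- cadence * n_snapshots
  traj <- run_langevin(engine, x0, n_steps = n_steps,
                       temperature = temperature, friction = friction,
                       dt = dt, seed = seed, save_every = cadence)
  traj$frames
}

#' Generate the replicate-by-shell conformation grid
#'
#' The heart of the MRC protocol.  The template complex is minimized to
#' the gradient tolerance, the bound state (r = 0) is sampled with a
#' short Langevin trajectory into `n_conf` snapshots, and every nonzero
#' shell is filled by giving each snapshot's ligand an independent random
#' rigid-body placement at that shell's distance.  Every conformation
#' (including the bound-state snapshots, for grid uniformity) is then
#' energy-minimized for `n_min` steps and the final-step potential energy
#' is recorded as `U[replicate, shell]`.
#'
#' Placements that bring any ligand atom within `clash_dist` of the
#' receptor are redrawn up to `clash_retries` times; if no clash-free
#' draw is found the last draw is kept and left to the
#' displacement-capped minimizer to relax.
#'
#' With the defaults (`n_conf = 100`, the 12-point "r1" schedule) the
#' grid holds 1,200 conformations.
#'
#' @param system A `complex_system`.
#' @param schedule An `r_schedule` (default preset "r1").
#' @param n_conf Replicates per shell.
#' @param n_min Minimization steps per conformation.
#' @param seed Top-level RNG seed; per-(replicate, shell) substreams are
#'   derived from it deterministically, so results do not depend on
#'   generation order.
#' @param eps_in Interior dielectric for the built-in engine.
#' @param engine Optional energy model factory `function(receptor,
#'   ligand)`; defaults to [toy_engine()] with `eps_in` and
#'   `engine_args`.
#' @param engine_args Extra arguments for [toy_engine()].
#' @param sampler List of bound-state sampler settings: `t_ps`, `dt`,
#'   `temperature`, `friction`.
#' @param placement_mode Orientation sampling mode, see
#'   [random_placement_draw()].
#' @param clash_dist,clash_retries Clash screening parameters (Angstrom,
#'   count).
#' @param template_tol Gradient tolerance for the template minimization.
#' @param store_conformations Keep the minimized coordinates (TRUE) or
#'   only the energy grid.
#' @return A `conformation_set`: `schedule`, `n_replicates`, `energies`
#'   (n_conf x n_shells matrix, kcal/mol), `conformations`, `draws`,
#'   `receptor_variant_used`, plus provenance fields.
#' @export
generate_conformation_set <- function(system, schedule = default_r_schedule(),
                                      n_conf = 100L, n_min = 100L, seed = 1L,
                                      eps_in = 1, engine = NULL,
                                      engine_args = list(),
                                      sampler = list(),
                                      placement_mode = "quaternion",
                                      clash_dist = 0.8, clash_retries = 50L,
                                      template_tol = 0.1,
                                      store_conformations = TRUE) {
  stopifnot(inherits(system, "complex_system"), inherits(schedule, "r_schedule"),
            n_conf >= 1L, n_min >= 0L)
  sampler <- modifyList(list(t_ps = 10, dt = 1.0, temperature = 300,
                             friction = 2.0), sampler)
  make_engine <- if (is.null(engine)) {
    function(rec, lig) do.call(toy_engine,
                               c(list(list(rec, lig), eps_in = eps_in), engine_args))
  } else if (is.function(engine)) {
    engine
  } else if (is_energy_model(engine)) {
    if (!is.null(system$receptor_apo))
      stop("a single energy model cannot serve both receptor variants; ",
           "pass a factory function(receptor, ligand)")
    function(rec, lig) engine
  } else stop("engine must be NULL, a factory function, or an energy model")

  rs <- schedule$distances
  n_shells <- length(rs)
  n_rec <- nrow(system$receptor$atoms)
  lig_idx <- n_rec + seq_len(nrow(system$ligand$atoms))
  masses_lig <- system$ligand$atoms$mass

  eng_holo <- make_engine(system$receptor, system$ligand)
  eng_apo <- if (!is.null(system$receptor_apo))
    make_engine(system$receptor_apo, system$ligand) else NULL

  x0 <- rbind(coords(system$receptor), coords(system$ligand))
  tmpl <- minimize_template(eng_holo, x0, tol = template_tol)
  snaps <- sample_bound_state(system, eng_holo, tmpl$final_coordinates,
                              n_snapshots = n_conf, t_ps = sampler$t_ps,
                              dt = sampler$dt,
                              temperature = sampler$temperature,
                              friction = sampler$friction,
                              seed = substream_seed(seed, 0L, 0L))

  U <- matrix(NA_real_, n_conf, n_shells)
  confs <- if (store_conformations) vector("list", n_conf) else NULL
  draws <- vector("list", n_conf)
  variant <- character(n_shells)
  apo_xyz <- if (!is.null(system$receptor_apo)) coords(system$receptor_apo)

  for (i in seq_len(n_shells)) {
    sel <- select_receptor_variant(rs[i], system)
    variant[i] <- sel$label
    eng_i <- if (identical(sel$label, "apo")) eng_apo else eng_holo
    for (j in seq_len(n_conf)) {
      if (store_conformations && is.null(confs[[j]]))
        confs[[j]] <- vector("list", n_shells)
      if (is.null(draws[[j]])) draws[[j]] <- vector("list", n_shells)
      if (rs[i] == 0) {
        x <- snaps[[j]]
      } else {
        x <- snaps[[j]]
        if (identical(sel$label, "apo")) x[seq_len(n_rec), ] <- apo_xyz
        set.seed(substream_seed(seed, j, i))
        placed <- NULL
        for (try_k in seq_len(max(1L, clash_retries))) {
          dr <- random_placement_draw(rs[i], mode = placement_mode)
          cand <- apply_placement(x, lig_idx, masses_lig, dr)
          dmin <- min_cross_distance_cpp(cand[seq_len(n_rec), , drop = FALSE],
                                         cand[lig_idx, , drop = FALSE])
          placed <- cand
          if (dmin >= clash_dist) break
        }
        draws[[j]][[i]] <- dr
        x <- placed
      }
      mres <- minimize_conformation(eng_i, x, n_min = n_min)
      if (!is.finite(mres$final_energy))
        stop("generation error: non-finite energy at replicate ", j,
             ", shell ", i)
      U[j, i] <- mres$final_energy
      if (store_conformations) confs[[j]][[i]] <- mres$final_coordinates
    }
  }
  structure(list(schedule = schedule, n_replicates = n_conf, energies = U,
                 conformations = confs, draws = draws,
                 receptor_variant_used = variant, seed = seed,
                 eps_in = eng_holo$eps_in, n_min = n_min,
                 placement_mode = placement_mode,
                 template_energy = tmpl$final_energy),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf(paste0("<conformation_set: %d replicates x %d shells = %d ",
                     "conformations, eps_in=%g, seed=%s>\n"),
              x$n_replicates, length(x$schedule$distances),
              x$n_replicates * length(x$schedule$distances),
              x$eps_in, format(x$seed)))
  invisible(x)
}
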