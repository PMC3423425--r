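# Deterministic toy receptor/ligand systems.  The receptor is a bonded
# cage of LJ sites forming a concave pocket (a spherical cup opening
# toward +x); the ligand is a small rigid cluster seated in the pocket.
# Binding strength is controlled through the LJ well depth of the pocket
# atoms: pair epsilon between a pocket atom and a ligand atom equals
# `pocket_depth` exactly, which makes the receptor-ligand interaction
# energy affine in `pocket_depth` at fixed geometry -- the property the
# ranking-recovery experiments rely on.

golden_spiral <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Toy-system specification
#'
#' @param n_receptor_atoms Number of receptor cage atoms (<= 64 keeps the
#'   full default grid desk-scale).
#' @param pocket_depth Pair LJ well depth (kcal/mol) between pocket atoms
#'   and ligand atoms; 0 gives a non-binding cage.
#' @param ligand_size Number of ligand atoms (<= 8 recommended).
#' @param ligand_charge Total ligand charge (e), spread evenly.
#' @param seed Seed controlling the deterministic geometry jitter.
#' @param receptor_radius Cage radius in Angstrom.
#' @param apo Also build an open-state (radially dilated) receptor.
#' @param apo_dilation Radial dilation factor of the apo cage.
#' @param lj_sigma LJ sigma (Angstrom) of every atom; smaller values
#'   shorten the interaction range of the whole system.
#' @param relax Energy-minimize the assembled complex so the ligand sits
#'   at a genuine local minimum of the toy potential.
#' @return A `toy_system_spec` list.
#' @export
toy_system_spec <- function(n_receptor_atoms = 48L, pocket_depth = 3,
                            ligand_size = 4L, ligand_charge = 0, seed = 1L,
                            receptor_radius = 4.0, apo = FALSE,
                            apo_dilation = 1.3, lj_sigma = 3.0,
                            relax = TRUE) {
  stopifnot(n_receptor_atoms >= 1L, pocket_depth >= 0, ligand_size >= 1L)
  structure(list(n_receptor_atoms = as.integer(n_receptor_atoms),
                 pocket_depth = pocket_depth,
                 ligand_size = as.integer(ligand_size),
                 ligand_charge = ligand_charge, seed = as.integer(seed),
                 receptor_radius = receptor_radius, apo = apo,
                 apo_dilation = apo_dilation, lj_sigma = lj_sigma,
                 relax = relax),
            class = "toy_system_spec")
}

.LIG_EPS <- 0.25    # ligand LJ epsilon; pocket receptor eps = depth^2 / this
.RIM_EPS <- 0.01    # non-pocket receptor epsilon (weak wall repulsion)

nearest_neighbour_bonds <- function(xyz, k = 3L, kb = 100) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pairs <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:min(n, k + 1L)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  data.frame(i = pairs[, 1], j = pairs[, 2], kb = kb,
             b0 = d[pairs])
}

#' Build a deterministic toy protein-ligand complex
#'
#' See [toy_system_spec()] for the dials.  The returned system carries a
#' `fixture_meta` attribute recording the pocket atom indices and the
#' depth-to-epsilon mapping, so derived fixtures (ligand series) can
#' retune the binding strength without touching the geometry.
#'
#' @param spec A `toy_system_spec`.
#' @return A `complex_system`.
#' @export
make_toy_complex <- function(spec = toy_system_spec()) {
  stopifnot(inherits(spec, "toy_system_spec"))
  set.seed(spec$seed)
  # cup: sphere points whose direction avoids the +x opening
  dirs <- golden_spiral(3L * spec$n_receptor_atoms + 8L)
  dirs <- dirs[dirs[, 1] < 0.55, , drop = FALSE]
  if (nrow(dirs) < spec$n_receptor_atoms)
    stop("receptor atom count too large for the cup construction")
  dirs <- dirs[seq_len(spec$n_receptor_atoms), , drop = FALSE]
  rec_xyz <- dirs * spec$receptor_radius +
    matrix(rnorm(3 * spec$n_receptor_atoms, sd = 0.05), ncol = 3)
  pocket_idx <- which(dirs[, 1] < -0.25)
  if (!length(pocket_idx)) pocket_idx <- which.min(dirs[, 1])
  rec_eps <- rep(.RIM_EPS, spec$n_receptor_atoms)
  rec_eps[pocket_idx] <- spec$pocket_depth^2 / .LIG_EPS
  rec_atoms <- data.frame(
    name = paste0("R", seq_len(spec$n_receptor_atoms)), element = "C",
    x = rec_xyz[, 1], y = rec_xyz[, 2], z = rec_xyz[, 3],
    charge = 0, sigma = spec$lj_sigma, epsilon = rec_eps, born_radius = 1.7,
    mass = 12,
    resno = seq_len(spec$n_receptor_atoms), resid = "CAG", chain = "A",
    stringsAsFactors = FALSE)
  receptor <- molecular_structure(rec_atoms,
                                  nearest_neighbour_bonds(rec_xyz),
                                  role = "receptor", label = "toy_receptor")

  nl <- spec$ligand_size
  lig_xyz <- if (nl == 1L) matrix(0, 1, 3) else
    rbind(c(0, 0, 0), golden_spiral(nl - 1L) * 1.2)
  lig_bonds <- if (nl > 1L)
    data.frame(i = 1L, j = 2:nl, kb = 300,
               b0 = sqrt(rowSums(lig_xyz[-1, , drop = FALSE]^2)))
  lig_atoms <- data.frame(
    name = paste0("L", seq_len(nl)), element = "C",
    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    charge = spec$ligand_charge / nl, sigma = spec$lj_sigma, epsilon = .LIG_EPS,
    born_radius = 1.5, mass = 12, resno = 1L, resid = "LIG", chain = "B",
    stringsAsFactors = FALSE)
  ligand <- molecular_structure(lig_atoms, lig_bonds,
                                role = "ligand", label = "toy_ligand")

  if (spec$relax) {
    eng <- toy_engine(list(receptor, ligand), eps_in = 1)
    x <- rbind(coords(receptor), coords(ligand))
    res <- minimize_template(eng, x, tol = 0.3, max_steps = 400L)
    receptor <- set_coords(receptor,
                           res$final_coordinates[seq_len(nrow(rec_atoms)), ,
                                                 drop = FALSE])
    ligand <- set_coords(ligand,
                         res$final_coordinates[nrow(rec_atoms) + seq_len(nl), ,
                                               drop = FALSE])
  }
  receptor_apo <- NULL
  if (spec$apo) {
    ctr <- center_of_mass(ligand)
    axyz <- sweep(sweep(coords(receptor), 2, ctr), 2, rep(spec$apo_dilation, 3),
                  FUN = "*")
    axyz <- sweep(axyz, 2, ctr, FUN = "+")
    receptor_apo <- receptor
    receptor_apo <- set_coords(receptor_apo, axyz)
    # uniform dilation scales every pairwise distance by the same factor
    receptor_apo$bonds$b0 <- receptor$bonds$b0 * spec$apo_dilation
    receptor_apo$label <- "toy_receptor_apo"
  }
  sys <- complex_system(receptor, ligand, receptor_apo)
  attr(sys, "fixture_meta") <- list(spec = spec, pocket_idx = pocket_idx,
                                    lig_eps = .LIG_EPS)
  sys
}

#' Retune the pocket depth of a toy complex without moving atoms
#'
#' @param system A toy `complex_system` from [make_toy_complex()].
#' @param depth New pocket depth (kcal/mol).
#' @return The retuned system.
#' @export
set_pocket_depth <- function(system, depth) {
  meta <- attr(system, "fixture_meta")
  if (is.null(meta)) stop("not a toy fixture (no fixture_meta)")
  stopifnot(depth >= 0)
  for (fld in c("receptor", "receptor_apo")) {
    if (is.null(system[[fld]])) next
    system[[fld]]$atoms$epsilon[meta$pocket_idx] <- depth^2 / meta$lig_eps
  }
  meta$spec$pocket_depth <- depth
  attr(system, "fixture_meta") <- meta
  system
}

#' Synthetic ligand series with pseudo-experimental affinities
#'
#' One complex per pocket depth, all sharing the base system's geometry
#' (only the pocket epsilon changes), with pseudo-experimental binding
#' free energies assigned as the affine map
#' `dg_exp = dg_intercept + dg_slope * depth` plus seeded Gaussian noise.
#' With `noise_sd = 0` the affinities are an exact affine function of
#' depth, so any scoring method whose output is affine in depth attains
#' |Pearson R| = 1 by construction.
#'
#' @param base A `toy_system_spec` for the shared geometry.
#' @param depths Numeric vector (>= 3) of pocket depths, kcal/mol.
#' @param dg_slope,dg_intercept Affine affinity map (kcal/mol per
#'   kcal/mol, kcal/mol); the negative default slope makes deeper
#'   pockets stronger binders.
#' @param noise_sd Gaussian noise added to `dg_exp`, kcal/mol.
#' @param seed Seed for the noise.
#' @return List of entries `list(label, system, depth, dg_exp)` with a
#'   `series_meta` attribute describing the mapping.
#' @export
make_ligand_series <- function(base = toy_system_spec(), depths = c(1, 2, 3, 4, 5),
                               dg_slope = -1.2, dg_intercept = -2.0,
                               noise_sd = 0, seed = 1L) {
  if (length(depths) < 3L) stop("need at least 3 depths")
  sys0 <- make_toy_complex(base)
  set.seed(as.integer(seed))
  noise <- rnorm(length(depths), sd = noise_sd)
  out <- lapply(seq_along(depths), function(k) {
    list(label = sprintf("LIG%02d", k),
         system = set_pocket_depth(sys0, depths[k]),
         depth = depths[k],
         dg_exp = dg_intercept + dg_slope * depths[k] + noise[k])
  })
  attr(out, "series_meta") <- list(dg_slope = dg_slope,
                                   dg_intercept = dg_intercept,
                                   noise_sd = noise_sd, seed = seed,
                                   depths = depths)
  out
}

#' Synthetic docking pose set with prescribed RMSDs
#'
#' Perturbs the reference ligand by a rigid rotation (about the heavy-
#' atom centroid) plus translation chosen in closed form so that the
#' ligand RMSD after receptor fit equals each requested target.  Because
#' the rotation center is the unweighted heavy-atom centroid, the
#' rotational and translational RMSD contributions add in quadrature and
#' the targets are met essentially exactly (checked to 0.01 Angstrom).
#'
#' @param reference A `complex_system`.
#' @param target_rmsds Non-negative target RMSDs, Angstrom.
#' @param seed RNG seed for the perturbation directions.
#' @param rotation_fraction Fraction (0..1) of the target RMSD assigned
#'   to the rotational component; requires >= 2 heavy ligand atoms when
#'   positive.
#' @param dg_exp Optional experimental affinity recorded on the set.
#' @return A `pose_set` whose k-th pose matches `target_rmsds[k]`.
#' @export
make_pose_set <- function(reference, target_rmsds, seed = 1L,
                          rotation_fraction = 0.5, dg_exp = NA_real_) {
  stopifnot(inherits(reference, "complex_system"), all(target_rmsds >= 0))
  heavy <- is_heavy(reference$ligand)
  if (rotation_fraction > 0 && sum(heavy) < 2L)
    stop("generation error: rotational perturbation unreachable for a ",
         "single-heavy-atom ligand")
  poses <- lapply(seq_along(target_rmsds), function(k) {
    target <- target_rmsds[k]
    if (target == 0) return(reference)
    set.seed(substream_seed(seed, k, 1L))
    lig <- coords(reference$ligand)
    ctr <- colMeans(lig[heavy, , drop = FALSE])
    rot_target <- rotation_fraction * target
    Rk <- diag(3); rot_rmsd <- 0
    if (rot_target > 0) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      perp2 <- rowSums(sweep(lig[heavy, , drop = FALSE], 2, ctr)^2) -
        (sweep(lig[heavy, , drop = FALSE], 2, ctr) %*% ax)^2
      rho <- sqrt(mean(pmax(0, perp2)))   # rms distance from the axis
      theta <- if (2 * rho <= rot_target) pi else 2 * asin(rot_target / (2 * rho))
      Rk <- rotation_about_axis(ax, theta)
      disp <- sweep(lig[heavy, , drop = FALSE], 2, ctr) %*% t(Rk) -
        sweep(lig[heavy, , drop = FALSE], 2, ctr)
      rot_rmsd <- sqrt(mean(rowSums(disp^2)))
    }
    t_mag <- sqrt(max(0, target^2 - rot_rmsd^2))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    new_lig <- sweep(sweep(lig, 2, ctr) %*% t(Rk), 2, ctr + t_mag * u, FUN = "+")
    pose <- reference
    pose$ligand <- set_coords(pose$ligand, new_lig)
    pose
  })
  ps <- pose_set(label = reference$ligand$label, reference = reference,
                 poses = poses, dg_exp = dg_exp)
  achieved <- vapply(poses, function(p)
    ligand_rmsd_after_receptor_fit(reference, p), numeric(1))
  if (any(abs(achieved - target_rmsds) > 0.01))
    stop("generation error: pose RMSD target missed by more than 0.01 A")
  attr(ps, "achieved_rmsd") <- achieved
  ps
}

rotation_about_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Exhaustive placement enumeration of the energy grid
#'
#' Replaces the random sampling of [generate_conformation_set()] with a
#' deterministic grid: rotations about `n_axes` golden-spiral axes by
#' `n_angles` evenly spaced angles, crossed with `n_dir` displacement
#' directions, all applied to the reference conformation.  The bound-
#' state column replicates the reference energy.  Used for estimator-
#' consistency checks against [brute_force_score_oracle()].
#'
#' @param system A `complex_system`.
#' @param schedule An `r_schedule`.
#' @param n_axes,n_angles,n_dir Grid resolution (total placements per
#'   shell = `n_axes * n_angles * n_dir`, capped at 10^4).
#' @param n_min Minimization steps applied to every grid point.
#' @param eps_in Interior dielectric.
#' @param engine_args Extra [toy_engine()] arguments.
#' @return Energy matrix with one row per grid point and one column per
#'   shell.
#' @export
enumerate_placement_energies <- function(system, schedule, n_axes = 3L,
                                         n_angles = 4L, n_dir = 6L,
                                         n_min = 0L, eps_in = 1,
                                         engine_args = list()) {
  stopifnot(inherits(system, "complex_system"), inherits(schedule, "r_schedule"))
  n_grid <- n_axes * n_angles * n_dir
  if (n_grid > 1e4) stop("size error: enumeration budget exceeded (", n_grid,
                         " > 10000 grid points per shell)")
  axes <- golden_spiral(n_axes)
  angles <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  dirs <- golden_spiral(n_dir)
  eng <- do.call(toy_engine,
                 c(list(list(system$receptor, system$ligand), eps_in = eps_in),
                   engine_args))
  x0 <- rbind(coords(system$receptor), coords(system$ligand))
  n_rec <- nrow(system$receptor$atoms)
  lig_idx <- n_rec + seq_len(nrow(system$ligand$atoms))
  m_lig <- system$ligand$atoms$mass
  rs <- schedule$distances
  U <- matrix(NA_real_, n_grid, length(rs))
  e0 <- minimize_conformation(eng, x0, n_min = n_min)$final_energy
  for (i in seq_along(rs)) {
    if (rs[i] == 0) { U[, i] <- e0; next }
    g <- 0L
    for (a in seq_len(n_axes)) for (t in seq_along(angles)) {
      Rk <- rotation_about_axis(axes[a, ], angles[t])
      for (d in seq_len(n_dir)) {
        g <- g + 1L
        draw <- structure(list(theta = NULL, rotation = Rk,
                               displacement = dirs[d, ] * rs[i], r = rs[i]),
                          class = "placement_draw")
        x <- apply_placement(x0, lig_idx, m_lig, draw)
        U[g, i] <- minimize_conformation(eng, x, n_min = n_min)$final_energy
      }
    }
  }
  U
}

#' Brute-force score oracle by full enumeration
#'
#' Independent reference for the score estimator: enumerates the same
#' deterministic placement grid as [enumerate_placement_energies()] and
#' computes each transition's increment directly as
#' `-kT * log(mean(exp(-U_near/kT)) / mean(exp(-U_far/kT)))` with naive
#' arithmetic (no log-sum-exp shift), i.e. the ratio of the shells'
#' Boltzmann sums under the uniform enumeration measure.  Suitable for
#' toy systems with moderate energies only.
#'
#' @inheritParams enumerate_placement_energies
#' @param kT Thermal energy, kcal/mol.
#' @return A `score_result` with the enumerated energy grid attached as
#'   attribute `energies`.
#' @export
brute_force_score_oracle <- function(system, schedule, n_axes = 3L,
                                     n_angles = 4L, n_dir = 6L, n_min = 0L,
                                     eps_in = 1, kT = kT_at(300),
                                     engine_args = list()) {
  U <- enumerate_placement_energies(system, schedule, n_axes, n_angles,
                                    n_dir, n_min, eps_in, engine_args)
  n_tr <- ncol(U) - 1L
  shell_scores <- vapply(seq_len(n_tr), function(i) {
    -kT * log(mean(exp(-U[, i] / kT)) / mean(exp(-U[, i + 1L] / kT)))
  }, numeric(1))
  structure(list(shell_scores = shell_scores,
                 total_score = sum(shell_scores), kT = kT,
                 epsilon_in = eps_in, pairing_mode = "ensemble",
                 direction = "binding", n_replicates = nrow(U),
                 schedule = schedule),
            class = "score_result", energies = U)
}

#' Write a toy fixture to disk as PDB + parameter TSV
#'
#' Emits `receptor.pdb`, `ligand.pdb`, optionally `receptor_apo.pdb`, a
#' combined `params.tsv` covering every atom name, and `spec.json` with
#' the generating specification, so a fixture can be consumed through
#' the same file-based interface as real inputs.
#'
#' @param system A `complex_system` (typically from [make_toy_complex()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_fixture_dir <- function(system, dir) {
  stopifnot(inherits(system, "complex_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(system$receptor, file.path(dir, "receptor.pdb"))
  write_pdb(system$ligand, file.path(dir, "ligand.pdb"))
  if (!is.null(system$receptor_apo))
    write_pdb(system$receptor_apo, file.path(dir, "receptor_apo.pdb"))
  at <- rbind(system$receptor$atoms, system$ligand$atoms)
  tab <- unique(at[, c("name", "charge", "sigma", "epsilon", "born_radius",
                       "mass")])
  names(tab)[1] <- "atom_name"
  write.table(tab, file.path(dir, "params.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- attr(system, "fixture_meta")
  if (!is.null(meta))
    jsonlite::write_json(unclass(meta$spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE)
  invisible(dir)
}
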