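#' Built-in toy MM-GBSA energy model
#'
#' Constructs an energy model over one or more molecules (typically
#' `list(receptor, ligand)`).  The potential is a deliberately small but
#' complete MM-GBSA functional form with fixed per-atom Born radii:
#' harmonic bonds, Lennard-Jones 12-6 with Lorentz-Berthelot combining,
#' Coulomb electrostatics screened by the interior dielectric, the Still
#' pairwise generalized-Born polar solvation term, and a nonpolar term
#' proportional to the Shrake-Rupley solvent-accessible surface area.
#' Nonbonded interactions act between all inter-molecular atom pairs and
#' between intra-molecular pairs separated by at least three bonds.
#'
#' The returned object satisfies the energy-model contract used
#' everywhere else in the package: a list with `energy(x)`, `gradient(x)`,
#' `eps_in`, `eps_w`, `masses` and `n_atoms`.  Any list with those fields
#' (for example an adapter around an external molecular-mechanics engine)
#' can stand in for it.
#'
#' The SASA term is evaluated on a finite point lattice and is therefore
#' locally constant in the coordinates; it contributes to the energy but
#' not to the analytic gradient.
#'
#' @param molecules A `molecular_structure` or list of them; atoms are
#'   concatenated in list order.
#' @param eps_in Interior (solute) dielectric constant; the paper-style
#'   sweep uses 1, 2 and 4.
#' @param eps_w Solvent dielectric constant (default 78.5).
#' @param gamma_sasa Surface-tension coefficient, kcal mol^-1 A^-2
#'   (default 0.005); set to 0 to disable the nonpolar term.
#' @param sasa_points Sphere-lattice resolution for the SASA evaluation.
#' @param probe Solvent probe radius in Angstrom.
#' @return An object of class `energy_model`.
#' @export
toy_engine <- function(molecules, eps_in = 1, eps_w = 78.5,
                       gamma_sasa = 0.005, sasa_points = 144, probe = 1.4) {
  if (inherits(molecules, "molecular_structure")) molecules <- list(molecules)
  stopifnot(length(molecules) >= 1L, eps_in > 0, eps_w > 0)
  counts <- vapply(molecules, function(m) nrow(m$atoms), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  at <- do.call(rbind, lapply(molecules, function(m)
    m$atoms[, c("charge", "sigma", "epsilon", "born_radius", "mass")]))
  bonds <- do.call(rbind, Map(function(m, off) {
    b <- m$bonds
    if (nrow(b)) data.frame(i = b$i + off, j = b$j + off, kb = b$kb, b0 = b$b0)
    else b
  }, molecules, as.list(offsets)))
  mol_id <- rep(seq_along(molecules), counts)
  nb <- nonbonded_pairs(nrow(at), bonds, mol_id)
  eng <- list(
    eps_in = eps_in, eps_w = eps_w, gamma_sasa = gamma_sasa,
    sasa_points = as.integer(sasa_points), probe = probe,
    n_atoms = nrow(at), masses = at$mass, mol_id = mol_id,
    charge = at$charge, sigma = at$sigma, lj_eps = at$epsilon,
    born = at$born_radius,
    bonds = as.matrix(bonds[, c("i", "j"), drop = FALSE]) - 1L,
    kb = bonds$kb, b0 = bonds$b0, nb = nb - 1L)
  storage.mode(eng$bonds) <- "integer"
  storage.mode(eng$nb) <- "integer"
  eng$energy <- function(x) .toy_eval(eng, x, grad = FALSE)$energy
  eng$gradient <- function(x) .toy_eval(eng, x, grad = TRUE, sasa = FALSE)$gradient
  eng$energy_components <- function(x) .toy_eval(eng, x, grad = FALSE)$components
  class(eng) <- "energy_model"
  eng
}

.toy_eval <- function(eng, x, grad = FALSE, sasa = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == eng$n_atoms, ncol(x) == 3L)
  res <- toy_energy_cpp(x, eng$charge, eng$sigma, eng$lj_eps, eng$born,
                        eng$bonds, eng$kb, eng$b0, eng$nb,
                        eng$eps_in, eng$eps_w, 0, eng$sasa_points,
                        eng$probe, grad, FALSE)
  if (sasa && eng$gamma_sasa != 0) {
    # evaluate the lattice SASA in the configuration's principal-axes
    # frame so the energy is invariant under global rigid motions
    a <- sasa_cpp(align_principal(x), eng$born, eng$sasa_points, eng$probe)
    res$sasa_area <- a
    res$components[["sasa"]] <- eng$gamma_sasa * a
    res$energy <- res$energy + eng$gamma_sasa * a
  }
  res
}

# deterministic body frame: principal axes of the unweighted coordinate
# covariance, signs fixed by the third (then fourth) moment of the
# projections so the frame co-rotates with the molecule
align_principal <- function(x) {
  ctr <- colMeans(x)
  X <- sweep(x, 2, ctr)
  V <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors
  P <- X %*% V
  for (k in 1:3) {
    m3 <- sum(P[, k]^3)
    s <- if (abs(m3) > 1e-8) sign(m3) else {
      m1 <- sum(P[, k])
      if (abs(m1) > 1e-8) sign(m1) else 1
    }
    if (s < 0) P[, k] <- -P[, k]
  }
  P
}

#' Toy MM-GBSA potential energy of a configuration
#'
#' Convenience wrapper building a one-shot [toy_engine()] around the
#' supplied molecules and evaluating it at `x` (or at the molecules' own
#' coordinates).
#'
#' @inheritParams toy_engine
#' @param x Optional N x 3 coordinate matrix overriding the structure
#'   coordinates.
#' @param ... Passed to [toy_engine()].
#' @return Energy in kcal/mol with a `components` attribute.
#' @export
toy_gbsa_energy <- function(molecules, x = NULL, eps_in = 1, ...) {
  eng <- toy_engine(molecules, eps_in = eps_in, ...)
  if (is.null(x)) {
    if (inherits(molecules, "molecular_structure")) molecules <- list(molecules)
    x <- do.call(rbind, lapply(molecules, coords))
  }
  res <- .toy_eval(eng, x)
  structure(res$energy, components = res$components)
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("<energy_model: %d atoms, %d bonds, %d nonbonded pairs, ",
                     "eps_in=%g, eps_w=%g, gamma_sasa=%g>\n"),
              x$n_atoms, nrow(x$bonds), nrow(x$nb), x$eps_in, x$eps_w,
              x$gamma_sasa))
  invisible(x)
}

is_energy_model <- function(x) {
  is.list(x) && is.function(x$energy) && is.function(x$gradient) &&
    is.numeric(x$masses)
}

# nonbonded pair list: all cross-molecule pairs, plus intra-molecular pairs
# whose bond-graph distance is >= 3 (1-2 and 1-3 pairs excluded)
nonbonded_pairs <- function(n, bonds, mol_id) {
  if (n < 2L) return(matrix(integer(), 0, 2))
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  excl <- vector("list", n)  # neighbours within 2 bonds
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one], use.names = FALSE))
    excl[[i]] <- setdiff(unique(c(one, two)), i)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    keep[k] <- mol_id[i] != mol_id[j] || !(j %in% excl[[i]])
  }
  unname(pairs[keep, , drop = FALSE])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param radius Per-atom radii (Angstrom); the toy engine uses the Born
#'   radii here.
#' @param n_points Sphere-lattice resolution.
#' @param probe Probe radius (Angstrom, default 1.4).
#' @return Area in Angstrom^2.
#' @export
sasa <- function(xyz, radius, n_points = 960, probe = 1.4) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == length(radius))
  sasa_cpp(xyz, as.numeric(radius), as.integer(n_points), probe)
}
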