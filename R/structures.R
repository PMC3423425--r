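#' Molecular structure container
#'
#' A `molecular_structure` holds an ordered atom table plus harmonic-bond
#' terms.  It is the common currency of the package: readers produce it,
#' the energy engine consumes it, and fixtures construct it directly.
#'
#' @param atoms data.frame with one row per atom and columns `name`,
#'   `element`, `x`, `y`, `z` (Angstrom), `charge` (e), `sigma` (Angstrom),
#'   `epsilon` (kcal/mol), `born_radius` (Angstrom), `mass` (amu).
#'   Optional `resno`, `resid`, `chain` columns are filled with defaults
#'   when absent.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `kb` (kcal mol^-1 A^-2) and `b0` (Angstrom).  May be empty.
#' @param role `"receptor"` or `"ligand"`.
#' @param label identifier used in reports.
#' @return An object of class `molecular_structure`.
#' @export
molecular_structure <- function(atoms, bonds = NULL, role = c("receptor", "ligand"),
                                label = "mol") {
  role <- match.arg(role)
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) < 1L)
    stop("a molecular_structure needs at least one atom")
  needed <- c("name", "element", "x", "y", "z", "charge", "sigma",
              "epsilon", "born_radius", "mass")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$resno)) atoms$resno <- 1L
  if (is.null(atoms$resid))
    atoms$resid <- if (role == "ligand") "LIG" else "REC"
  if (is.null(atoms$chain)) atoms$chain <- if (role == "ligand") "B" else "A"
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite atom coordinates")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  if (any(atoms$sigma <= 0)) stop("lj sigma must be positive")
  if (any(atoms$epsilon < 0)) stop("lj epsilon must be non-negative")
  if (any(atoms$born_radius <= 0)) stop("born radii must be positive")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(),
                        kb = numeric(), b0 = numeric())
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "kb", "b0") %in% names(bonds)))
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond indices out of range")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  }
  structure(list(atoms = atoms, bonds = bonds, role = role, label = label),
            class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat(sprintf("<molecular_structure '%s' role=%s: %d atoms, %d bonds>\n",
              x$label, x$role, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Atom coordinates as an N x 3 matrix
#' @param structure A `molecular_structure`.
#' @return Numeric matrix of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace atom coordinates
#' @param structure A `molecular_structure`.
#' @param xyz N x 3 coordinate matrix.
#' @return The updated structure.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3L)
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

is_heavy <- function(structure) toupper(structure$atoms$element) != "H"

#' Mass-weighted center of mass
#'
#' @param structure A `molecular_structure`.
#' @return Length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(structure) {
  m <- structure$atoms$mass
  if (sum(m) <= 0) stop("zero total mass")
  drop(crossprod(coords(structure), m)) / sum(m)
}

#' Protein-ligand complex container
#'
#' Bundles receptor and ligand (and, for flexible targets, a ligand-free
#' "apo" receptor conformation) and records the ligand center of mass of
#' the reference complex, which anchors the protein-ligand distance r.
#'
#' @param receptor receptor `molecular_structure` (holo conformation).
#' @param ligand ligand `molecular_structure`.
#' @param receptor_apo optional open-state receptor with the same residue
#'   numbering and atom naming contract as `receptor`.
#' @return An object of class `complex_system`.
#' @export
complex_system <- function(receptor, ligand, receptor_apo = NULL) {
  stopifnot(inherits(receptor, "molecular_structure"),
            inherits(ligand, "molecular_structure"))
  if (receptor$role != "receptor" || ligand$role != "ligand")
    stop("receptor/ligand roles do not match the arguments")
  if (!is.null(receptor_apo)) {
    stopifnot(inherits(receptor_apo, "molecular_structure"))
    if (nrow(receptor_apo$atoms) != nrow(receptor$atoms))
      stop("apo receptor must have the same atoms as the holo receptor")
  }
  structure(list(receptor = receptor, receptor_apo = receptor_apo,
                 ligand = ligand,
                 reference_ligand_com = center_of_mass(ligand)),
            class = "complex_system")
}

#' @export
print.complex_system <- function(x, ...) {
  cat(sprintf("<complex_system: receptor %d atoms%s, ligand '%s' %d atoms>\n",
              nrow(x$receptor$atoms),
              if (is.null(x$receptor_apo)) "" else " (+apo)",
              x$ligand$label, nrow(x$ligand$atoms)))
  invisible(x)
}

#' Optimal superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation of `mobile` from `reference`.  Reflections are excluded:
#' `det(rotation) = +1`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, not all
#'   collinear.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).  The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("point counts differ between mobile and reference")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for a superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  H <- crossprod(sweep(mobile, 2, cm), sweep(reference, 2, cr))
  sv <- svd(H)
  # collinear or coincident point sets leave the rotation underdetermined
  spread_m <- svd(sweep(mobile, 2, cm), nu = 0, nv = 0)$d
  if (spread_m[2] < 1e-8 * max(spread_m[1], 1))
    stop("degenerate (collinear) configuration: superposition ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - drop(R %*% cm)
  fitted <- mobile %*% t(R) + rep(tr, each = n)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# receptor atom correspondence by (residue number, atom name); ligand by order
match_receptor_atoms <- function(ref, pose) {
  key <- function(s) paste(s$atoms$resno, s$atoms$name, sep = "/")
  kr <- key(ref); kp <- key(pose)
  idx <- match(kr, kp)
  if (anyNA(idx))
    stop("receptor atom correspondence failure: missing ",
         paste(utils::head(kr[is.na(idx)], 3), collapse = ", "))
  idx
}

#' Ligand RMSD after receptor superposition
#'
#' Superposes the pose receptor onto the reference receptor (Kabsch, heavy
#' atoms, matched by residue number and atom name), applies that same
#' transform to the pose ligand, and returns the heavy-atom RMSD between
#' the transformed pose ligand and the reference ligand.  The ligand is
#' deliberately not re-fitted: this is the displacement of the ligand in
#' the receptor frame, the quantity the 2.0-Angstrom optimal-pose
#' criterion is defined on.
#'
#' @param reference,pose `complex_system` objects sharing receptor
#'   labelling and ligand atom order.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd_after_receptor_fit <- function(reference, pose) {
  stopifnot(inherits(reference, "complex_system"),
            inherits(pose, "complex_system"))
  if (nrow(reference$ligand$atoms) != nrow(pose$ligand$atoms))
    stop("ligand atom correspondence failure: atom counts differ")
  idx <- match_receptor_atoms(reference$receptor, pose$receptor)
  hr <- is_heavy(reference$receptor)
  ref_rec <- coords(reference$receptor)[hr, , drop = FALSE]
  pose_rec <- coords(pose$receptor)[idx, , drop = FALSE][hr, , drop = FALSE]
  fit <- kabsch_superpose(pose_rec, ref_rec)
  hl <- is_heavy(reference$ligand)
  ref_lig <- coords(reference$ligand)[hl, , drop = FALSE]
  pose_lig <- coords(pose$ligand)[hl, , drop = FALSE]
  moved <- pose_lig %*% t(fit$rotation) + rep(fit$translation, each = nrow(pose_lig))
  sqrt(mean(rowSums((moved - ref_lig)^2)))
}
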