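test_that("center of mass matches hand arithmetic and handles errors", {
  one <- molecular_structure(data.frame(
    name = "A", element = "C", x = 1, y = 2, z = 3, charge = 0, sigma = 3,
    epsilon = 0.1, born_radius = 1.5, mass = 12), role = "ligand")
  expect_equal(center_of_mass(one), c(1, 2, 3))

  two <- molecular_structure(data.frame(
    name = c("A", "B"), element = "C", x = c(0, 2), y = 0, z = 0, charge = 0,
    sigma = 3, epsilon = 0.1, born_radius = 1.5, mass = 12), role = "ligand")
  expect_equal(center_of_mass(two), c(1, 0, 0))

  # masses 1 and 3 at x = 0 and 4: com = (0*1 + 4*3)/4 = 3
  wt <- molecular_structure(data.frame(
    name = c("A", "B"), element = "C", x = c(0, 4), y = 0, z = 0, charge = 0,
    sigma = 3, epsilon = 0.1, born_radius = 1.5, mass = c(1, 3)),
    role = "ligand")
  expect_equal(center_of_mass(wt)[1], 3)
})

test_that("center of mass is equivariant under rigid transforms", {
  set.seed(42)
  s <- tiny_sys()$ligand
  for (k in 1:5) {
    R <- random_rotation(); tr <- rnorm(3)
    s2 <- set_coords(s, coords(s) %*% t(R) + rep(tr, each = nrow(s$atoms)))
    expect_equal(center_of_mass(s2), drop(R %*% center_of_mass(s)) + tr,
                 tolerance = 1e-10)
  }
})

test_that("molecular_structure validates atoms and bonds", {
  at <- data.frame(name = "A", element = "C", x = 0, y = 0, z = 0,
                   charge = 0, sigma = 3, epsilon = 0.1, born_radius = 1.5,
                   mass = 12)
  expect_error(molecular_structure(at[0, ], role = "ligand"), "at least one")
  expect_error(molecular_structure(at, bonds = data.frame(i = 1, j = 1,
                                                          kb = 1, b0 = 1)),
               "self-bonds")
  expect_error(molecular_structure(at, bonds = data.frame(i = 1, j = 5,
                                                          kb = 1, b0 = 1)),
               "out of range")
  at$mass <- -1
  expect_error(molecular_structure(at, role = "ligand"), "mass")
})

test_that("PDB write/read roundtrip preserves structure to format precision", {
  sys <- tiny_sys()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lig.pdb")
  write_pdb(sys$ligand, p)
  params <- param_table(
    atom_name = c(sys$ligand$atoms$name),
    charge = sys$ligand$atoms$charge, sigma = sys$ligand$atoms$sigma,
    epsilon = sys$ligand$atoms$epsilon,
    born_radius = sys$ligand$atoms$born_radius, mass = sys$ligand$atoms$mass)
  back <- read_pdb(p, params, role = "ligand")
  expect_equal(nrow(back$atoms), nrow(sys$ligand$atoms))
  expect_equal(back$atoms$name, sys$ligand$atoms$name)
  expect_equal(back$atoms$element, sys$ligand$atoms$element)
  expect_equal(coords(back), coords(sys$ligand), tolerance = 1e-3)
  # CONECT records survive (indices shift to file order, here identical)
  expect_equal(back$bonds$i, sys$ligand$bonds$i)
  expect_equal(back$bonds$j, sys$ligand$bonds$j)
  # file has exactly the expected ATOM/HETATM line count
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "HETATM") | startsWith(lines, "ATOM")),
               nrow(sys$ligand$atoms))
  expect_true(any(startsWith(lines, "END")))
})

test_that("single ATOM record parses to its coordinates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "one.pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.500   2.250  -3.125  1.00  0.00           C",
    "END"), p)
  params <- param_table("*C", 0, 3, 0.1, 1.5, 12)
  s <- read_pdb(p, params, role = "receptor")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(coords(s)[1, ]), c(1.5, 2.25, -3.125))
  expect_equal(s$atoms$mass, 12)
})

test_that("hand-written CONECT between atoms 1 and 2 becomes bond (1,2)", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bonded.pdb")
  writeLines(c(
    "HETATM    1  L1  LIG B   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  L2  LIG B   1       1.500   0.000   0.000  1.00  0.00           C",
    "CONECT    1    2",
    "END"), p)
  s <- read_pdb(p, param_table("*C", 0, 3, 0.1, 1.5, 12), role = "ligand")
  expect_equal(s$bonds$i, 1L)
  expect_equal(s$bonds$j, 2L)
  expect_equal(s$bonds$b0, 1.5)
})

test_that("missing parameters raise a parameterization error naming the atom", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.pdb")
  writeLines(c(
    "ATOM      1  XX  GLY A   1       0.000   0.000   0.000  1.00  0.00           X",
    "END"), p)
  expect_error(read_pdb(p, param_table("*C", 0, 3, 0.1, 1.5, 12),
                        role = "receptor"), "XX")
})

test_that("kabsch superposition recovers exact transforms", {
  set.seed(3)
  pts <- matrix(rnorm(15), 5, 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_equal(same$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)

  shifted <- kabsch_superpose(pts, pts + rep(c(5, 0, 0), each = 5))
  expect_equal(shifted$translation, c(5, 0, 0), tolerance = 1e-10)
  expect_equal(shifted$rmsd, 0, tolerance = 1e-10)

  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  rot <- kabsch_superpose(pts, pts %*% t(R90))
  expect_equal(rot$rotation, R90, tolerance = 1e-10)
  expect_equal(rot$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(rot$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rejects mismatched and degenerate inputs", {
  pts <- matrix(rnorm(12), 4, 3)
  expect_error(kabsch_superpose(pts, pts[1:3, ]), "differ")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
})

test_that("kabsch rmsd attains the brute-force minimum over rotations", {
  # dense rotation grid over axis-angle on a 4-point set
  set.seed(11)
  mob <- matrix(rnorm(12), 4, 3)
  R <- random_rotation()
  ref <- mob %*% t(R) + rep(c(1, -2, 0.5), each = 4)
  fit <- kabsch_superpose(mob, ref)
  best <- Inf
  axes <- sphere_pts(40)
  cm <- colMeans(mob); cr <- colMeans(ref)
  for (a in seq_len(nrow(axes))) for (th in seq(0, pi, length.out = 40)) {
    ax <- axes[a, ]
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    Rg <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    moved <- sweep(mob, 2, cm) %*% t(Rg)
    val <- sqrt(mean(rowSums((moved - sweep(ref, 2, cr))^2)))
    if (val < best) best <- val
  }
  expect_lte(fit$rmsd, best + 1e-3)
})

test_that("ligand RMSD after receptor fit isolates ligand displacement", {
  sys <- tiny_sys()
  expect_equal(ligand_rmsd_after_receptor_fit(sys, sys), 0, tolerance = 1e-10)

  # whole-complex rigid motion is absorbed by the receptor fit
  set.seed(8)
  R <- random_rotation(); tr <- c(3, -1, 2)
  moved <- sys
  moved$receptor <- set_coords(moved$receptor,
                               coords(sys$receptor) %*% t(R) +
                                 rep(tr, each = nrow(sys$receptor$atoms)))
  moved$ligand <- set_coords(moved$ligand,
                             coords(sys$ligand) %*% t(R) +
                               rep(tr, each = nrow(sys$ligand$atoms)))
  expect_equal(ligand_rmsd_after_receptor_fit(sys, moved), 0,
               tolerance = 1e-8)

  # pure ligand translation of 3 A with the receptor fixed reads back 3 A
  shifted <- sys
  shifted$ligand <- set_coords(shifted$ligand,
                               coords(sys$ligand) +
                                 rep(c(3, 0, 0), each = nrow(sys$ligand$atoms)))
  expect_equal(ligand_rmsd_after_receptor_fit(sys, shifted), 3,
               tolerance = 1e-10)
})
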