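test_that("jarzynski estimate is exact for zero-variance work", {
  expect_equal(jarzynski_free_energy(rep(2.5, 10), kT = 0.5961), 2.5)
  expect_equal(jarzynski_free_energy(c(0, 0), kT = 0.5961), 0)
  expect_equal(jarzynski_free_energy(rep(-7, 3), kT = 1), -7)
  expect_error(jarzynski_free_energy(numeric(0)), "empty")
})

test_that("jarzynski matches direct high-precision arithmetic", {
  kT <- 0.5961
  w <- c(1, 2)
  direct <- -kT * log((exp(-1 / kT) + exp(-2 / kT)) / 2)
  expect_equal(jarzynski_free_energy(w, kT), direct, tolerance = 1e-12)
  # larger random case against naive evaluation
  set.seed(6)
  w2 <- rnorm(50, sd = 0.5)
  expect_equal(jarzynski_free_energy(w2, kT),
               -kT * log(mean(exp(-w2 / kT))), tolerance = 1e-10)
})

test_that("jarzynski satisfies the Jensen (second-law) bound", {
  set.seed(101)
  kT <- kT_at(300)
  for (i in 1:300) {
    w <- rnorm(sample(2:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0, 3))
    dg <- jarzynski_free_energy(w, kT)
    expect_lte(dg, mean(w) + 1e-10)
  }
})

test_that("log-sum-exp keeps extreme work ratios finite", {
  kT <- kT_at(300)
  w <- c(-700 * kT, 0, 700 * kT)
  dg <- jarzynski_free_energy(w, kT)
  expect_true(is.finite(dg))
  # dominated by the most negative work value
  expect_equal(dg, -700 * kT + kT * log(3), tolerance = 1e-6)
})

test_that("work samples follow the binding-direction convention", {
  U <- cbind(rep(10, 4), rep(12, 4))
  expect_equal(shell_work_samples(U, 1), rep(-2, 4))
  U2 <- cbind(c(1, 3), c(2, 5))
  expect_equal(shell_work_samples(U2, 1), c(-1, -2))
  expect_equal(shell_work_samples(U2, 1, direction = "unbinding"), c(1, 2))
  expect_error(shell_work_samples(U2, 2), "range")
  expect_error(shell_work_samples(cbind(c(1, NA), c(1, 2)), 1), "incomplete")
})

test_that("permuting replicate rows leaves shell scores unchanged", {
  set.seed(12)
  U <- matrix(rnorm(40), 8, 5)
  s1 <- mrc_score(U)
  s2 <- mrc_score(U[sample(8), ])
  expect_equal(s1$shell_scores, s2$shell_scores, tolerance = 1e-12)
  expect_equal(sort(shell_work_samples(U, 2)),
               sort(shell_work_samples(U[sample(8), ], 2)))
})

test_that("zero-variance grids telescope to the end-shell difference", {
  # constant columns: total = U(r=0) - U(r_max) for any schedule
  U <- matrix(rep(c(-10, 0), each = 3), 3, 2)
  s <- mrc_score(U)
  expect_equal(s$total_score, -10)
  cols <- c(-31, -17, -9, -3.5, -1, 0.25)
  U2 <- matrix(rep(cols, each = 4), 4, length(cols))
  for (pm in c("replicate", "ensemble")) {
    s2 <- mrc_score(U2, pairing_mode = pm)
    expect_equal(s2$total_score, cols[1] - cols[length(cols)],
                 tolerance = 1e-9)
    expect_equal(s2$shell_scores, utils::head(cols, -1) - cols[-1],
                 tolerance = 1e-9)
  }
  expect_error(mrc_score(U2[, 1, drop = FALSE]), "2 shells")
})

test_that("total equals the sum of shell scores and direction flips sign", {
  set.seed(33)
  U <- matrix(rnorm(60, sd = 0.5), 10, 6)
  s <- mrc_score(U)
  expect_equal(s$total_score, sum(s$shell_scores))
  # zero-variance limit: unbinding total is the exact negation
  Uc <- matrix(rep(c(-5, -2, 0), each = 4), 4, 3)
  expect_equal(mrc_score(Uc, direction = "unbinding")$total_score,
               -mrc_score(Uc)$total_score)
})

test_that("adding a constant to one shell column shifts adjacent scores", {
  Uc <- matrix(rep(c(-8, -4, -1, 0), each = 5), 5, 4)
  s0 <- mrc_score(Uc)
  c0 <- 2.5
  U2 <- Uc; U2[, 2] <- U2[, 2] + c0
  s1 <- mrc_score(U2)
  expect_equal(s1$shell_scores[1], s0$shell_scores[1] - c0)
  expect_equal(s1$shell_scores[2], s0$shell_scores[2] + c0)
  expect_equal(s1$shell_scores[3], s0$shell_scores[3])
  expect_equal(s1$total_score, s0$total_score)
})

test_that("ensemble pairing equals the log partition-ratio", {
  set.seed(44)
  kT <- kT_at(300)
  U <- matrix(rnorm(30, sd = 0.4), 10, 3)
  s <- mrc_score(U, pairing_mode = "ensemble", kT = kT)
  for (i in 1:2) {
    expect_equal(s$shell_scores[i],
                 -kT * log(sum(exp(-U[, i] / kT)) / sum(exp(-U[, i + 1] / kT))),
                 tolerance = 1e-9)
  }
})

test_that("s_mmgbsa score vanishes for rigid non-interacting species", {
  # pocket_depth 0 and rim epsilon are the only couplings; with frozen
  # geometries the decomposition is additive up to those tiny terms
  sys0 <- set_pocket_depth(tiny_sys(), 0)
  s <- s_mmgbsa_score(sys0, eps_in = 1, minimize = FALSE,
                      engine_args = list(gamma_sasa = 0))
  expect_lt(abs(as.numeric(s)), 0.2)
})

test_that("s_mmgbsa with a single LJ contact at its minimum returns -eps", {
  d <- 2^(1/6) * 3
  rec <- molecular_structure(data.frame(
    name = "R1", element = "C", x = 0, y = 0, z = 0, charge = 0, sigma = 3,
    epsilon = 1, born_radius = 1.5, mass = 12), role = "receptor")
  lig <- molecular_structure(data.frame(
    name = "L1", element = "C", x = d, y = 0, z = 0, charge = 0, sigma = 3,
    epsilon = 1, born_radius = 1.5, mass = 12), role = "ligand")
  sys <- complex_system(rec, lig)
  s <- s_mmgbsa_score(sys, eps_in = 1, minimize = FALSE,
                      engine_args = list(gamma_sasa = 0))
  expect_equal(as.numeric(s), -1, tolerance = 1e-12)
})

test_that("deeper pockets give monotonically more negative comparator scores", {
  series <- make_ligand_series(toy_system_spec(n_receptor_atoms = 24L,
                                               ligand_size = 3L, seed = 7L),
                               depths = c(1, 3, 5), noise_sd = 0)
  sc <- vapply(series, function(e)
    as.numeric(s_mmgbsa_score(e$system, eps_in = 1, minimize = FALSE)),
    numeric(1))
  expect_true(all(diff(sc) < 0))
})

test_that("linear affinity scaling is the stated affine map", {
  expect_equal(linear_affinity(-40, alpha = 0.25, beta = 0.91),
               0.25 * -40 + 0.91)
  expect_equal(linear_affinity(-12.3, alpha = 0, beta = 4), 4)
  expect_equal(linear_affinity(-12.3, alpha = 1, beta = 0), -12.3)
})

test_that("delta_delta_g references the weakest binder and scales by alpha", {
  tab <- data.frame(ligand = c("a", "b"), score = c(-10, -20),
                    dg_exp = c(-3, -6))
  out <- delta_delta_g(tab, alpha = 0.20)
  expect_equal(attr(out, "reference"), "a")
  expect_equal(out$ddg_calc, c(0, -2))
  expect_equal(out$ddg_exp, c(0, -3))
  expect_error(delta_delta_g(tab[1, ]), "2 ligands")
  expect_error(delta_delta_g(data.frame(ligand = c("a", "b"),
                                        score = c(1, 2))),
               "configuration error")
  # ties broken deterministically by label with a warning
  tie <- data.frame(ligand = c("z", "m", "q"), score = c(-1, -2, -3),
                    dg_exp = c(-5, -2, -2))
  expect_warning(out2 <- delta_delta_g(tie), "tie")
  expect_equal(attr(out2, "reference"), "m")
})

test_that("pearson_r matches hand-computed correlations", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)
  expect_error(pearson_r(x, c(1, 2)), "differ")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3 observations")
  expect_error(pearson_r(c(1, 1, 1), x), "zero variance")
})

test_that("a fully decoupled ligand yields exactly zero shell scores", {
  # with every receptor-ligand coupling zeroed, replicate lineages at
  # adjacent shells minimize identically and the work samples cancel
  sys <- make_toy_complex(toy_system_spec(n_receptor_atoms = 16L,
                                          ligand_size = 2L, seed = 4L,
                                          relax = FALSE))
  sys$receptor$atoms$epsilon[] <- 0
  sys$receptor$atoms$charge[] <- 0
  sys$ligand$atoms$charge[] <- 0
  cs <- generate_conformation_set(sys, r_schedule(c(0, 2, 5, 8)),
                                  n_conf = 6L, n_min = 30L, seed = 3,
                                  sampler = list(t_ps = 0.3),
                                  engine_args = list(gamma_sasa = 0),
                                  store_conformations = FALSE)
  s <- mrc_score(cs)
  expect_lt(max(abs(s$shell_scores)), 1e-6)
})
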