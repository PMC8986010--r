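test_that("pairwise MM terms: Coulomb closed form, LJ minimum, symmetry", {
  # two unit charges at 3.320636 A with eps_in = 1 -> exactly 100 kcal/mol
  co <- matrix(c(0, 0, 0, 3.320636, 0, 0), 2, 3, byrow = TRUE)
  p <- forcefield_params(partial_charge = c(1, 1), lj_epsilon = c(0, 0),
                         lj_rmin_half = c(1, 1), gb_radius = c(1.5, 1.5))
  e <- pairwise_mm(co, p, cbind(1L, 2L))
  expect_equal(e$E_elec, 100, tolerance = 1e-9)
  expect_equal(e$E_vdW, 0)

  # LJ pair at r = Rmin_ij gives exactly -eps_ij
  p2 <- forcefield_params(partial_charge = c(0, 0),
                          lj_epsilon = c(0.12, 0.3),
                          lj_rmin_half = c(1.7, 1.5),
                          gb_radius = c(1.5, 1.5))
  rmin <- 1.7 + 1.5
  co2 <- matrix(c(0, 0, 0, rmin, 0, 0), 2, 3, byrow = TRUE)
  e2 <- pairwise_mm(co2, p2, cbind(1L, 2L))
  expect_equal(e2$E_vdW, -sqrt(0.12 * 0.3), tolerance = 1e-12)

  # swapping the two molecules leaves cross energies unchanged
  set.seed(3)
  n <- 6
  co3 <- matrix(runif(3 * n, -4, 4), n, 3)
  p3 <- forcefield_params(runif(n, -0.5, 0.5), runif(n, 0.05, 0.3),
                          runif(n, 1.2, 1.9), runif(n, 1, 2.5))
  ab <- as.matrix(expand.grid(1:3, 4:6))
  ba <- ab[, 2:1]
  expect_equal(pairwise_mm(co3, p3, ab), pairwise_mm(co3, p3, ba))

  expect_error(pairwise_mm(rbind(c(0, 0, 0), c(0, 0, 0)), p2, cbind(1L, 2L)),
               "zero")
})

test_that("GB polar term: Born limit, separability, rigid-motion invariance", {
  # single ion: the Born equation exactly (effective radius = intrinsic)
  p1 <- forcefield_params(1, 0.1, 1.5, 2.0)
  got <- gb_polar(matrix(0, 1, 3), p1)
  born <- -0.5 * (1 - 1 / 78.5) * 332.0636 / 2.0
  expect_equal(got, born, tolerance = 1e-6 * abs(born))

  # two far-separated ions: sum of isolated Born energies
  p2 <- forcefield_params(c(1, -1), c(0.1, 0.1), c(1.5, 1.5), c(2.0, 1.2))
  far <- matrix(c(0, 0, 0, 1e5, 0, 0), 2, 3, byrow = TRUE)
  iso <- gb_polar(matrix(0, 1, 3), forcefield_params(1, 0.1, 1.5, 2.0)) +
    gb_polar(matrix(0, 1, 3), forcefield_params(-1, 0.1, 1.5, 1.2))
  expect_equal(gb_polar(far, p2), iso, tolerance = 1e-4 * abs(iso))

  # rotation/translation invariance
  set.seed(14)
  n <- 5
  co <- matrix(runif(3 * n, -3, 3), n, 3)
  p <- forcefield_params(runif(n, -0.5, 0.5), runif(n, 0.05, 0.3),
                         runif(n, 1.2, 1.9), runif(n, 1.2, 2.2))
  e0 <- gb_polar(co, p)
  for (rep in 1:3) {
    mo <- random_rigid_motion()
    expect_equal(gb_polar(apply_rigid(co, mo), p), e0, tolerance = 1e-9)
  }
})

test_that("OBC effective radii grow under descreening by neighbours", {
  # a buried atom's effective radius must exceed its intrinsic radius
  co <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(-2.8, 0, 0), c(0, 2.8, 0),
              c(0, -2.8, 0), c(0, 0, 2.8), c(0, 0, -2.8))
  n <- nrow(co)
  p <- forcefield_params(rep(0.1, n), rep(0.1, n), rep(1.7, n), rep(1.5, n))
  R <- ppiscreen:::.obc_radii(co, p)
  expect_true(all(R > 1.5))
  expect_gt(R[1], max(R[-1]))  # the central atom is the most descreened
})

test_that("SASA: isolated-sphere closed form, burial, overlap, convergence", {
  s1 <- sasa(matrix(0, 1, 3), radii = 1.5)
  expect_equal(s1$total, 4 * pi * 2.9^2, tolerance = 1e-3 * 4 * pi * 2.9^2)

  # fully buried central atom
  co <- rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
              c(0, 0, 2), c(0, 0, -2))
  s2 <- sasa(co, radii = c(1.5, rep(3, 6)))
  expect_equal(s2$area[1], 0)

  # overlapping pair: total strictly less than sum of isolated areas
  pairco <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  s3 <- sasa(pairco, radii = c(1.5, 1.5))
  expect_lt(s3$total, 2 * s1$total)
  expect_gt(s3$total, 0)

  # quadrature convergence: doubling the points changes totals < 0.5%
  set.seed(6)
  cloud <- matrix(runif(24, -3, 3), 8, 3)
  r <- runif(8, 1.2, 2)
  a1 <- sasa(cloud, r, n_points = 480L)$total
  a2 <- sasa(cloud, r, n_points = 960L)$total
  expect_lt(abs(a2 - a1) / a2, 0.005)
})

test_that("binding energy: non-interacting limit and bookkeeping identities", {
  # 3-atom "protein" + 1-atom ligand pushed 1e4 A away in every frame
  atoms <- data.frame(
    serial = 1:4, name = c("C1", "C2", "C3", "L1"),
    element = c("C", "C", "C", "C"),
    resname = c("ALA", "ALA", "ALA", "LIG"),
    resseq = c(1L, 1L, 1L, 99L), chain = c("A", "A", "A", "X"),
    x = c(0, 1.5, 0.7, 1e4), y = c(0, 0, 1.3, 0), z = c(0, 0, 0, 0),
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  topo <- molecular_structure(atoms)
  p <- forcefield_params(c(0.2, -0.5, 0.3, 0.4), rep(0.12, 4),
                         rep(1.7, 4), rep(1.6, 4))
  tr <- trajectory_ensemble(topo, rep(list(coords(topo)), 2))
  dec <- binding_energy(tr, p)
  s <- setNames(dec$summary$mean, dec$summary$term)
  expect_lt(abs(s["dE_vdW"]), 1e-3)
  expect_lt(abs(s["dE_elec"]), 1e-3)
  expect_lt(abs(s["dG_bind"]), 1e-3)

  # interacting geometry: per-frame identities to 1e-10
  atoms2 <- atoms
  atoms2$x[4] <- 3.2
  topo2 <- molecular_structure(atoms2)
  f1 <- coords(topo2)
  f2 <- f1 + matrix(rnorm(12, 0, 0.05), 4, 3)
  tr2 <- trajectory_ensemble(topo2, list(f1, f2))
  dec2 <- binding_energy(tr2, p)
  pf <- dec2$per_frame
  expect_equal(pf$dG_gas, pf$dE_bond + pf$dE_vdW + pf$dE_elec,
               tolerance = 1e-10)
  expect_equal(pf$dG_solv, pf$dG_GB + pf$dG_SA, tolerance = 1e-10)
  expect_equal(pf$dG_bind, pf$dG_gas + pf$dG_solv, tolerance = 1e-10)
  expect_true(all(pf$dE_bond == 0))

  # missing parameters are reported with the offending atoms
  pbad <- p
  pbad$partial_charge[2] <- NA
  expect_error(binding_energy(tr2, pbad), "atom")
})

test_that("hand-built single-frame decomposition matches term-by-term arithmetic", {
  atoms <- data.frame(
    serial = 1:4, name = c("C1", "C2", "C3", "L1"),
    element = c("C", "C", "C", "N"),
    resname = c("ALA", "ALA", "ALA", "LIG"),
    resseq = c(1L, 1L, 1L, 99L), chain = c("A", "A", "A", "X"),
    x = c(0, 1.5, 0.7, 1.2), y = c(0, 0, 1.3, 3.0), z = c(0, 0, 0, 0.4),
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  topo <- molecular_structure(atoms)
  q <- c(0.2, -0.5, 0.3, 0.4)
  eps <- c(0.10, 0.15, 0.20, 0.17)
  rmh <- c(1.7, 1.8, 1.6, 1.75)
  gbr <- c(1.6, 1.7, 1.5, 1.55)
  p <- forcefield_params(q, eps, rmh, gbr)
  tr <- trajectory_ensemble(topo, list(coords(topo)))
  dec <- binding_energy(tr, p, sasa_points = 960L)
  pf <- dec$per_frame

  # independent hand computation of the gas-phase cross terms
  xyz <- coords(topo)
  e_el <- 0; e_vdw <- 0
  for (i in 1:3) {
    r <- sqrt(sum((xyz[i, ] - xyz[4, ])^2))
    e_el <- e_el + 332.0636 * q[i] * q[4] / r
    eij <- sqrt(eps[i] * eps[4]); rij <- rmh[i] + rmh[4]
    e_vdw <- e_vdw + eij * ((rij / r)^12 - 2 * (rij / r)^6)
  }
  expect_equal(pf$dE_elec, e_el, tolerance = 1e-10)
  expect_equal(pf$dE_vdW, e_vdw, tolerance = 1e-10)

  # solvation deltas recomputed from the exported primitives
  dgb <- gb_polar(xyz, p) -
    gb_polar(xyz[1:3, ], ppiscreen:::.subset_params(p, 1:3)) -
    gb_polar(xyz[4, , drop = FALSE], ppiscreen:::.subset_params(p, 4))
  dsa <- 0.0072 * (sasa(xyz, gbr, 1.4, 960L)$total -
                     sasa(xyz[1:3, ], gbr[1:3], 1.4, 960L)$total -
                     sasa(xyz[4, , drop = FALSE], gbr[4], 1.4, 960L)$total)
  expect_equal(pf$dG_GB, dgb, tolerance = 1e-10)
  expect_equal(pf$dG_SA, dsa, tolerance = 1e-10)
  expect_equal(pf$dG_bind, e_el + e_vdw + dgb + dsa, tolerance = 1e-10)
})

test_that("all energy terms are invariant under global rigid motion", {
  cs <- make_contact_system()
  e <- cs$entries$salt_bridge; e$p <- 1; e$mode <- "deterministic"
  tr <- make_trajectory(cs$topology, contact_schedule(list(e), 1,
                                                      jitter_sigma = 0))
  p <- assign_toy_forcefield(cs$topology)
  d0 <- binding_energy(tr, p, sasa_points = 240L)
  set.seed(55)
  mo <- random_rigid_motion()
  tr2 <- trajectory_ensemble(cs$topology, list(apply_rigid(tr$frames[[1]], mo)))
  d1 <- binding_energy(tr2, p, sasa_points = 240L)
  for (t in c("dE_vdW", "dE_elec", "dG_GB")) {
    expect_equal(d1$per_frame[[t]], d0$per_frame[[t]], tolerance = 1e-6)
  }
  # SASA uses a fixed quadrature grid, so rotation changes it only within
  # the quadrature tolerance
  expect_equal(d1$per_frame$dG_SA, d0$per_frame$dG_SA, tolerance = 0.05)
})
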