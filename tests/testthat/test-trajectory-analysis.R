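test_that("Kabsch superposition: identity, rigid motion, degenerate input", {
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3)
  fit0 <- kabsch_superpose(X, X)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  mo <- random_rigid_motion()
  Y <- apply_rigid(X, mo)
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("Kabsch RMSD matches the rotation-grid-search oracle", {
  set.seed(23)
  for (case in 1:5) {
    A <- matrix(rnorm(15, sd = 2), 5, 3)
    B <- matrix(rnorm(15, sd = 2), 5, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, grid_search_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("weighted superposition honours the weights", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  Y <- X
  Y[6, ] <- Y[6, ] + 5  # one outlier point
  w <- c(rep(1, 5), 0)
  fit <- kabsch_superpose(X, Y, weights = w)
  expect_lt(fit$rmsd, 1e-9)  # outlier ignored at zero weight
})

test_that("RMSD series: static, rigid-motion, and planted-displacement cases", {
  cs <- make_contact_system()
  base <- coords(cs$topology)
  n <- nrow(base)
  prot <- which(!cs$topology$atoms$is_ligand)
  lig <- which(cs$topology$atoms$is_ligand)

  static <- trajectory_ensemble(cs$topology, rep(list(base), 5))
  r <- rmsd_series(static, prot)
  expect_equal(r$rmsd, rep(0, 5), tolerance = 1e-12)
  expect_equal(attr(r, "mean"), 0)
  expect_equal(attr(r, "sd"), 0)

  # frames are rigid motions of the reference: fitting removes everything
  set.seed(8)
  rigid <- trajectory_ensemble(cs$topology, lapply(1:6, function(k)
    apply_rigid(base, random_rigid_motion())))
  rr <- rmsd_series(rigid, prot, prot)
  expect_lt(max(rr$rmsd), 1e-9)

  # ligand displaced by exactly d after protein fit
  d <- 1.75
  shift <- c(d, 0, 0)
  frames <- lapply(1:4, function(k) {
    f <- base
    if (k > 1) f[lig, ] <- sweep(f[lig, , drop = FALSE], 2, shift, `+`)
    f
  })
  tl <- trajectory_ensemble(cs$topology, frames)
  rl <- rmsd_series(tl, fit_selection = prot, measure_selection = lig)
  expect_equal(rl$rmsd[1], 0, tolerance = 1e-12)
  expect_equal(rl$rmsd[2:4], rep(d, 3), tolerance = 1e-9)

  expect_error(rmsd_series(tl, prot, lig, reference = 9L), "invalid")
})

test_that("RMSF: static zero, planted oscillation, rigid-motion invariance", {
  cs <- make_contact_system()
  base <- coords(cs$topology)
  sel <- seq_len(nrow(base))

  static <- trajectory_ensemble(cs$topology, rep(list(base), 4))
  expect_equal(rmsf(static, sel)$rmsf, rep(0, length(sel)), tolerance = 1e-12)
  expect_error(rmsf(trajectory_ensemble(cs$topology, list(base)), sel),
               "2 frames")

  # one atom oscillating +/- delta along x in an otherwise rigid system
  delta <- 0.5
  osc <- 1L
  frames <- lapply(1:8, function(k) {
    f <- base
    f[osc, 1] <- f[osc, 1] + delta * (-1)^k
    f
  })
  tro <- trajectory_ensemble(cs$topology, frames)
  out <- rmsf(tro, sel)
  expect_equal(out$rmsf[osc], delta, tolerance = 0.03)
  expect_lt(max(out$rmsf[-osc]), 0.05)

  # global rigid motion of every frame leaves RMSF unchanged
  set.seed(31)
  frames2 <- lapply(frames, function(f) apply_rigid(f, random_rigid_motion()))
  out2 <- rmsf(trajectory_ensemble(cs$topology, frames2), sel)
  expect_equal(out2$rmsf, out$rmsf, tolerance = 1e-6)
})

test_that("hydrogen-bond detection follows the distance and angle criteria", {
  # minimal system: donor N at origin, its H 1 A along -y, ligand O placed
  dha_topology <- function(A) {
    molecular_structure(data.frame(
      serial = 1:3, name = c("ND", "HD", "OA"),
      element = c("N", "H", "O"), resname = c("ARG", "ARG", "LIG"),
      resseq = c(1L, 1L, 99L), chain = c("A", "A", "X"),
      x = c(0, 0, A[1]), y = c(0, -1, A[2]), z = c(0, 0, A[3]),
      is_ligand = c(FALSE, FALSE, TRUE)))
  }
  place <- function(A) {
    topo <- dha_topology(A)
    detect_hbonds(coords(topo), topo, donors = 1L, acceptors = 3L)
  }
  # D-A = 3.4 A, angle 180 deg -> detected
  ev <- place(c(0, -3.4, 0))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$contact_class, "hbond")
  expect_equal(ev$role, "donor")
  expect_equal(ev$distance, 3.4, tolerance = 1e-12)
  # D-A = 3.6 A, angle ~180 -> distance fails
  expect_equal(nrow(place(c(0, -3.6, 0))), 0L)
  # D-A = 3.0 A but angle 90 deg at H -> angle fails
  expect_equal(nrow(place(c(3.0, -1.0, 0) / sqrt(sum(c(3, -1, 0)^2)) * 3.0)), 0L)
  # acceptor side: ligand as donor records role = "acceptor" for protein
  topo2 <- molecular_structure(data.frame(
    serial = 1:3, name = c("OA", "ND", "HD"),
    element = c("O", "N", "H"), resname = c("GLU", "LIG", "LIG"),
    resseq = c(1L, 99L, 99L), chain = c("A", "X", "X"),
    x = c(0, 0, 0), y = c(0, -3.0, -2.0), z = 0,
    is_ligand = c(FALSE, TRUE, TRUE)))
  ev2 <- detect_hbonds(coords(topo2), topo2, donors = 2L, acceptors = 1L)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$role, "acceptor")
})

test_that("detectors equal a brute-force restatement on random geometries", {
  set.seed(12)
  # --- hydrogen bonds: 1,000 random acceptor placements
  base_topo <- molecular_structure(data.frame(
    serial = 1:3, name = c("ND", "HD", "OA"),
    element = c("N", "H", "O"), resname = c("ARG", "ARG", "LIG"),
    resseq = c(1L, 1L, 99L), chain = c("A", "A", "X"),
    x = c(0, 0, 0), y = c(0, -1, -9), z = c(0, 0, 0),
    is_ligand = c(FALSE, FALSE, TRUE)))
  base <- coords(base_topo)
  agree <- 0L
  for (k in 1:1000) {
    A <- runif(3, -4.5, 4.5)
    f <- base
    f[3L, ] <- A
    got <- nrow(detect_hbonds(f, base_topo, donors = 1L, acceptors = 3L)) > 0
    want <- hbond_oracle(f[1L, ], f[2L, ], A)
    expect_equal(got, want, info = sprintf("hbond case %d", k))
    agree <- agree + got
  }
  expect_gt(agree, 0L)  # the sweep hits both sides of the criteria

  # --- salt bridge: charged ligand atom around a glutamate
  topo_sb <- make_probe_topology("GLU", rbind(c(0, -9, 0)), "N", lig_charge = 1L)
  lidx <- which(topo_sb$atoms$name == "L1")
  grp <- which(topo_sb$atoms$name %in% c("OE1", "OE2"))
  base_sb <- coords(topo_sb)
  for (k in 1:340) {
    A <- runif(3, -6, 6)
    f <- base_sb
    f[lidx, ] <- A
    got <- nrow(detect_salt_bridges(f, topo_sb)) > 0
    want <- min(sqrt(rowSums(sweep(f[grp, , drop = FALSE], 2, A)^2))) < 4.0
    expect_equal(got, want, info = sprintf("salt case %d", k))
  }

  # --- hydrophobic: single ligand carbon cluster around a leucine
  topo_hp <- make_probe_topology("LEU", rbind(c(0, -9, 0)), "C")
  lidx <- which(topo_hp$atoms$name == "L1")
  sc <- which(topo_hp$atoms$element == "C" &
                !(topo_hp$atoms$name %in% ppiscreen:::.backbone_atoms) &
                !topo_hp$atoms$is_ligand)
  base_hp <- coords(topo_hp)
  for (k in 1:330) {
    A <- runif(3, -6.5, 6.5)
    f <- base_hp
    f[lidx, ] <- A
    got <- nrow(detect_hydrophobic(f, topo_hp)) > 0
    want <- min(sqrt(rowSums(sweep(f[sc, , drop = FALSE], 2, A)^2))) < 4.5
    expect_equal(got, want, info = sprintf("hydrophobic case %d", k))
  }

  # --- aromatic: ligand ring centroid around a phenylalanine ring
  th <- (0:5) * pi / 3
  ring_local <- cbind(1.395 * cos(th), 1.395 * sin(th), 0)
  topo_ar <- make_probe_topology("PHE", ring_local + matrix(c(0, -9, 0), 6, 3,
                                                            byrow = TRUE),
                                 rep("C", 6))
  lring <- which(topo_ar$atoms$is_ligand)
  attr(topo_ar, "ligand_rings") <- list(lring)
  pring <- which(topo_ar$atoms$name %in% c("CG", "CD1", "CE1", "CZ",
                                           "CE2", "CD2"))
  base_ar <- coords(topo_ar)
  pcen <- colMeans(base_ar[pring, ])
  for (k in 1:330) {
    cen <- runif(3, -7, 7)
    f <- base_ar
    f[lring, ] <- ring_local + matrix(cen, 6, 3, byrow = TRUE)
    got <- nrow(detect_aromatic(f, topo_ar)) > 0
    want <- sqrt(sum((pcen - cen)^2)) <= 5.5
    expect_equal(got, want, info = sprintf("aromatic case %d", k))
  }
})

test_that("detectors are invariant under global rigid motion", {
  cs <- make_contact_system()
  e <- cs$entries$hbond; e$p <- 1; e$mode <- "deterministic"
  tr <- make_trajectory(cs$topology, contact_schedule(list(e), 1,
                                                      jitter_sigma = 0))
  f <- tr$frames[[1]]
  ev0 <- detect_contacts(tr)
  set.seed(77)
  for (rep in 1:3) {
    f2 <- apply_rigid(f, random_rigid_motion())
    tr2 <- trajectory_ensemble(cs$topology, list(f2))
    attr(tr2$topology, "ligand_rings") <- attr(cs$topology, "ligand_rings")
    ev2 <- detect_contacts(tr2)
    expect_equal(nrow(ev2), nrow(ev0))
    expect_equal(sort(ev2$pair_id), sort(ev0$pair_id))
    expect_equal(sort(ev2$distance), sort(ev0$distance), tolerance = 1e-9)
  }
})

test_that("occupancy arithmetic and residue aggregation follow the formula", {
  # N = 10 frames, one pair contacting in 4 frames -> 40.00%
  ev <- data.frame(frame = 1:4, contact_class = "hbond", chain = "A",
                   resseq = 10L, resname = "ARG", residue = "Arg10",
                   role = "donor", protein_atoms = "1", ligand_atoms = "2",
                   pair_id = "Arg10-Side|LIG[O1]", distance = 3.0,
                   angle = 150)
  occ <- occupancy(ev, 10, "pair")
  expect_equal(occ$occupancy_percent, 40)
  expect_equal(occ$n_frames, 10L)
  expect_error(occupancy(ev, 0), "N > 0")

  # residue-level equals the sum of pair rows (printed-table convention)
  pair_tab <- data.frame(residue = c("Glu278", "Glu278", "Arg179", "Arg179"),
                         occupancy_percent = c(392.92, 99.22, 171.67, 54.84))
  res <- residue_occupancy_from_pairs(pair_tab)
  expect_equal(res$occupancy_percent[res$residue == "Glu278"], 492.14)
  expect_equal(res$occupancy_percent[res$residue == "Arg179"], 226.51)
})

test_that("strong-hydrogen-bond flag uses a strict 75% threshold", {
  tab <- data.frame(residue = c("Phe229", "Glu278", "Gln75"),
                    occupancy_percent = c(92.34, 75.00, 12.5))
  out <- strong_hbond_flag(tab)
  expect_equal(out$strong, c(TRUE, FALSE, FALSE))
  none <- strong_hbond_flag(data.frame(residue = "X",
                                       occupancy_percent = 40))
  expect_false(any(none$strong))
  empty <- strong_hbond_flag(data.frame(residue = character(),
                                        occupancy_percent = numeric()))
  expect_equal(nrow(empty), 0L)
})
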