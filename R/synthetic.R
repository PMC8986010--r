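# Synthetic-data generators: everything needed to exercise the pipeline
# without external structures, compound libraries, or MD engines.
# Toy residues use real amino-acid side-chain atom names (minimal backbone
# N/CA/C/O) so feature derivation and the contact detectors run unmodified.
# Geometry is idealized, not force-field-relaxed; schedules reserve wide
# margins (several Angstrom) inside/outside every detector cutoff so the
# default 0.1 Angstrom jitter cannot flip a scheduled contact state.

.unit <- function(v) v / sqrt(sum(v^2))

# one toy residue built in global coordinates: the side-chain functional
# group sits at `anchor` and the backbone extends along dir * +y.
.toy_residue <- function(resname, resseq, chain, anchor, dir = 1) {
  a <- function(name, element, off) {
    data.frame(name = name, element = element,
               x = anchor[1] + off[1], y = anchor[2] + dir * off[2],
               z = anchor[3] + off[3], stringsAsFactors = FALSE)
  }
  ring6 <- function(prefix_names) {
    th <- (0:5) * pi / 3
    do.call(rbind, lapply(seq_len(6), function(k)
      a(prefix_names[k], "C", c(1.395 * sin(th[k]), 0, 1.395 * cos(th[k])))))
  }
  side <- switch(resname,
    PHE = rbind(ring6(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
                a("CB", "C", c(0, 1.55, 1.395)),
                a("CA", "C", c(0, 2.90, 1.00))),
    TYR = rbind(ring6(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
                a("OH", "O", c(0, 0, -2.755)),
                a("CB", "C", c(0, 1.55, 1.395)),
                a("CA", "C", c(0, 2.90, 1.00))),
    GLU = rbind(a("OE1", "O", c(1.10, 0, 0)), a("OE2", "O", c(-1.10, 0, 0)),
                a("CD", "C", c(0, 0.60, 0)), a("CG", "C", c(0, 1.90, 0.40)),
                a("CB", "C", c(0, 3.20, 0)), a("CA", "C", c(0, 4.50, 0.40))),
    ARG = rbind(a("NH1", "N", c(1.15, 0, 0.40)), a("NH2", "N", c(-1.15, 0, 0.40)),
                a("CZ", "C", c(0, 0, 0)), a("NE", "N", c(0, 1.20, -0.30)),
                a("CD", "C", c(0, 2.50, 0)), a("CG", "C", c(0, 3.80, 0.40)),
                a("CB", "C", c(0, 5.10, 0)), a("CA", "C", c(0, 6.40, 0.40))),
    LYS = rbind(a("NZ", "N", c(0, 0, 0)), a("CE", "C", c(0, 1.30, 0.30)),
                a("CD", "C", c(0, 2.60, 0)), a("CG", "C", c(0, 3.90, 0.30)),
                a("CB", "C", c(0, 5.20, 0)), a("CA", "C", c(0, 6.50, 0.30))),
    LEU = rbind(a("CG", "C", c(0, 0.50, 0)), a("CD1", "C", c(1.25, -0.40, 0)),
                a("CD2", "C", c(-1.25, -0.40, 0)),
                a("CB", "C", c(0, 1.80, 0.30)), a("CA", "C", c(0, 3.10, 0))),
    stop("no toy template for residue ", resname)
  )
  ca <- side[side$name == "CA", c("x", "y", "z")]
  bb <- rbind(
    data.frame(name = "N", element = "N", x = ca$x - 1.20,
               y = ca$y + dir * 0.70, z = ca$z + 0.20),
    data.frame(name = "C", element = "C", x = ca$x + 1.25,
               y = ca$y + dir * 0.60, z = ca$z),
    data.frame(name = "O", element = "O", x = ca$x + 1.55,
               y = ca$y + dir * 1.70, z = ca$z + 0.35)
  )
  out <- rbind(side, bb)
  out$resname <- resname
  out$resseq <- resseq
  out$chain <- chain
  out
}

.assemble_structure <- function(res_list, ligand_chains = character(0)) {
  atoms <- do.call(rbind, res_list)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$is_ligand <- atoms$chain %in% ligand_chains
  molecular_structure(atoms)
}

#' Generate a toy two-chain interface with hot-spot residues
#'
#' Chain R mimics the receptor side (Glu277, Glu278, Phe229, Tyr230,
#' Phe279) and chain L the cytokine side (Arg179, Arg182, Phe74, Phe78,
#' Leu178), positioned so every interaction-class partner pair (aromatic
#' ring, hydrophobic, salt bridge) lies well inside its contact-detector
#' cutoff. Residue base positions are jittered by the seed within validity
#' margins.
#'
#' @param seed RNG seed (default 20220406).
#' @return list with `structure` (a `MolecularStructure`), and hotspot
#'   tables `hotspots_receptor` / `hotspots_ligand` (chain, resseq, ftype)
#'   giving the two interface pharmacophore recipes.
#' @export
make_toy_interface <- function(seed = 20220406) {
  set.seed(seed)
  j <- function() runif(3, -0.15, 0.15)
  res <- list(
    # receptor-like chain R, functional groups on the y = 0 plane
    .toy_residue("PHE", 229, "R", c(0, 0, 0) + j(), dir = 1),
    .toy_residue("TYR", 230, "R", c(8, 0, 0) + j(), dir = 1),
    .toy_residue("GLU", 277, "R", c(24, 0, 0) + j(), dir = 1),
    .toy_residue("GLU", 278, "R", c(32, 0, 0) + j(), dir = 1),
    .toy_residue("PHE", 279, "R", c(16, 0, 0) + j(), dir = 1),
    # cytokine-like chain L facing it from below
    .toy_residue("PHE", 78, "L", c(0, -4.5, 0) + j(), dir = -1),
    .toy_residue("PHE", 74, "L", c(8, -4.5, 0) + j(), dir = -1),
    .toy_residue("LEU", 178, "L", c(16, -3.4, 0) + j(), dir = -1),
    .toy_residue("ARG", 179, "L", c(24, -3.3, 0) + j(), dir = -1),
    .toy_residue("ARG", 182, "L", c(32, -3.3, 0) + j(), dir = -1)
  )
  structure_ <- .assemble_structure(res)
  hotspots_receptor <- data.frame(
    chain = "R", resseq = c(277L, 278L, 229L, 230L, 279L),
    ftype = c("Ani", "Ani", "Aro", "Aro", "Hyd"), stringsAsFactors = FALSE)
  hotspots_ligand <- data.frame(
    chain = "L", resseq = c(74L, 78L, 179L, 182L, 178L),
    ftype = c("Aro", "Aro", "Cat", "Cat", "Hyd"), stringsAsFactors = FALSE)
  list(structure = structure_, hotspots_receptor = hotspots_receptor,
       hotspots_ligand = hotspots_ligand, seed = seed)
}

# ---- matching / decoy ligand construction --------------------------------

.rand_frame <- function() {
  # random orthonormal pair (u, v) spanning a random plane
  u <- .unit(rnorm(3))
  w <- rnorm(3)
  v <- .unit(w - sum(w * u) * u)
  list(u = u, v = v, n = .unit(pracma_cross(u, v)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Each builder returns list(elements, charge, coords, bonds, link: index of
# the preferred linker atom within the fragment)
.frag_aro <- function(center) {
  fr <- .rand_frame()
  th <- (0:5) * pi / 3
  pos <- t(vapply(th, function(t)
    center + 1.395 * (cos(t) * fr$u + sin(t) * fr$v), numeric(3)))
  list(elements = rep("C", 6), charge = integer(6), coords = pos,
       bonds = data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
       link = 1L)
}

.frag_cat <- function(center) {
  # diprotonated piperazine; one ring nitrogen sits exactly at the center
  fr <- .rand_frame()
  th <- (0:5) * pi / 3
  cen <- center - 1.46 * (cos(th[1]) * fr$u + sin(th[1]) * fr$v)
  pos <- t(vapply(th, function(t)
    cen + 1.46 * (cos(t) * fr$u + sin(t) * fr$v), numeric(3)))
  # atom 1 (N) is at `center` by construction
  el <- c("N", "C", "C", "N", "C", "C")
  list(elements = el, charge = c(1L, 0L, 0L, 1L, 0L, 0L), coords = pos,
       bonds = data.frame(i = 1:6, j = c(2:6, 1), order = rep(1L, 6)),
       link = 2L)
}

.frag_ani <- function(center) {
  fr <- .rand_frame()
  pos <- rbind(center + 1.1 * fr$u,       # O1
               center - 1.1 * fr$u,       # O2
               center + 1.2 * fr$v)       # C
  list(elements = c("O", "O", "C"), charge = c(0L, -1L, 0L), coords = pos,
       bonds = data.frame(i = c(3, 3), j = c(1, 2), order = c(2L, 1L)),
       link = 3L)
}

.frag_hyd <- function(center) {
  fr <- .rand_frame()
  th <- c(0, 2, 4) * pi / 3
  pos <- t(vapply(th, function(t)
    center + 0.866 * (cos(t) * fr$u + sin(t) * fr$v), numeric(3)))
  list(elements = rep("C", 3), charge = integer(3), coords = pos,
       bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1L, 1L)),
       link = 1L)
}

.frag_don <- function(center) {
  fr <- .rand_frame()
  pos <- rbind(center, center + 0.96 * fr$u)
  list(elements = c("O", "H"), charge = c(0L, 0L), coords = pos,
       bonds = data.frame(i = 1, j = 2, order = 1L), link = 1L)
}

.frag_acc <- function(center) {
  # ether-like oxygen anchor with a methyl carbon so the O is not free-floating
  fr <- .rand_frame()
  pos <- rbind(center, center + 1.43 * fr$u)
  list(elements = c("O", "C"), charge = c(0L, 0L), coords = pos,
       bonds = data.frame(i = 1, j = 2, order = 1L), link = 2L)
}

#' Build a ligand that matches (or decoys) a pharmacophore model
#'
#' Places an idealized chemical fragment at each requested model feature
#' center - benzene for Aro, diprotonated piperazine for Cat (a nitrogen at
#' the center), carboxylate for Ani (oxygen midpoint at the center), a
#' propyl-like carbon triangle for Hyd, hydroxyl/ether groups for Don/Acc -
#' and links consecutive fragments with single bonds so the scaffold is
#' connected. Perceived features of the result include the requested types
#' exactly at the subset's centers. The decoy variant omits one label's
#' fragment (typically the essential feature).
#'
#' @param model a `PharmacophoreModel`.
#' @param subset character vector of model labels to realize; must pass the
#'   model's constraints.
#' @param seed RNG seed.
#' @param drop_label optional label whose fragment is omitted (decoy).
#' @param name molecule name.
#' @return a [small_molecule()] with one conformer.
#' @export
make_matching_ligand <- function(model, subset, seed = 20220406,
                                 drop_label = NULL, name = "synthetic-ligand") {
  if (!constraints_satisfied(model$constraints, subset))
    stop("requested subset does not satisfy the model constraints")
  set.seed(seed)
  centers <- model_centers(model)
  use <- setdiff(subset, drop_label)
  frags <- list()
  for (lab in use) {
    ft <- model$features$ftype[model$features$label == lab]
    ctr <- centers[lab, ]
    frags[[lab]] <- switch(ft,
      Aro = .frag_aro(ctr), Cat = .frag_cat(ctr), Ani = .frag_ani(ctr),
      Hyd = .frag_hyd(ctr), Don = .frag_don(ctr), Acc = .frag_acc(ctr))
  }
  elements <- character(0); charge <- integer(0)
  coords_ <- NULL; bonds <- NULL; offs <- integer(length(frags))
  for (k in seq_along(frags)) {
    f <- frags[[k]]
    offs[k] <- length(elements)
    b <- f$bonds
    b$i <- b$i + offs[k]; b$j <- b$j + offs[k]
    bonds <- rbind(bonds, b)
    elements <- c(elements, f$elements)
    charge <- c(charge, f$charge)
    coords_ <- rbind(coords_, f$coords)
  }
  # link consecutive fragments at their preferred linker atoms
  if (length(frags) > 1L) {
    for (k in seq_len(length(frags) - 1L)) {
      bonds <- rbind(bonds, data.frame(i = offs[k] + frags[[k]]$link,
                                       j = offs[k + 1L] + frags[[k + 1L]]$link,
                                       order = 1L))
    }
  }
  small_molecule(elements, bonds, coords_, charge, name = name)
}

# ---- trajectories with planted contact schedules -------------------------

#' Contact schedule for a synthetic trajectory
#'
#' @param entries list of schedule entries, each a list with
#'   `contact_class` (hbond / salt_bridge / hydrophobic / aromatic),
#'   `protein_atoms` (for hbond: c(donor, hydrogen) indices; otherwise the
#'   protein group/ring atom indices), `ligand_atoms` (the ligand group to
#'   pose), `p` (contact fraction/probability), `mode` ("deterministic" or
#'   "bernoulli"), and `m` (bonds per contacting frame; hbond only).
#' @param n_frames number of frames N.
#' @param jitter_sigma Gaussian positional jitter (Angstrom, default 0.1),
#'   applied everywhere except scheduled-contact atoms.
#' @param seed RNG seed recorded in the trajectory metadata.
#' @return object of class `ContactSchedule`.
#' @export
contact_schedule <- function(entries, n_frames, jitter_sigma = 0.1,
                             seed = 20220406) {
  for (e in entries) {
    stopifnot(!is.null(e$contact_class), !is.null(e$protein_atoms),
              !is.null(e$ligand_atoms), !is.null(e$p))
    if (e$p < 0 || e$p > 1) stop("schedule p must be in [0, 1]")
    if (!is.null(e[["m"]]) && e[["m"]] < 1) stop("schedule multiplicity m must be >= 1")
  }
  lig_all <- unlist(lapply(entries, `[[`, "ligand_atoms"))
  if (anyDuplicated(lig_all))
    stop("infeasible schedule: entries share ligand atoms")
  structure(list(entries = entries, n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma, seed = seed),
            class = "ContactSchedule")
}

# contact-present pose for one entry; returns new coordinates for the
# entry's ligand atoms
.pose_entry <- function(base, entry, present) {
  pa <- entry$protein_atoms
  la <- entry$ligand_atoms
  cls <- entry$contact_class
  m <- entry[["m"]] %||% 1L
  if (cls == "hbond") {
    D <- base[pa[1], ]; H <- base[pa[2], ]
    u <- .unit(H - D)
    v <- .unit(pracma_cross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    pos <- matrix(NA_real_, length(la), 3)
    if (present) {
      for (k in seq_along(la)) {
        pos[k, ] <- if (k <= m) D + 2.9 * u + (k - 1) * 1.5 * v
                    else D + (2.9 + 2.2 * (k - m)) * u + 1.5 * (m - 1) * v
      }
    } else {
      for (k in seq_along(la)) pos[k, ] <- D + (9 + 2.2 * (k - 1)) * u
    }
    return(pos)
  }
  anchor <- colMeans(base[pa, , drop = FALSE])
  away <- .unit(c(0, -1, 0))
  gap <- switch(cls, salt_bridge = 3.0, hydrophobic = 3.4, aromatic = 4.5)
  far <- switch(cls, salt_bridge = 9, hydrophobic = 9, aromatic = 10)
  dist <- if (present) gap else far
  target <- anchor + dist * away
  cur <- base[la, , drop = FALSE]
  shift <- target - colMeans(cur)
  sweep(cur, 2, shift, `+`)
}

#' Generate a trajectory realizing a contact schedule
#'
#' Per frame, each scheduled contact that is "present" is posed inside its
#' geometric criteria (with the requested multiplicity, e.g. a bidentate
#' hydrogen bond for m = 2) and otherwise well outside them; Gaussian
#' jitter is added to every atom not involved in a scheduled contact.
#' Deterministic mode makes the contact present in exactly
#' `round(p * n_frames)` frames (the leading ones); Bernoulli mode draws
#' each frame independently.
#'
#' @param topology `MolecularStructure` of protein + flagged ligand.
#' @param schedule a [contact_schedule()].
#' @return a `TrajectoryEnsemble`; `attr(, "schedule")` records the
#'   schedule and per-entry expected occupancies.
#' @export
make_trajectory <- function(topology, schedule) {
  stopifnot(inherits(schedule, "ContactSchedule"))
  set.seed(schedule$seed)
  N <- schedule$n_frames
  base <- coords(topology)
  fixed <- unique(unlist(lapply(schedule$entries, function(e)
    c(e$protein_atoms, e$ligand_atoms))))
  presence <- lapply(schedule$entries, function(e) {
    mode <- e$mode %||% "deterministic"
    if (mode == "deterministic") seq_len(N) <= round(e$p * N)
    else runif(N) < e$p
  })
  frames <- vector("list", N)
  for (f in seq_len(N)) {
    fr <- base + matrix(rnorm(length(base), 0, schedule$jitter_sigma),
                        nrow(base), 3)
    fr[fixed, ] <- base[fixed, ]
    for (k in seq_along(schedule$entries)) {
      e <- schedule$entries[[k]]
      fr[e$ligand_atoms, ] <- .pose_entry(base, e, presence[[k]][f])
    }
    frames[[f]] <- fr
  }
  traj <- trajectory_ensemble(topology, frames)
  expected <- vapply(seq_along(schedule$entries), function(k) {
    e <- schedule$entries[[k]]
    100 * sum(presence[[k]]) / N * (e[["m"]] %||% 1L)
  }, numeric(1))
  attr(traj, "schedule") <- list(schedule = schedule,
                                 expected_occupancy = expected,
                                 seed = schedule$seed)
  traj
}

#' Toy protein-ligand system for contact-schedule trajectories
#'
#' Builds a four-residue protein chain (ARG with an explicit guanidinium
#' hydrogen, GLU, LEU, PHE) and a ligand with one functional group per
#' contact class (two acceptor oxygens, a protonated amine nitrogen, a
#' carbon triangle, a six-carbon ring), plus ready-made schedule entries
#' for each class.
#'
#' @param seed RNG seed.
#' @return list with `topology` and `entries` (named: hbond, salt_bridge,
#'   hydrophobic, aromatic), each entry missing only `p`/`mode`/`m`.
#' @export
make_contact_system <- function(seed = 20220406) {
  set.seed(seed)
  res <- list(
    .toy_residue("ARG", 10, "A", c(0, 0, 0), dir = 1),
    .toy_residue("GLU", 20, "A", c(10, 0, 0), dir = 1),
    .toy_residue("LEU", 30, "A", c(20, 0, 0), dir = 1),
    .toy_residue("PHE", 40, "A", c(30, 0, 0), dir = 1)
  )
  prot <- do.call(rbind, res)
  # explicit hydrogen on ARG NH1, pointing down toward the ligand region
  nh1 <- which(prot$name == "NH1" & prot$resseq == 10)
  prot <- rbind(prot, data.frame(
    name = "HH11", element = "H", x = prot$x[nh1], y = prot$y[nh1] - 1.0,
    z = prot$z[nh1], resname = "ARG", resseq = 10, chain = "A"))
  th <- (0:5) * pi / 3
  lig <- rbind(
    data.frame(name = "O1", element = "O", x = 0, y = -8, z = 0),
    data.frame(name = "O2", element = "O", x = 0, y = -8, z = 2.2),
    data.frame(name = "N1", element = "N", x = 10, y = -8, z = 0),
    data.frame(name = "C1", element = "C", x = 20 + 0.87, y = -8, z = 0),
    data.frame(name = "C2", element = "C", x = 20 - 0.43, y = -8, z = 0.75),
    data.frame(name = "C3", element = "C", x = 20 - 0.43, y = -8, z = -0.75),
    do.call(rbind, lapply(1:6, function(k)
      data.frame(name = paste0("R", k), element = "C",
                 x = 30 + 1.395 * cos(th[k]), y = -8,
                 z = 1.395 * sin(th[k]))))
  )
  lig$resname <- "LIG"; lig$resseq <- 99; lig$chain <- "X"
  topo <- .assemble_structure(list(prot, lig), ligand_chains = "X")
  atoms <- topo$atoms
  idx <- function(nm) which(atoms$name %in% nm & atoms$is_ligand)
  pidx <- function(nm, rs) which(atoms$name %in% nm & atoms$resseq == rs &
                                   !atoms$is_ligand)
  attr(topo, "ligand_rings") <- list(vapply(paste0("R", 1:6), idx, 1L))
  entries <- list(
    hbond = list(contact_class = "hbond",
                 protein_atoms = c(pidx("NH1", 10), pidx("HH11", 10)),
                 ligand_atoms = c(idx("O1"), idx("O2"))),
    salt_bridge = list(contact_class = "salt_bridge",
                       protein_atoms = c(pidx("OE1", 20), pidx("OE2", 20)),
                       ligand_atoms = idx("N1")),
    hydrophobic = list(contact_class = "hydrophobic",
                       protein_atoms = c(pidx("CG", 30), pidx("CD1", 30),
                                         pidx("CD2", 30)),
                       ligand_atoms = c(idx("C1"), idx("C2"), idx("C3"))),
    aromatic = list(contact_class = "aromatic",
                    protein_atoms = pidx(c("CG", "CD1", "CE1", "CZ",
                                           "CE2", "CD2"), 40),
                    ligand_atoms = vapply(paste0("R", 1:6), idx, 1L))
  )
  # the amine nitrogen is formally protonated so charged-group detection
  # sees a positive ligand group
  topo$atoms$formal_charge[idx("N1")] <- 1L
  list(topology = topo, entries = entries, seed = seed)
}

#' Assign toy force-field parameters to a structure
#'
#' Charges are drawn uniformly and shifted so each molecule (protein /
#' ligand) sums exactly to its total formal charge; Lennard-Jones and Born
#' parameters are drawn from physically plausible ranges (epsilon 0.05-0.2
#' kcal/mol, Rmin/2 1.3-1.9 Angstrom, Born radii 1.0-2.5 Angstrom).
#' Deterministic given the seed.
#'
#' @param structure a `MolecularStructure`.
#' @param seed RNG seed.
#' @return a [forcefield_params()] aligned with the structure's atoms.
#' @export
assign_toy_forcefield <- function(structure, seed = 20220406) {
  set.seed(seed)
  a <- structure$atoms
  n <- nrow(a)
  q <- numeric(n)
  for (grp in split(seq_len(n), a$is_ligand)) {
    qq <- runif(length(grp), -0.3, 0.3)
    total <- sum(a$formal_charge[grp])
    q[grp] <- qq - mean(qq) + total / length(grp)
  }
  forcefield_params(
    partial_charge = q,
    lj_epsilon = runif(n, 0.05, 0.2),
    lj_rmin_half = runif(n, 1.3, 1.9),
    gb_radius = runif(n, 1.0, 2.5)
  )
}

#' @export
print.ContactSchedule <- function(x, ...) {
  cat(sprintf("ContactSchedule: %d entries over %d frames (jitter %.2f A, seed %d)\n",
              length(x$entries), x$n_frames, x$jitter_sigma, x$seed))
  invisible(x)
}
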