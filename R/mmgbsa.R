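# Single-trajectory MM-GBSA binding free-energy decomposition.
#
# dG_bind = dG_gas + dG_solv (entropy neglected), with
#   dG_gas  = dE_bond + dE_vdW + dE_elec   (dE_bond = 0: complex, receptor
#             and ligand geometries all come from the complex frame, so
#             intramolecular bonded terms cancel exactly)
#   dG_solv = dG_GB + dG_SA
# The polar term is generalized Born with OBC rescaling, parameter set I
# (alpha = 0.8, beta = 0, gamma = 2.909125); the nonpolar term is
# gamma_sasa * SASA + beta_sasa over a Shrake-Rupley surface.
# Electrostatic constant 332.0636 kcal*Angstrom/(mol*e^2); no cutoffs.

.KE <- 332.0636

#' Force-field parameter set for MM-GBSA
#'
#' @param partial_charge per-atom partial charges (e).
#' @param lj_epsilon per-atom Lennard-Jones well depths (kcal/mol).
#' @param lj_rmin_half per-atom Rmin/2 (Angstrom).
#' @param gb_radius per-atom intrinsic Born radii (Angstrom).
#' @param eps_in,eps_out interior/exterior dielectric (1, 78.5).
#' @param sasa_gamma,sasa_beta nonpolar surface coefficients
#'   (0.0072 kcal/mol/A^2, 0 kcal/mol).
#' @param probe_radius solvent probe radius (1.4 Angstrom).
#' @param gb_offset dielectric-boundary offset subtracted from intrinsic
#'   radii before descreening (default 0: radii used as given).
#' @param gb_alpha,gb_beta,gb_gamma OBC rescaling coefficients; defaults are
#'   parameter set I.
#' @param gb_screen per-atom descreening scale factors (default 0.8).
#' @return object of class `ForceFieldParams`.
#' @export
forcefield_params <- function(partial_charge, lj_epsilon, lj_rmin_half,
                              gb_radius, eps_in = 1, eps_out = 78.5,
                              sasa_gamma = 0.0072, sasa_beta = 0,
                              probe_radius = 1.4, gb_offset = 0,
                              gb_alpha = 0.8, gb_beta = 0,
                              gb_gamma = 2.909125, gb_screen = 0.8) {
  n <- length(partial_charge)
  stopifnot(length(lj_epsilon) == n, length(lj_rmin_half) == n,
            length(gb_radius) == n)
  if (eps_in <= 0 || eps_out <= 0) stop("dielectrics must be positive")
  if (any(gb_radius <= 0)) stop("Born radii must be positive")
  if (length(gb_screen) == 1L) gb_screen <- rep(gb_screen, n)
  structure(list(partial_charge = as.numeric(partial_charge),
                 lj_epsilon = as.numeric(lj_epsilon),
                 lj_rmin_half = as.numeric(lj_rmin_half),
                 gb_radius = as.numeric(gb_radius),
                 gb_screen = as.numeric(gb_screen),
                 eps_in = eps_in, eps_out = eps_out,
                 sasa_gamma = sasa_gamma, sasa_beta = sasa_beta,
                 probe_radius = probe_radius, gb_offset = gb_offset,
                 gb_alpha = gb_alpha, gb_beta = gb_beta,
                 gb_gamma = gb_gamma),
            class = "ForceFieldParams")
}

.subset_params <- function(params, idx) {
  p <- params
  for (nm in c("partial_charge", "lj_epsilon", "lj_rmin_half",
               "gb_radius", "gb_screen"))
    p[[nm]] <- params[[nm]][idx]
  p
}

#' Pairwise molecular-mechanics energies
#'
#' Coulomb and Lennard-Jones energies over an explicit pair list:
#' `E_elec = sum 332.0636 q_i q_j / (eps_in r_ij)` and
#' `E_vdW = sum eps_ij [(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6]` with
#' `eps_ij = sqrt(eps_i eps_j)`, `Rmin_ij = Rmin_i/2 + Rmin_j/2`.
#' No distance cutoff.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param params a [forcefield_params()] aligned with `coords`.
#' @param pairs 2-column integer matrix of atom-index pairs.
#' @return list with `E_vdW` and `E_elec` in kcal/mol.
#' @export
pairwise_mm <- function(coords, params, pairs) {
  if (!nrow(pairs)) return(list(E_vdW = 0, E_elec = 0))
  i <- pairs[, 1]; j <- pairs[, 2]
  if (any(is.na(params$partial_charge[c(i, j)])) ||
      any(is.na(params$lj_epsilon[c(i, j)])))
    stop("missing charge/LJ parameters for atoms in pair list")
  d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  if (any(d == 0)) stop("zero interatomic distance in pair list")
  q <- params$partial_charge
  e_elec <- sum(.KE * q[i] * q[j] / (params$eps_in * d))
  eps_ij <- sqrt(params$lj_epsilon[i] * params$lj_epsilon[j])
  rmin_ij <- params$lj_rmin_half[i] + params$lj_rmin_half[j]
  sr6 <- (rmin_ij / d)^6
  e_vdw <- sum(eps_ij * (sr6^2 - 2 * sr6))
  list(E_vdW = e_vdw, E_elec = e_elec)
}

# OBC effective Born radii: pairwise HCT descreening integral with the
# tanh rescaling of parameter set I.
.obc_radii <- function(coords, params) {
  n <- nrow(coords)
  rho <- params$gb_radius - params$gb_offset
  if (any(rho <= 0)) stop("nonpositive reduced Born radius for atom ",
                          which(rho <= 0)[1])
  s <- params$gb_screen * rho
  R <- numeric(n)
  if (n > 1L) d <- .dist_mat(coords, coords)
  for (i in seq_len(n)) {
    I_i <- 0
    if (n > 1L) for (j in seq_len(n)) {
      if (j == i) next
      r <- d[i, j]; sj <- s[j]
      if (rho[i] >= r + sj) next             # j fully inside i
      U <- r + sj
      L <- if (rho[i] > r - sj) rho[i] else r - sj
      term <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                       (1 / (2 * r)) * log(L / U) +
                       (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
      if (rho[i] < sj - r) term <- term + (1 / rho[i] - 1 / L)
      I_i <- I_i + term
    }
    psi <- I_i * rho[i]
    inv <- 1 / rho[i] -
      tanh(params$gb_alpha * psi - params$gb_beta * psi^2 +
             params$gb_gamma * psi^3) / params$gb_radius[i]
    if (inv <= 0)
      stop("nonpositive effective Born radius for atom ", i)
    R[i] <- 1 / inv
  }
  R
}

#' Generalized-Born polar solvation energy (OBC variant)
#'
#' Effective Born radii come from the pairwise descreening integral with
#' OBC tanh rescaling (parameter set I by default); the energy is the
#' canonical pairwise expression
#' `-1/2 (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`, self terms
#' included. A single atom reduces to the Born equation with its intrinsic
#' radius.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param params a [forcefield_params()] aligned with `coords`.
#' @return `dG_GB` in kcal/mol.
#' @export
gb_polar <- function(coords, params) {
  coords <- as.matrix(coords)
  R <- .obc_radii(coords, params)
  q <- params$partial_charge
  tau <- 1 / params$eps_in - 1 / params$eps_out
  n <- nrow(coords)
  e <- sum(q^2 / R)  # self terms (f_GB = R_i at r = 0)
  if (n > 1L) {
    d <- .dist_mat(coords, coords)
    RR <- outer(R, R)
    f <- sqrt(d^2 + RR * exp(-d^2 / (4 * RR)))
    qq <- outer(q, q)
    off <- qq / f
    diag(off) <- 0
    e <- e + sum(off)
  }
  -0.5 * .KE * tau * e
}

# deterministic generalized-spiral (golden-angle) point set on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere sampling with a deterministic generalized-spiral point set: a
#' sample point on atom i's expanded sphere (radius + probe) is accessible
#' iff it lies outside every other atom's expanded sphere. Per-atom SASA is
#' the accessible fraction times the expanded-sphere area.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom radii (Angstrom).
#' @param probe probe radius (default 1.4 Angstrom).
#' @param n_points sample points per atom (default 960, >= 100).
#' @return list with `total` and per-atom `area` (Angstrom^2).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0), n_points >= 100L)
  pts <- .sphere_points(n_points)
  ext <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * ext[i], 2, coords[i, ], `+`)
    # neighbors that could occlude
    if (n > 1L) {
      dctr <- sqrt(colSums((t(coords) - coords[i, ])^2))
      nb <- which(dctr < ext[i] + ext & seq_len(n) != i)
    } else nb <- integer(0)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, coords[j, ])^2)
      free <- free & d2 > ext[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * ext[i]^2 * sum(free) / n_points
  }
  list(total = sum(area), area = area)
}

#' Single-trajectory MM-GBSA binding energy decomposition
#'
#' For every (strided) frame, the complex, receptor, and ligand geometries
#' are all taken from the complex frame, so intramolecular terms cancel:
#' dE_vdW and dE_elec are the direct receptor-ligand cross sums, dG_GB is
#' GB(complex) - GB(receptor) - GB(ligand), and dG_SA likewise over
#' Shrake-Rupley areas. Entropy is neglected. Per-term means and population
#' SDs over frames are reported.
#'
#' @param traj a `TrajectoryEnsemble` whose topology flags ligand atoms.
#' @param params a [forcefield_params()] aligned with the topology atoms.
#' @param ligand ligand atom indices (default: flagged atoms).
#' @param stride use every `stride`-th frame (default 1).
#' @param sasa_points Shrake-Rupley sample points per atom.
#' @return object of class `EnergyDecomposition`: `per_frame` data.frame
#'   with all Delta terms, and `summary` (mean, sd per term).
#' @export
binding_energy <- function(traj, params, ligand = NULL, stride = 1L,
                           sasa_points = 480L) {
  topo <- traj$topology
  nat <- nrow(topo$atoms)
  if (is.null(ligand)) ligand <- which(topo$atoms$is_ligand)
  if (!length(ligand)) stop("no ligand atoms flagged or supplied")
  if (length(params$partial_charge) != nat)
    stop("params cover ", length(params$partial_charge),
         " atoms; topology has ", nat)
  bad <- which(is.na(params$partial_charge) | is.na(params$lj_epsilon) |
                 is.na(params$lj_rmin_half) | is.na(params$gb_radius))
  if (length(bad))
    stop("missing force-field parameters for atom(s): ",
         paste(head(bad, 10L), collapse = ", "))
  recept <- setdiff(seq_len(nat), ligand)
  pairs <- as.matrix(expand.grid(recept, ligand))
  pp <- .subset_params(params, recept)
  pl <- .subset_params(params, ligand)
  frames <- seq(1L, n_frames(traj), by = stride)
  per <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- traj$frames[[frames[k]]]
    mm <- pairwise_mm(f, params, pairs)
    g_c <- gb_polar(f, params)
    g_p <- gb_polar(f[recept, , drop = FALSE], pp)
    g_l <- gb_polar(f[ligand, , drop = FALSE], pl)
    s_c <- sasa(f, params$gb_radius, params$probe_radius, sasa_points)$total
    s_p <- sasa(f[recept, , drop = FALSE], pp$gb_radius,
                params$probe_radius, sasa_points)$total
    s_l <- sasa(f[ligand, , drop = FALSE], pl$gb_radius,
                params$probe_radius, sasa_points)$total
    dE_vdW <- mm$E_vdW
    dE_elec <- mm$E_elec
    dG_GB <- g_c - g_p - g_l
    dG_SA <- (params$sasa_gamma * s_c + params$sasa_beta) -
      (params$sasa_gamma * s_p + params$sasa_beta) -
      (params$sasa_gamma * s_l + params$sasa_beta)
    per[[k]] <- data.frame(frame = frames[k], dE_bond = 0,
                           dE_vdW = dE_vdW, dE_elec = dE_elec,
                           dG_gas = 0 + dE_vdW + dE_elec,
                           dG_GB = dG_GB, dG_SA = dG_SA,
                           dG_solv = dG_GB + dG_SA,
                           dG_bind = dE_vdW + dE_elec + dG_GB + dG_SA)
  }
  per <- do.call(rbind, per)
  terms <- setdiff(names(per), "frame")
  summ <- data.frame(
    term = terms,
    mean = vapply(terms, function(t) mean(per[[t]]), 0),
    sd = vapply(terms, function(t) sqrt(mean((per[[t]] - mean(per[[t]]))^2)), 0),
    row.names = NULL
  )
  structure(list(per_frame = per, summary = summ,
                 n_frames_used = nrow(per)),
            class = "EnergyDecomposition")
}

#' @export
print.EnergyDecomposition <- function(x, ...) {
  cat(sprintf("MM-GBSA decomposition over %d frames (kcal/mol):\n",
              x$n_frames_used))
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-8s %10.4f +/- %.4f\n", s$term[r], s$mean[r], s$sd[r]))
  invisible(x)
}
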