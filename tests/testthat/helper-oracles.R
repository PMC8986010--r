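# Independent oracles and small builders shared across the suite.
# Every oracle is a deliberately naive re-implementation kept separate from
# the package's code paths.

# rotation matrix from an axis-angle 3-vector (Rodrigues)
rot_from_vec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# brute-force minimum RMSD over rotations: coarse axis-angle grid followed
# by Nelder-Mead refinement; translation handled by centroid alignment.
grid_search_rmsd <- function(reference, mobile) {
  qc <- sweep(reference, 2, colMeans(reference))
  pc <- sweep(mobile, 2, colMeans(mobile))
  obj <- function(v) {
    R <- rot_from_vec(v)
    sqrt(mean(rowSums((pc %*% t(R) - qc)^2)))
  }
  best <- c(0, 0, 0); bestval <- obj(best)
  gr <- seq(-pi, pi, length.out = 9)
  for (a in gr) for (b in gr) for (cc in gr) {
    v <- c(a, b, cc)
    if (sqrt(sum(v^2)) > pi + 1e-9) next
    val <- obj(v)
    if (val < bestval) { bestval <- val; best <- v }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# direct re-statement of the hydrogen-bond inequalities
hbond_oracle <- function(D, H, A, dist_cutoff = 3.5, angle_cutoff = 120) {
  dDA <- sqrt(sum((D - A)^2))
  v1 <- D - H; v2 <- A - H
  ang <- acos(max(-1, min(1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  (dDA < dist_cutoff) && (ang > angle_cutoff)
}

# exhaustive pharmacophore matcher: expand.grid over per-label candidate
# lists (0 = unassigned), filtering injectivity, constraints, minimum size,
# and the radius acceptance rule after superposition.
exhaustive_match <- function(model, features, min_points = 3L) {
  labels <- model$features$label
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  rownames(centers) <- labels
  radii <- model$features$radius
  fpos <- as.matrix(features[, c("x", "y", "z")])
  cand <- lapply(model$features$ftype, function(t)
    c(0L, which(features$ftype == t)))
  grid <- do.call(expand.grid, cand)
  hits <- list()
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    sel <- which(assign > 0L)
    if (length(sel) < min_points) next
    if (any(duplicated(assign[sel]))) next
    if (!constraints_satisfied(model$constraints, labels[sel])) next
    fit <- tryCatch(kabsch_superpose(centers[sel, , drop = FALSE],
                                     fpos[assign[sel], , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    moved <- sweep(fpos[assign[sel], , drop = FALSE] %*% t(fit$rotation),
                   2, fit$translation, `+`)
    dev <- sqrt(rowSums((moved - centers[sel, , drop = FALSE])^2))
    if (any(dev > radii[sel])) next
    hits[[length(hits) + 1L]] <- list(
      key = paste(labels[sel], assign[sel], sep = ":", collapse = ","),
      rmsd = fit$rmsd)
  }
  hits
}

# one-residue + one-ligand-atom-group toy topology for detector tests
make_probe_topology <- function(resname = "ARG", lig_atoms, lig_elements,
                                lig_charge = 0L) {
  prot <- ppiscreen:::.toy_residue(resname, 1, "A", c(0, 0, 0), dir = 1)
  lig <- data.frame(name = paste0("L", seq_len(nrow(lig_atoms))),
                    element = lig_elements,
                    x = lig_atoms[, 1], y = lig_atoms[, 2], z = lig_atoms[, 3],
                    resname = "LIG", resseq = 99, chain = "X")
  atoms <- rbind(prot, lig)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$is_ligand <- atoms$chain == "X"
  atoms$formal_charge <- 0L
  atoms$formal_charge[atoms$is_ligand] <- lig_charge
  molecular_structure(atoms)
}

random_rigid_motion <- function() {
  R <- rot_from_vec(runif(3, -pi, pi) * runif(1))
  t <- runif(3, -10, 10)
  list(R = R, t = t)
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, `+`)
}

# benzene as SDF text (Kekule connection table) for parser tests
benzene_sdf_text <- function(logp_field = NULL) {
  th <- (0:5) * pi / 3
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    1.395 * cos(th), 1.395 * sin(th), 0, "C")
  bond_lines <- sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), c(2, 1, 2, 1, 2, 1))
  extra <- if (!is.null(logp_field))
    c(">  <LOGP>", as.character(logp_field), "") else character(0)
  c("benzene", "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 6L, 6L),
    atom_lines, bond_lines, "M  END", extra, "$$$$")
}

# glycine zwitterion with explicit heavy atoms only
glycine_zwitterion <- function() {
  small_molecule(
    elements = c("N", "C", "C", "O", "O"),
    bonds = data.frame(i = c(1, 2, 3, 3), j = c(2, 3, 4, 5),
                       order = c(1, 1, 2, 1)),
    conformers = matrix(c(0, 0, 0,
                          1.47, 0, 0,
                          2.2, 1.25, 0,
                          1.6, 2.3, 0,
                          3.45, 1.2, 0), 5, 3, byrow = TRUE),
    formal_charge = c(1L, 0L, 0L, 0L, -1L),
    name = "glycine-zwitterion")
}

# diprotonated piperazine ring
piperazine_2h <- function() {
  th <- (0:5) * pi / 3
  small_molecule(
    elements = c("N", "C", "C", "N", "C", "C"),
    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = 1),
    conformers = cbind(1.46 * cos(th), 1.46 * sin(th), 0),
    formal_charge = c(1L, 0L, 0L, 1L, 0L, 0L),
    name = "piperazine-2H")
}

# a Ph_1-style model built fresh from the toy interface
toy_ph1 <- function(seed = 20220406) {
  ti <- make_toy_interface(seed)
  m <- build_interface_model(ti$structure, ti$hotspots_receptor, "Ph1-type")
  m$constraints <- interface_constraints()
  m
}

toy_ph2 <- function(seed = 20220406) {
  ti <- make_toy_interface(seed)
  m <- build_interface_model(ti$structure, ti$hotspots_ligand, "Ph2-type")
  m$constraints <- interface_constraints()
  m
}
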