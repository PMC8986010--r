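# Trajectory stability metrics and geometric contact detection.
#
# RMSD/RMSF use Kabsch superposition (proper rotation via SVD with
# reflection correction). Contact detectors implement the geometric
# criteria: hydrogen bond D-A < 3.5 A with D-H...A angle > 120 deg;
# salt bridge 4.0 A between oppositely charged group heavy atoms;
# hydrophobic 4.5 A carbon-carbon; aromatic 5.5 A ring-centroid distance.
# Occupancy aggregates events per pair and per residue, counted with
# multiplicity, so per-residue values can exceed 100%.

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `mobile` onto `reference`. Reflections are excluded.
#'
#' @param reference,mobile n x 3 coordinate matrices, n >= 3, not collinear.
#' @param weights optional non-negative weights, length n.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector), and `rmsd` (Angstrom): `x_fit = x_mobile %*% t(R) + t`.
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n < 3L || nrow(mobile) != n)
    stop("superposition needs >= 3 points and equal point counts")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cref <- colSums(reference * w)
  cmob <- colSums(mobile * w)
  P <- sweep(mobile, 2, cmob)
  Q <- sweep(reference, 2, cref)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  # collinearity check: the two largest principal extents must be nonzero
  ext <- svd(Q, nu = 0, nv = 0)$d
  if (ext[2] < 1e-8 * max(ext[1], 1e-30))
    stop("degenerate (collinear) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fit - Q)^2)))
  list(rotation = R, translation = as.numeric(cref - cmob %*% t(R)),
       rmsd = rmsd)
}

.apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

.rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series of a trajectory
#'
#' Each frame is superposed onto the reference frame using `fit_selection`
#' only; the RMSD is then measured over `measure_selection`. Protein
#' backbone-on-backbone and protein-fit/ligand-measure modes are both just
#' choices of the two selections.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param fit_selection atom indices used for superposition (>= 3).
#' @param measure_selection atom indices over which RMSD is computed
#'   (default: the fit selection).
#' @param reference reference frame index (default 1).
#' @return data.frame (`frame`, `time`, `rmsd`) with attributes `mean` and
#'   `sd` (population SD over frames).
#' @export
rmsd_series <- function(traj, fit_selection,
                        measure_selection = fit_selection, reference = 1L) {
  N <- n_frames(traj)
  if (reference < 1L || reference > N) stop("invalid reference frame index")
  if (!length(fit_selection) || !length(measure_selection))
    stop("selections must be non-empty")
  ref <- traj$frames[[reference]]
  out <- numeric(N)
  for (k in seq_len(N)) {
    f <- traj$frames[[k]]
    fit <- kabsch_superpose(ref[fit_selection, , drop = FALSE],
                            f[fit_selection, , drop = FALSE])
    moved <- .apply_fit(f[measure_selection, , drop = FALSE], fit)
    out[k] <- .rmsd_plain(moved, ref[measure_selection, , drop = FALSE])
  }
  res <- data.frame(frame = seq_len(N), time = traj$frame_times, rmsd = out)
  attr(res, "mean") <- mean(out)
  attr(res, "sd") <- sqrt(mean((out - mean(out))^2))
  res
}

#' Per-atom RMSF about the time-average structure
#'
#' Two-pass procedure: frames are first fitted to frame 1 on the selection,
#' the selection's time-average structure is computed, frames are refitted
#' to that average, and RMSF_a = sqrt(mean_t |x_a(t) - mean_x_a|^2).
#'
#' @param traj a `TrajectoryEnsemble` with >= 2 frames.
#' @param selection atom indices (>= 3) to fit and report.
#' @return data.frame (`atom`, `name`, `resname`, `resseq`, `chain`, `rmsf`).
#' @export
rmsf <- function(traj, selection) {
  N <- n_frames(traj)
  if (N < 2L) stop("RMSF needs at least 2 frames")
  sel_frames <- lapply(traj$frames, function(f) f[selection, , drop = FALSE])
  ref <- sel_frames[[1]]
  fitted <- lapply(sel_frames, function(f) .apply_fit(f, kabsch_superpose(ref, f)))
  avg <- Reduce(`+`, fitted) / N
  fitted <- lapply(sel_frames, function(f) .apply_fit(f, kabsch_superpose(avg, f)))
  avg <- Reduce(`+`, fitted) / N
  dev2 <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - avg)^2))) / N
  a <- traj$topology$atoms[selection, , drop = FALSE]
  data.frame(atom = selection, name = a$name, resname = a$resname,
             resseq = a$resseq, chain = a$chain, rmsf = sqrt(dev2))
}

# ------------------------------------------------------------------
# contact detection
# ------------------------------------------------------------------

.dist_mat <- function(a, b) {
  # pairwise Euclidean distances between rows of a and rows of b
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.angle_deg <- function(p1, p2, p3) {
  # angle at p2 between p1 and p3, degrees
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# single-linkage clustering of points at a distance cutoff; returns integer
# cluster labels. Deterministic given input order.
.link_clusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 0L) return(integer(0))
  lab <- seq_len(n)
  if (n > 1L) {
    d <- .dist_mat(xyz, xyz)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (d[i, j] <= cutoff && lab[i] != lab[j]) {
          lab[lab == lab[j]] <- lab[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(lab, unique(lab))
}

.moiety <- function(name) ifelse(name %in% .backbone_atoms, "Main", "Side")

.res_label <- function(atoms, i) {
  sprintf("%s%d", tools::toTitleCase(tolower(atoms$resname[i])), atoms$resseq[i])
}

.empty_events <- function() {
  data.frame(frame = integer(), contact_class = character(),
             chain = character(), resseq = integer(), resname = character(),
             residue = character(), role = character(),
             protein_atoms = character(), ligand_atoms = character(),
             pair_id = character(), distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

.event_row <- function(frame, class, atoms, prot_i, lig_i, role,
                       pair_extra, distance, angle = NA_real_) {
  i1 <- prot_i[1]
  data.frame(frame = frame, contact_class = class,
             chain = atoms$chain[i1], resseq = atoms$resseq[i1],
             resname = atoms$resname[i1],
             residue = .res_label(atoms, i1), role = role,
             protein_atoms = paste(prot_i, collapse = ","),
             ligand_atoms = paste(lig_i, collapse = ","),
             pair_id = pair_extra, distance = distance, angle = angle,
             stringsAsFactors = FALSE)
}

# polar ligand atoms grouped into functional groups (single linkage, 2.5 A)
.ligand_polar_groups <- function(frame, lig_idx, elements) {
  polar <- lig_idx[elements[lig_idx] %in% c("N", "O", "S")]
  if (!length(polar)) return(list())
  cl <- .link_clusters(frame[polar, , drop = FALSE], 2.5)
  split(polar, cl)
}

#' Detect hydrogen bonds between protein and ligand in one frame
#'
#' A hydrogen bond is a (D, H, A) triple with donor-acceptor distance
#' < 3.5 Angstrom and D-H...A angle > 120 degrees, where donor and acceptor
#' heavy atoms (N/O/S) sit on opposite sides of the protein-ligand divide.
#' Each satisfying triple is one event, so a donor group can contribute
#' multiple simultaneous bonds (the source of >100% occupancies). Donors
#' need an explicit bonded hydrogen (within 1.25 Angstrom); donors without
#' one are skipped with a warning.
#'
#' @param frame n x 3 coordinate matrix.
#' @param topology `MolecularStructure` of the full system.
#' @param donors,acceptors heavy-atom indices considered as donors /
#'   acceptors. Defaults: all N/O/S atoms on both sides.
#' @param ligand atom indices of the ligand side (default: flagged atoms).
#' @param frame_index frame number recorded in the events.
#' @param dist_cutoff,angle_cutoff criteria (default 3.5 A, 120 deg).
#' @return data.frame of contact events (`residue` is the protein residue).
#' @export
detect_hbonds <- function(frame, topology, donors = NULL, acceptors = NULL,
                          ligand = NULL, frame_index = 1L,
                          dist_cutoff = 3.5, angle_cutoff = 120) {
  atoms <- topology$atoms
  if (is.null(ligand)) ligand <- which(atoms$is_ligand)
  if (!length(ligand)) stop("no ligand atoms flagged or supplied")
  polar <- which(atoms$element %in% c("N", "O", "S"))
  if (is.null(donors)) donors <- polar
  if (is.null(acceptors)) acceptors <- polar
  hyd <- which(atoms$element == "H")
  is_lig <- seq_len(nrow(atoms)) %in% ligand
  lig_groups <- .ligand_polar_groups(frame, ligand, atoms$element)
  grp_of <- integer(nrow(atoms))
  for (g in seq_along(lig_groups)) grp_of[lig_groups[[g]]] <- g
  grp_name <- vapply(lig_groups, function(ix)
    paste0("LIG[", paste(sort(atoms$name[ix]), collapse = "+"), "]"), "")

  events <- list()
  for (D in donors) {
    # bonded hydrogens located geometrically
    if (!length(hyd)) { next }
    dh <- .dist_mat(frame[D, , drop = FALSE], frame[hyd, , drop = FALSE])
    Hs <- hyd[dh[1, ] < 1.25]
    if (!length(Hs)) {
      warning(sprintf("donor atom %d (%s) has no bonded hydrogen; skipped",
                      D, atoms$name[D]), call. = FALSE)
      next
    }
    for (A in acceptors) {
      if (A == D || is_lig[A] == is_lig[D]) next  # must cross the divide
      dDA <- sqrt(sum((frame[D, ] - frame[A, ])^2))
      if (dDA >= dist_cutoff) next
      for (H in Hs) {
        ang <- .angle_deg(frame[D, ], frame[H, ], frame[A, ])
        if (ang <= angle_cutoff) next
        prot_atom <- if (is_lig[D]) A else D
        lig_atom <- if (is_lig[D]) D else A
        role <- if (is_lig[D]) "acceptor" else "donor"
        lig_part <- if (grp_of[lig_atom] > 0) grp_name[grp_of[lig_atom]]
                    else paste0("LIG[", atoms$name[lig_atom], "]")
        prot_part <- sprintf("%s-%s", .res_label(atoms, prot_atom),
                             .moiety(atoms$name[prot_atom]))
        pair <- if (role == "donor") paste(prot_part, lig_part, sep = "|")
                else paste(lig_part, prot_part, sep = "|")
        events[[length(events) + 1L]] <-
          .event_row(frame_index, "hbond", atoms, prot_atom, lig_atom, role,
                     pair, dDA, ang)
      }
    }
  }
  if (!length(events)) return(.empty_events())
  do.call(rbind, events)
}

# charged groups of protein-like residues (template by residue name) or, for
# non-standard residues, clusters of formally charged atoms.
.charged_groups <- function(frame, topology, idx) {
  atoms <- topology$atoms
  out <- list()
  ri <- residue_index(topology)
  for (r in seq_len(nrow(ri))) {
    ai <- intersect(ri$atom_idx[[r]], idx)
    if (!length(ai)) next
    rn <- ri$resname[r]
    tmpl <- switch(rn,
      ARG = list(list(names = c("NE", "NH1", "NH2"), sign = +1)),
      LYS = list(list(names = "NZ", sign = +1)),
      HIS = list(list(names = c("ND1", "NE2"), sign = +1)),
      GLU = list(list(names = c("OE1", "OE2"), sign = -1)),
      ASP = list(list(names = c("OD1", "OD2"), sign = -1)),
      NULL)
    if (!is.null(tmpl)) {
      for (g in tmpl) {
        gi <- ai[atoms$name[ai] %in% g$names]
        if (length(gi)) out[[length(out) + 1L]] <-
            list(idx = gi, sign = g$sign, res = r)
      }
    } else {
      ch <- ai[atoms$formal_charge[ai] != 0]
      if (!length(ch)) next
      for (sgn in c(-1, 1)) {
        si <- ch[sign(atoms$formal_charge[ch]) == sgn]
        if (!length(si)) next
        cl <- .link_clusters(frame[si, , drop = FALSE], 2.5)
        for (g in split(si, cl)) out[[length(out) + 1L]] <-
            list(idx = g, sign = sgn, res = r)
      }
    }
  }
  out
}

#' Detect salt bridges between protein and ligand in one frame
#'
#' One event per (protein charged group, ligand charged group) pair of
#' opposite sign with any heavy-atom distance within the cutoff. Protein
#' charged groups follow residue templates (ARG/LYS/HIS positive, GLU/ASP
#' negative); ligand groups are clusters of formally charged atoms.
#'
#' @inheritParams detect_hbonds
#' @param cutoff heavy-atom distance cutoff (default 4.0 Angstrom).
#' @return data.frame of contact events.
#' @export
detect_salt_bridges <- function(frame, topology, ligand = NULL,
                                frame_index = 1L, cutoff = 4.0) {
  atoms <- topology$atoms
  if (is.null(ligand)) ligand <- which(atoms$is_ligand)
  prot <- setdiff(seq_len(nrow(atoms)), ligand)
  pg <- .charged_groups(frame, topology, prot)
  lg <- .charged_groups(frame, topology, ligand)
  events <- list()
  for (p in pg) for (l in lg) {
    if (p$sign * l$sign >= 0) next
    d <- min(.dist_mat(frame[p$idx, , drop = FALSE],
                       frame[l$idx, , drop = FALSE]))
    if (d >= cutoff) next
    pair <- sprintf("%s-%s(%s)|LIG[%s]",
                    .res_label(atoms, p$idx[1]), .moiety(atoms$name[p$idx[1]]),
                    if (p$sign > 0) "+" else "-",
                    paste(sort(atoms$name[l$idx]), collapse = "+"))
    events[[length(events) + 1L]] <-
      .event_row(frame_index, "salt_bridge", atoms, p$idx, l$idx, "none",
                 pair, d)
  }
  if (!length(events)) return(.empty_events())
  do.call(rbind, events)
}

#' Detect hydrophobic contacts between protein and ligand in one frame
#'
#' One event per (protein residue, ligand hydrophobic carbon cluster) with
#' any side-chain-carbon to ligand-carbon distance within the cutoff.
#'
#' @inheritParams detect_hbonds
#' @param ligand_hyd ligand carbon atom indices treated as hydrophobic
#'   (default: all ligand carbons); clustered at 2.0 Angstrom linkage.
#' @param cutoff carbon-carbon distance cutoff (default 4.5 Angstrom).
#' @return data.frame of contact events.
#' @export
detect_hydrophobic <- function(frame, topology, ligand = NULL,
                               ligand_hyd = NULL, frame_index = 1L,
                               cutoff = 4.5) {
  atoms <- topology$atoms
  if (is.null(ligand)) ligand <- which(atoms$is_ligand)
  prot <- setdiff(seq_len(nrow(atoms)), ligand)
  if (is.null(ligand_hyd)) ligand_hyd <- ligand[atoms$element[ligand] == "C"]
  if (!length(ligand_hyd)) return(.empty_events())
  cl <- .link_clusters(frame[ligand_hyd, , drop = FALSE], 2.0)
  clusters <- split(ligand_hyd, cl)
  sc <- prot[atoms$element[prot] == "C" & !(atoms$name[prot] %in% .backbone_atoms)]
  if (!length(sc)) return(.empty_events())
  ri <- residue_index(topology)
  events <- list()
  for (r in seq_len(nrow(ri))) {
    rsc <- intersect(ri$atom_idx[[r]], sc)
    if (!length(rsc)) next
    for (g in seq_along(clusters)) {
      d <- min(.dist_mat(frame[rsc, , drop = FALSE],
                         frame[clusters[[g]], , drop = FALSE]))
      if (d >= cutoff) next
      pair <- sprintf("%s-Side|LIG.hyd%d", .res_label(atoms, rsc[1]), g)
      events[[length(events) + 1L]] <-
        .event_row(frame_index, "hydrophobic", atoms, rsc, clusters[[g]],
                   "none", pair, d)
    }
  }
  if (!length(events)) return(.empty_events())
  do.call(rbind, events)
}

#' Detect aromatic (ring-ring) contacts between protein and ligand
#'
#' One event per (protein aromatic ring, ligand ring) pair whose centroid
#' distance is within the cutoff. Protein rings come from PHE/TYR/TRP/HIS
#' templates; ligand rings must be supplied (or stored on the topology as
#' `attr(topology, "ligand_rings")`, a list of atom-index vectors), since a
#' merged topology carries no bond orders.
#'
#' @inheritParams detect_hbonds
#' @param ligand_rings list of ligand atom-index vectors, one per ring.
#' @param cutoff centroid-centroid cutoff (default 5.5 Angstrom).
#' @return data.frame of contact events.
#' @export
detect_aromatic <- function(frame, topology, ligand = NULL,
                            ligand_rings = NULL, frame_index = 1L,
                            cutoff = 5.5) {
  atoms <- topology$atoms
  if (is.null(ligand)) ligand <- which(atoms$is_ligand)
  if (is.null(ligand_rings)) ligand_rings <- attr(topology, "ligand_rings")
  prot <- setdiff(seq_len(nrow(atoms)), ligand)
  ri <- residue_index(topology)
  if (is.null(ligand_rings)) {
    # protein-like "ligand" side (e.g. the partner chain of an interface):
    # derive rings from aromatic residue templates
    ligand_rings <- list()
    for (r in seq_len(nrow(ri))) {
      ring <- .ring6[[ri$resname[r]]]
      if (is.null(ring)) next
      ai <- intersect(ri$atom_idx[[r]], ligand)
      gi <- ai[match(ring, atoms$name[ai])]
      if (!any(is.na(gi))) ligand_rings[[length(ligand_rings) + 1L]] <- gi
    }
    if (!length(ligand_rings)) return(.empty_events())
  }
  events <- list()
  for (r in seq_len(nrow(ri))) {
    ring <- .ring6[[ri$resname[r]]]
    if (is.null(ring)) next
    ai <- intersect(ri$atom_idx[[r]], prot)
    gi <- ai[match(ring, atoms$name[ai])]
    if (any(is.na(gi))) next
    cen_p <- colMeans(frame[gi, , drop = FALSE])
    for (g in seq_along(ligand_rings)) {
      lr <- ligand_rings[[g]]
      cen_l <- colMeans(frame[lr, , drop = FALSE])
      d <- sqrt(sum((cen_p - cen_l)^2))
      if (d > cutoff) next
      pair <- sprintf("%s-Side|LIG.ring%d", .res_label(atoms, gi[1]), g)
      events[[length(events) + 1L]] <-
        .event_row(frame_index, "aromatic", atoms, gi, lr, "none", pair, d)
    }
  }
  if (!length(events)) return(.empty_events())
  do.call(rbind, events)
}

#' Run all contact detectors over every frame of a trajectory
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param classes which contact classes to detect.
#' @param ... passed through to the individual detectors.
#' @return data.frame of contact events over all frames.
#' @export
detect_contacts <- function(traj, classes = c("hbond", "salt_bridge",
                                              "hydrophobic", "aromatic"),
                            ...) {
  ev <- list()
  for (k in seq_len(n_frames(traj))) {
    f <- traj$frames[[k]]
    if ("hbond" %in% classes)
      ev[[length(ev) + 1L]] <- suppressWarnings(
        detect_hbonds(f, traj$topology, frame_index = k, ...))
    if ("salt_bridge" %in% classes)
      ev[[length(ev) + 1L]] <- detect_salt_bridges(f, traj$topology,
                                                   frame_index = k)
    if ("hydrophobic" %in% classes)
      ev[[length(ev) + 1L]] <- detect_hydrophobic(f, traj$topology,
                                                  frame_index = k)
    if ("aromatic" %in% classes)
      ev[[length(ev) + 1L]] <- detect_aromatic(f, traj$topology,
                                               frame_index = k)
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) out <- .empty_events()
  out
}

#' Contact occupancy aggregation
#'
#' Occupancy of a contact is `100/N * sum over frames of the number of
#' simultaneous bonds`, so a pair row counts multiplicity and a residue row
#' is the sum of its pair rows (and can exceed 100%).
#'
#' @param events contact-event data.frame from the detectors.
#' @param n_frames number of trajectory frames N.
#' @param grouping `"pair"` (residue, class, pair identity) or `"residue"`
#'   (residue, class).
#' @return data.frame with `occupancy_percent` (2-decimal convention applied
#'   at print time, full precision kept) and `n_frames`.
#' @export
occupancy <- function(events, n_frames,
                      grouping = c("pair", "residue")) {
  grouping <- match.arg(grouping)
  if (n_frames <= 0L) stop("occupancy needs N > 0 frames")
  keys <- if (grouping == "pair")
    c("chain", "resseq", "resname", "residue", "contact_class", "role", "pair_id")
  else c("chain", "resseq", "resname", "residue", "contact_class")
  if (!nrow(events)) {
    out <- events[keys]
    out$occupancy_percent <- numeric(0)
    out$n_frames <- integer(0)
    return(out)
  }
  counts <- aggregate(list(n_events = events$frame),
                      by = events[keys], FUN = length)
  counts$occupancy_percent <- 100 * counts$n_events / n_frames
  counts$n_events <- NULL
  counts$n_frames <- n_frames
  counts[order(-counts$occupancy_percent), , drop = FALSE]
}

#' Aggregate pair-level occupancies to residue level
#'
#' The per-residue occupancy is the sum of that residue's pair-level rows
#' (within a contact class); this is exactly how per-residue percentages
#' above 100% arise.
#'
#' @param pair_table data.frame with columns `residue` and
#'   `occupancy_percent` (optionally `contact_class`).
#' @return data.frame with one row per residue (and class, if present).
#' @export
residue_occupancy_from_pairs <- function(pair_table) {
  keys <- intersect(c("chain", "resseq", "resname", "residue", "contact_class"),
                    names(pair_table))
  out <- aggregate(list(occupancy_percent = pair_table$occupancy_percent),
                   by = pair_table[keys], FUN = sum)
  out[order(-out$occupancy_percent), , drop = FALSE]
}

#' Flag strong hydrogen bonds
#'
#' Rows with occupancy strictly above the threshold (default 75%) are
#' flagged strong.
#'
#' @param table an occupancy table.
#' @param threshold percent threshold (default 75).
#' @return the table with a logical `strong` column.
#' @export
strong_hbond_flag <- function(table, threshold = 75) {
  if (!nrow(table)) { table$strong <- logical(0); return(table) }
  table$strong <- table$occupancy_percent > threshold
  table
}
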