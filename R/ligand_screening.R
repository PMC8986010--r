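# Ligand-side pharmacophore perception and geometric matching.
#
# Feature perception is rule-based and deterministic from the bonded
# topology: aromatic rings from a fundamental cycle basis whose members are
# all unsaturated ring atoms; cations from protonatable/charged nitrogens;
# anions from carboxylate/sulfonate/phosphate/nitro group anchors;
# hydrophobic centroids from heteroatom-free carbon clusters (aromatic ring
# carbons excluded, since the ring is already represented by Aro); donors
# and acceptors from N/O hydrogen counts.

.default_valence <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, CL = 1, BR = 1, I = 1)

# implicit hydrogens on each atom from standard valences, bond orders and
# formal charge (N+ -> 4, O- -> 1, N- -> 2, O+ -> 3)
.implicit_h <- function(mol) {
  n <- n_atoms(mol)
  bsum <- numeric(n)
  for (r in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[r]
    if (o == 4) o <- 1.5  # aromatic bond flag
    bsum[mol$bonds$i[r]] <- bsum[mol$bonds$i[r]] + o
    bsum[mol$bonds$j[r]] <- bsum[mol$bonds$j[r]] + o
  }
  val <- .default_valence[mol$elements]
  val[is.na(val)] <- 0
  adj <- mol$formal_charge
  adj[!(mol$elements %in% c("N", "O", "P", "S"))] <- 0
  pmax(0, round(val + adj - bsum))
}

# fundamental-cycle ring basis via igraph; returns list of atom-index rings
.ring_basis <- function(mol) {
  if (nrow(mol$bonds) < 3L) return(list())
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms(mol))
    g <- igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g))
  mst <- igraph::mst(g)
  extra <- igraph::difference(g, mst)
  rings <- list()
  ee <- igraph::as_edgelist(extra)
  for (r in seq_len(nrow(ee))) {
    p <- igraph::shortest_paths(mst, from = ee[r, 1], to = ee[r, 2])$vpath[[1]]
    rings[[length(rings) + 1L]] <- as.integer(p)
  }
  rings
}

#' Perceive pharmacophore features on a ligand conformer
#'
#' @param mol a `SmallMolecule` with bonds.
#' @param conformer conformer index (default 1).
#' @return data.frame with columns `ftype`, `x`, `y`, `z` and a list-column
#'   `member_atoms` of atom indices.
#' @export
perceive_features <- function(mol, conformer = 1L) {
  if (conformer < 1L || conformer > length(mol$conformers))
    stop("conformer index ", conformer, " out of range")
  cf <- mol$conformers[[conformer]]
  el <- mol$elements
  adj <- .mol_adjacency(mol)
  n <- n_atoms(mol)
  deg <- lengths(adj)
  maxord <- numeric(n)
  for (r in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[r]
    maxord[mol$bonds$i[r]] <- max(maxord[mol$bonds$i[r]], o)
    maxord[mol$bonds$j[r]] <- max(maxord[mol$bonds$j[r]], o)
  }
  unsat <- maxord >= 2  # order-2/3 or aromatic(4) bond participation
  imph <- .implicit_h(mol)
  exph <- vapply(adj, function(nb) sum(el[nb] == "H"), numeric(1))

  feats <- list()
  add <- function(ftype, members, pos = NULL) {
    if (is.null(pos)) pos <- colMeans(cf[members, , drop = FALSE])
    feats[[length(feats) + 1L]] <<- list(ftype = ftype, pos = pos,
                                         members = as.integer(members))
  }

  # aromatic rings: cycle-basis rings whose atoms are all unsaturated
  rings <- .ring_basis(mol)
  aro_atoms <- integer(0)
  for (ring in rings) {
    if (length(ring) < 5L || length(ring) > 7L) next
    if (all(unsat[ring])) {
      add("Aro", ring)
      aro_atoms <- union(aro_atoms, ring)
    }
  }

  # cations: quaternary N, guanidinium C, charged/aliphatic amines
  guan_c <- integer(0)
  for (i in which(el == "C")) {
    nb <- adj[[i]]
    if (sum(el[nb] == "N") == 3L && length(nb) == 3L) {
      add("Cat", i, cf[i, ])
      guan_c <- c(guan_c, i)
    }
  }
  guan_n <- unique(unlist(adj[guan_c]))
  for (i in which(el == "N")) {
    if (i %in% guan_n) next
    nb <- adj[[i]]
    heavy <- nb[el[nb] != "H"]
    quaternary <- length(heavy) == 4L
    charged <- mol$formal_charge[i] > 0L
    # aliphatic amine: sp3 N (no multiple bond), not aromatic, not amide
    has_carbonyl <- function(c_) {
      any(vapply(adj[[c_]], function(o_) {
        el[o_] == "O" &&
          any(mol$bonds$order[(mol$bonds$i == c_ & mol$bonds$j == o_) |
                              (mol$bonds$j == c_ & mol$bonds$i == o_)] == 2)
      }, logical(1)))
    }
    amide <- any(vapply(heavy[el[heavy] == "C"], has_carbonyl, logical(1)))
    aliphatic <- !unsat[i] && !(i %in% aro_atoms) && !amide
    if (quaternary || charged || aliphatic) add("Cat", i, cf[i, ])
  }

  # anions: carboxylate / sulfonate / phosphate (terminal-oxygen groups) and
  # nitro (one anchor at the O-O midpoint)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    term_o <- nb[el[nb] == "O" & vapply(nb, function(o_)
      length(adj[[o_]][el[adj[[o_]]] != "H"]) == 1L, logical(1))]
    if (el[i] == "C" && length(term_o) == 2L) {
      # carboxylate / carboxylic acid group: anchor at the two-oxygen midpoint
      add("Ani", term_o)
    } else if (el[i] %in% c("S", "P") && length(term_o) >= 3L) {
      add("Ani", term_o)
    } else if (el[i] == "N" && length(term_o) == 2L && length(nb) >= 2L) {
      add("Ani", term_o)  # nitro oxygens as one group anchor
    }
  }

  # hydrophobic: maximal connected sets of >= 3 carbons with no bonded
  # heteroatom; aromatic-ring carbons are excluded (represented by Aro)
  hyd_ok <- el == "C" & !(seq_len(n) %in% aro_atoms) &
    vapply(seq_len(n), function(i)
      !any(!(el[adj[[i]]] %in% c("C", "H"))), logical(1))
  if (any(hyd_ok)) {
    keep <- which(hyd_ok)
    g <- igraph::graph_from_edgelist(
      as.matrix(mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep,
                          c("i", "j"), drop = FALSE]), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    for (cl in unique(comp[keep])) {
      members <- keep[comp[keep] == cl]
      if (length(members) >= 3L) add("Hyd", members)
    }
  }

  # donors / acceptors
  for (i in which(el %in% c("N", "O"))) {
    heavy <- adj[[i]][el[adj[[i]]] != "H"]
    if (exph[i] + imph[i] > 0) add("Don", i, cf[i, ])
    quaternary <- el[i] == "N" && length(heavy) == 4L
    if (!quaternary) add("Acc", i, cf[i, ])
  }

  if (!length(feats)) {
    return(data.frame(ftype = character(), x = numeric(), y = numeric(),
                      z = numeric(), member_atoms = I(list())))
  }
  data.frame(
    ftype = vapply(feats, `[[`, "", "ftype"),
    x = vapply(feats, function(f) f$pos[1], 0),
    y = vapply(feats, function(f) f$pos[2], 0),
    z = vapply(feats, function(f) f$pos[3], 0),
    member_atoms = I(lapply(feats, `[[`, "members")),
    stringsAsFactors = FALSE
  )
}

# recursive enumeration of injective, type-compatible assignments of model
# labels to ligand features; each label may stay unassigned.
.enumerate_assignments <- function(model, features) {
  labels <- model$features$label
  types <- model$features$ftype
  cand <- lapply(types, function(t) which(features$ftype == t))
  results <- list()
  recurse <- function(k, assign, used) {
    if (k > length(labels)) {
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    recurse(k + 1L, assign, used)          # leave label k unmatched
    for (f in cand[[k]]) {
      if (f %in% used) next
      a2 <- assign; a2[k] <- f
      recurse(k + 1L, a2, c(used, f))
    }
  }
  recurse(1L, rep(NA_integer_, length(labels)), integer(0))
  results
}

#' Match ligand features against a pharmacophore model
#'
#' Enumerates every injective, type-compatible assignment of ligand features
#' to a subset of model labels that passes the model's constraints and has
#' at least `min_points` members (3 by default: a 1- or 2-point rigid
#' superposition is geometrically underdetermined). Each assignment is
#' scored by Kabsch superposition of the assigned ligand-feature positions
#' onto the model-feature centers; it is accepted iff every assigned ligand
#' feature falls within its model feature's tolerance radius after
#' superposition.
#'
#' @param model a `PharmacophoreModel` with >= 1 feature.
#' @param features ligand feature table from [perceive_features()].
#' @param conformer conformer index recorded in the results.
#' @param radius_scale multiply all feature radii by this factor.
#' @param min_points minimum matched-subset size (default 3).
#' @return data.frame of accepted matches sorted by (`fit_rmsd`,
#'   lexicographic assignment); columns `conformer`, `fit_rmsd`,
#'   `n_matched`, `matched_labels`, and list-column `assignment`
#'   (named integer vector label -> ligand feature row). Zero rows when
#'   nothing matches.
#' @export
match_model <- function(model, features, conformer = 1L, radius_scale = 1,
                        min_points = 3L) {
  if (!nrow(model$features)) stop("model has no features")
  empty <- data.frame(conformer = integer(), fit_rmsd = numeric(),
                      n_matched = integer(), matched_labels = character(),
                      assignment = I(list()))
  if (!nrow(features)) return(empty)
  centers <- model_centers(model)
  radii <- model$features$radius * radius_scale
  labels <- model$features$label
  fpos <- as.matrix(features[, c("x", "y", "z")])
  hits <- list()
  for (assign in .enumerate_assignments(model, features)) {
    sel <- which(!is.na(assign))
    if (length(sel) < min_points) next
    if (!constraints_satisfied(model$constraints, labels[sel])) next
    fit <- tryCatch(
      kabsch_superpose(centers[sel, , drop = FALSE],
                       fpos[assign[sel], , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fit)) next
    moved <- .apply_fit(fpos[assign[sel], , drop = FALSE], fit)
    dev <- sqrt(rowSums((moved - centers[sel, , drop = FALSE])^2))
    if (any(dev > radii[sel])) next
    named <- setNames(assign[sel], labels[sel])
    hits[[length(hits) + 1L]] <- list(rmsd = fit$rmsd, assignment = named,
                                      key = paste(labels[sel], assign[sel],
                                                  sep = ":", collapse = ","))
  }
  if (!length(hits)) return(empty)
  ord <- order(vapply(hits, `[[`, 0, "rmsd"),
               vapply(hits, `[[`, "", "key"))
  hits <- hits[ord]
  data.frame(
    conformer = conformer,
    fit_rmsd = vapply(hits, `[[`, 0, "rmsd"),
    n_matched = vapply(hits, function(h) length(h$assignment), 0L),
    matched_labels = vapply(hits, function(h)
      paste(names(h$assignment), collapse = ","), ""),
    assignment = I(lapply(hits, `[[`, "assignment")),
    stringsAsFactors = FALSE
  )
}

#' Screen a set of molecules against a pharmacophore model
#'
#' Convenience wrapper: perceives features on every conformer of every
#' molecule, matches them, and (optionally) applies the Lipinski filter.
#'
#' @param model a `PharmacophoreModel`.
#' @param mols list of `SmallMolecule`s.
#' @param radius_scale tolerance-sphere scale factor.
#' @param skip_lipinski if TRUE, the drug-likeness columns are NA.
#' @return data.frame with one row per molecule: best match (if any),
#'   matched labels, fit RMSD, Lipinski verdict.
#' @export
screen_ligands <- function(model, mols, radius_scale = 1,
                           skip_lipinski = FALSE) {
  rows <- lapply(mols, function(mol) {
    best <- NULL
    for (cf in seq_along(mol$conformers)) {
      m <- match_model(model, perceive_features(mol, cf), conformer = cf,
                       radius_scale = radius_scale)
      if (nrow(m) && (is.null(best) || m$fit_rmsd[1] < best$fit_rmsd))
        best <- m[1, ]
    }
    lip <- if (skip_lipinski) NULL else
      tryCatch(lipinski_filter(mol), error = function(e) NULL)
    data.frame(
      id = mol$name,
      matched = !is.null(best),
      conformer = if (!is.null(best)) best$conformer else NA_integer_,
      matched_labels = if (!is.null(best)) best$matched_labels else "",
      fit_rmsd = if (!is.null(best)) best$fit_rmsd else NA_real_,
      lipinski_pass = if (!is.null(lip)) lip$passes else NA,
      violations = if (!is.null(lip))
        paste(lip$violated_rules, collapse = ",") else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
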