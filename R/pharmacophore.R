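# Interface-derived 3D pharmacophore models.  Hot-spot residues of a
# protein-protein interface are turned into typed feature spheres (Aro, Hyd,
# Ani, Cat, Don, Acc); the constraint logic is an essential label set plus
# at-least-k choice groups, the shape shared by both interface models used
# in the IL-6/IL-6R alpha workflow.

.ftypes <- c("Aro", "Hyd", "Ani", "Cat", "Don", "Acc")

#' Constraint specification for a pharmacophore model
#'
#' @param essential character vector of feature labels that must always be
#'   matched.
#' @param choice_groups list of `list(labels = c(...), k = 1)` entries; at
#'   least `k` labels of each group must be matched.
#' @return object of class `ConstraintSpec`.
#' @export
constraint_spec <- function(essential = character(0), choice_groups = list()) {
  for (g in choice_groups) {
    if (is.null(g$labels) || is.null(g$k))
      stop("each choice group needs $labels and $k")
    if (g$k < 1 || g$k > length(g$labels))
      stop("choice-group k must be in [1, group size]")
  }
  structure(list(essential = as.character(essential),
                 choice_groups = choice_groups),
            class = "ConstraintSpec")
}

#' Build a pharmacophore model
#'
#' @param name model name.
#' @param features data.frame with columns `label`, `ftype`, `x`, `y`, `z`,
#'   `radius` and optional `source_chain`, `source_resseq`, `source_resname`.
#' @param constraints a [constraint_spec()].
#' @return object of class `PharmacophoreModel`.
#' @export
pharmacophore_model <- function(name, features,
                                constraints = constraint_spec()) {
  stopifnot(is.data.frame(features))
  if (anyDuplicated(features$label)) stop("feature labels must be unique")
  if (!all(features$ftype %in% .ftypes))
    stop("unknown feature type: ",
         paste(setdiff(features$ftype, .ftypes), collapse = ", "))
  if (any(features$radius <= 0)) stop("feature radii must be positive")
  refd <- c(constraints$essential,
            unlist(lapply(constraints$choice_groups, `[[`, "labels")))
  if (!all(refd %in% features$label))
    stop("constraint references unknown label(s): ",
         paste(setdiff(refd, features$label), collapse = ", "))
  rownames(features) <- NULL
  structure(list(name = name, features = features, constraints = constraints),
            class = "PharmacophoreModel")
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  cat(sprintf("PharmacophoreModel '%s': %d features (%s)\n", x$name,
              nrow(x$features),
              paste(x$features$ftype, collapse = ", ")))
  invisible(x)
}

#' Check constraint satisfaction for a set of matched labels
#'
#' True iff every essential label is matched and every choice group has at
#' least its minimum count of matched labels. The predicate is monotone in
#' the matched set.
#'
#' @param constraints a [constraint_spec()].
#' @param matched_labels character vector of matched feature labels.
#' @return logical scalar.
#' @export
constraints_satisfied <- function(constraints, matched_labels) {
  if (!all(constraints$essential %in% matched_labels)) return(FALSE)
  for (g in constraints$choice_groups) {
    if (sum(g$labels %in% matched_labels) < g$k) return(FALSE)
  }
  TRUE
}

#' Map an interface interaction class to the complementary feature type
#'
#' The hot-spot mapping covers the three interaction classes seen at the
#' IL-6/IL-6R alpha site I interface: aromatic ring stacking, hydrophobic
#' packing, and salt bridges. For a salt bridge the feature type depends on
#' the partner residue's chemistry: an acidic residue contributes an anion
#' feature, a basic one a cation feature.
#'
#' @param interaction_class one of `"aromatic_ring"`, `"hydrophobic"`,
#'   `"salt_bridge"`.
#' @param residue_chemistry residue name or chemistry keyword; needed only
#'   for salt bridges (acidic: GLU/ASP/"acidic"; basic: ARG/LYS/HIS/"basic").
#' @return feature type string (`"Aro"`, `"Hyd"`, `"Ani"`, `"Cat"`).
#' @export
complementary_ftype <- function(interaction_class, residue_chemistry = NULL) {
  switch(interaction_class,
    aromatic_ring = "Aro",
    hydrophobic = "Hyd",
    salt_bridge = {
      rc <- toupper(residue_chemistry %||% "")
      if (rc %in% c("GLU", "ASP", "GLUTAMATE", "ASPARTATE", "ACIDIC")) "Ani"
      else if (rc %in% c("ARG", "LYS", "HIS", "ARGININE", "LYSINE", "BASIC")) "Cat"
      else stop("salt_bridge needs an acidic or basic partner chemistry, got: ",
                residue_chemistry)
    },
    stop("unmapped interaction class: ", interaction_class)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- feature-center derivation rules (deterministic from PDB atom names) ----

.ring6 <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
               HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.centroid <- function(m) colMeans(m)

# Returns the 3-vector feature center for one hotspot residue, or errors
# naming the residue when its side chain lacks the needed atoms.
.feature_center <- function(structure, idx, ftype, label) {
  a <- structure$atoms[idx, , drop = FALSE]
  resname <- a$resname[1]
  who <- sprintf("%s %s:%d%s", resname, a$chain[1], a$resseq[1], a$icode[1])
  get_atoms <- function(names_needed) {
    hit <- match(names_needed, a$name)
    if (any(is.na(hit)))
      stop(sprintf("residue %s lacks side-chain atom(s) %s needed for %s",
                   who, paste(names_needed[is.na(hit)], collapse = ","), ftype))
    cbind(a$x[hit], a$y[hit], a$z[hit])
  }
  switch(ftype,
    Aro = {
      ring <- .ring6[[resname]]
      if (is.null(ring))
        stop(sprintf("residue %s is not aromatic; cannot derive Aro", who))
      .centroid(get_atoms(ring))
    },
    Ani = {
      ox <- switch(resname, GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"),
                   stop(sprintf("residue %s is not acidic; cannot derive Ani", who)))
      .centroid(get_atoms(ox))
    },
    Cat = {
      anchor <- switch(resname, ARG = "CZ", LYS = "NZ",
                       stop(sprintf("residue %s is not basic; cannot derive Cat", who)))
      drop(get_atoms(anchor))
    },
    Hyd = {
      sc <- a[!(a$name %in% c(.backbone_atoms, "CB")) & a$element == "C", ,
              drop = FALSE]
      if (!nrow(sc))
        stop(sprintf("residue %s has no side-chain carbons beyond CB for Hyd", who))
      .centroid(cbind(sc$x, sc$y, sc$z))
    },
    Don = ,
    Acc = stop("Don/Acc interface features are not derived from residues ",
               "in this workflow"),
    stop("unknown feature type for residue chemistry: ", ftype)
  )
}

#' Build an interface pharmacophore model from hot-spot residues
#'
#' One feature per hot-spot residue, labeled F1...Fn in input order. Feature
#' centers are derived deterministically from side-chain chemistry: Aro is
#' the six-ring centroid (PHE/TYR; TRP six-ring), Ani the carboxylate-oxygen
#' midpoint (GLU OE1/OE2, ASP OD1/OD2), Cat the guanidinium carbon CZ (ARG)
#' or NZ (LYS), and Hyd the centroid of side-chain carbons beyond C-beta.
#' Constraints are left empty for the caller to set.
#'
#' @param structure a `MolecularStructure` containing the hotspot residues.
#' @param hotspots list of `c(chain, resseq, ftype)` triples, or a data.frame
#'   with columns `chain`, `resseq`, `ftype`.
#' @param name model name.
#' @param default_radius feature tolerance-sphere radius in Angstrom
#'   (default 1.0).
#' @return a [pharmacophore_model()].
#' @export
build_interface_model <- function(structure, hotspots, name = "model",
                                  default_radius = 1.0) {
  if (!is.data.frame(hotspots)) {
    hotspots <- do.call(rbind, lapply(hotspots, function(h)
      data.frame(chain = as.character(h[[1]]),
                 resseq = as.integer(h[[2]]),
                 ftype = as.character(h[[3]]),
                 stringsAsFactors = FALSE)))
  }
  rows <- vector("list", nrow(hotspots))
  for (k in seq_len(nrow(hotspots))) {
    ch <- hotspots$chain[k]; rs <- hotspots$resseq[k]; ft <- hotspots$ftype[k]
    idx <- residue_atoms_idx(structure, ch, rs)
    ctr <- .feature_center(structure, idx, ft, paste0("F", k))
    rows[[k]] <- data.frame(label = paste0("F", k), ftype = ft,
                            x = ctr[1], y = ctr[2], z = ctr[3],
                            radius = default_radius,
                            source_chain = ch, source_resseq = rs,
                            source_resname = structure$atoms$resname[idx[1]],
                            stringsAsFactors = FALSE)
  }
  pharmacophore_model(name, do.call(rbind, rows))
}

#' Standard interface constraint rule
#'
#' The rule shared by both interface models: F5 is essential, and at least
#' one of F1/F2 and at least one of F3/F4 must be matched.
#'
#' @return a [constraint_spec()].
#' @export
interface_constraints <- function() {
  constraint_spec(essential = "F5",
                  choice_groups = list(list(labels = c("F1", "F2"), k = 1L),
                                       list(labels = c("F3", "F4"), k = 1L)))
}

#' Serialize / deserialize a pharmacophore model
#'
#' Models are stored as a small JSON document (name, features with label,
#' type, center, radius, source residue; constraints as essential labels and
#' choice groups) so they can be versioned as plain-text fixtures.
#'
#' @param model a `PharmacophoreModel`.
#' @param path file path; for `read_model`, the file to read.
#' @return `write_model` returns the JSON string invisibly; `read_model`
#'   returns a `PharmacophoreModel`.
#' @export
write_model <- function(model, path = NULL) {
  doc <- list(name = model$name,
              features = model$features,
              constraints = list(
                essential = model$constraints$essential,
                choice_groups = lapply(model$constraints$choice_groups,
                                       function(g) list(labels = g$labels,
                                                        k = g$k))))
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cg <- doc$constraints$choice_groups
  groups <- if (is.data.frame(cg)) {
    lapply(seq_len(nrow(cg)), function(r)
      list(labels = unlist(cg$labels[r]), k = as.integer(cg$k[r])))
  } else lapply(cg, function(g) list(labels = unlist(g$labels),
                                     k = as.integer(g$k)))
  pharmacophore_model(doc$name, as.data.frame(doc$features),
                      constraint_spec(unlist(doc$constraints$essential) %||% character(0),
                                      groups))
}

model_centers <- function(model) {
  m <- as.matrix(model$features[, c("x", "y", "z")])
  rownames(m) <- model$features$label
  m
}
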