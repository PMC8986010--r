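# Candidate-selection cascade: docking-score filter (scores are consumed,
# not computed - docking is an external stage), top-hit rule (score,
# key-residue contacts, drug-likeness), and the final multi-criteria
# ranking by strong key-residue contacts then binding energy.

#' Default key-residue sets of the IL-6 / IL-6R alpha site I interface
#'
#' @param side `"il6"` (cytokine) or `"il6ra"` (receptor).
#' @return character vector of residue labels.
#' @export
key_residues <- function(side = c("il6", "il6ra")) {
  side <- match.arg(side)
  switch(side,
         il6 = c("Phe74", "Phe78", "Leu178", "Arg179", "Arg182"),
         il6ra = c("Phe229", "Tyr230", "Glu277", "Glu278", "Phe279"))
}

#' Binding-site residues within a radius of key residues
#'
#' Returns every residue with any atom within `radius` Angstrom of any atom
#' of the listed center residues (the conventional 10-Angstrom-sphere
#' binding-site definition).
#'
#' @param structure a `MolecularStructure`.
#' @param centers data.frame with `chain`, `resseq` (and optional `icode`)
#'   of the center residues.
#' @param radius sphere radius in Angstrom (default 10).
#' @return residue-index data.frame subset (see [residue_index()]).
#' @export
binding_site_residues <- function(structure, centers, radius = 10) {
  xyz <- coords(structure)
  cidx <- unlist(lapply(seq_len(nrow(centers)), function(k)
    residue_atoms_idx(structure, centers$chain[k], centers$resseq[k],
                      if (!is.null(centers$icode)) centers$icode[k] else "")))
  d <- .dist_mat(xyz, xyz[cidx, , drop = FALSE])
  near <- apply(d, 1, min) <= radius
  ri <- residue_index(structure)
  keep <- vapply(ri$atom_idx, function(ix) any(near[ix]), logical(1))
  ri[keep, , drop = FALSE]
}

.contact_set <- function(x) {
  if (is.list(x)) x else strsplit(as.character(x), "[,;]\\s*")
}

#' Docking-score screen
#'
#' Keeps records whose docking score is strictly below the cutoff
#' (default -20 kJ/mol): scores at the boundary are excluded.
#'
#' @param records data.frame with a `docking_score` column (kJ/mol).
#' @param score_cutoff strict cutoff in kJ/mol (default -20).
#' @return the surviving rows.
#' @export
screen_stage_filter <- function(records, score_cutoff = -20) {
  if (!nrow(records)) return(records)
  records[records$docking_score < score_cutoff, , drop = FALSE]
}

#' Top-hit selection rule
#'
#' A top hit must (i) score strictly below the cutoff (default -25 kJ/mol),
#' (ii) contact at least `min_key_contacts` of the key residues, and (iii)
#' pass the Lipinski filter.
#'
#' @param records data.frame with `docking_score` (kJ/mol), `contacts`
#'   (comma-separated residue labels or list-column), and `lipinski_pass`.
#' @param score_cutoff strict kJ/mol cutoff (default -25).
#' @param min_key_contacts minimum distinct key residues contacted (3).
#' @param key_residues character vector of key-residue labels (non-empty).
#' @return surviving rows with an added `n_key_contacts` column.
#' @export
top_hit_rule <- function(records, score_cutoff = -25, min_key_contacts = 3L,
                         key_residues) {
  stopifnot(length(key_residues) >= 1L)
  if (!nrow(records)) {
    records$n_key_contacts <- integer(0)
    return(records)
  }
  sets <- .contact_set(records$contacts)
  records$n_key_contacts <- vapply(sets, function(s)
    length(intersect(s, key_residues)), 0L)
  lip <- if (!is.null(records$lipinski_pass)) records$lipinski_pass
         else rep(TRUE, nrow(records))
  keep <- records$docking_score < score_cutoff &
    records$n_key_contacts >= min_key_contacts & lip
  records[keep, , drop = FALSE]
}

#' Count key residues with strong contacts for each candidate
#'
#' @param occ_table residue-level occupancy table with columns `id` (the
#'   candidate), `residue`, `occupancy_percent`.
#' @param key_residues key-residue labels.
#' @param threshold strong-contact occupancy threshold (default 75%).
#' @return named integer vector: candidate -> number of distinct key
#'   residues with any contact above the threshold.
#' @export
count_strong_key_contacts <- function(occ_table, key_residues,
                                      threshold = 75) {
  flagged <- strong_hbond_flag(occ_table, threshold)
  flagged <- flagged[flagged$strong & flagged$residue %in% key_residues, ,
                     drop = FALSE]
  counts <- tapply(flagged$residue, flagged$id,
                   function(r) length(unique(r)))
  out <- setNames(integer(length(unique(occ_table$id))),
                  unique(occ_table$id))
  out[names(counts)] <- as.integer(counts)
  out
}

#' Final candidate ranking
#'
#' Orders top hits by (1) number of key residues with a strong contact,
#' descending, then (2) mean binding free energy `dG_bind`, ascending (more
#' negative binds better). The rule formalizes the qualitative
#' multi-criteria combination of interaction occupancy and binding energy.
#'
#' @param records data.frame with `id`, `strong_key_contacts`, `dG_bind`.
#' @return the records ordered best-first with a `rank` column.
#' @export
rank_candidates <- function(records) {
  if (!nrow(records)) { records$rank <- integer(0); return(records) }
  ord <- order(-records$strong_key_contacts, records$dG_bind, records$id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
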