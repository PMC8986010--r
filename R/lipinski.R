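# Drug-likeness: the classic Rule of Five. MW < 500 Da, logP < 5,
# HBA (all N + O) <= 10, HBD (N-H and O-H hydrogens) <= 5.

.atomic_weight <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                    BR = 79.904, I = 126.904, B = 10.81, SI = 28.085)

# Coarse element/context-level atom-contribution logP in the
# Wildman-Crippen style. Contributions are per heavy atom plus a hydrogen
# term; aromatic vs aliphatic carbon is distinguished via ring/unsaturation
# context. Intended as a self-contained fallback ranking estimate, not a
# reproduction of the full 68-type scheme.
.logp_contrib <- c(C_ar = 0.1581, C_al = 0.1441, N = -0.6, O = -0.4,
                   S = 0.6482, P = 0.8612, F = 0.4202, CL = 0.6895,
                   BR = 0.8456, I = 0.8857, H = 0.1230)

#' Atom-contribution logP estimate
#'
#' A coarse Wildman-Crippen-style additive estimate: each heavy atom
#' contributes by element (aromatic and aliphatic carbon are distinguished),
#' and every explicit or implicit hydrogen adds a constant term. Useful for
#' threshold filtering when no measured/precomputed logP is supplied.
#'
#' @param mol a `SmallMolecule`.
#' @return numeric logP estimate.
#' @export
crippen_logp <- function(mol) {
  el <- mol$elements
  feats <- tryCatch(perceive_features(mol), error = function(e) NULL)
  aro_atoms <- integer(0)
  if (!is.null(feats) && nrow(feats)) {
    aro_atoms <- unique(unlist(feats$member_atoms[feats$ftype == "Aro"]))
  }
  total <- 0
  imph <- .implicit_h(mol)
  for (i in seq_along(el)) {
    e <- el[i]
    if (e == "H") { total <- total + .logp_contrib[["H"]]; next }
    key <- if (e == "C") { if (i %in% aro_atoms) "C_ar" else "C_al" } else e
    if (!key %in% names(.logp_contrib))
      stop("no logP contribution for element ", e)
    total <- total + .logp_contrib[[key]] + imph[i] * .logp_contrib[["H"]]
  }
  unname(total)
}

#' Lipinski drug-likeness filter
#'
#' Applies the Rule of Five: molecular weight < 500 Da, logP < 5,
#' hydrogen-bond acceptors (all N and O atoms) <= 10, hydrogen-bond donors
#' (N-H and O-H hydrogens, implicit hydrogens counted from standard
#' valences when explicit ones are absent) <= 5. Note the boundary
#' semantics: HBA = 10 and HBD = 5 pass, MW = 500 does not.
#'
#' @param mol a `SmallMolecule`. A `logp` entry in `mol$properties` is
#'   preferred; otherwise `logp_estimator` is called.
#' @param logp_estimator function(mol) -> numeric, default [crippen_logp()];
#'   set to NULL to require a precomputed logP.
#' @return list of class `LipinskiReport` with `mw`, `logp`, `hba`, `hbd`,
#'   `passes`, `violated_rules`.
#' @export
lipinski_filter <- function(mol, logp_estimator = crippen_logp) {
  el <- mol$elements
  unknown <- setdiff(el, names(.atomic_weight))
  if (length(unknown)) stop("unknown element(s): ",
                            paste(unknown, collapse = ", "))
  imph <- .implicit_h(mol)
  mw <- sum(.atomic_weight[el]) + sum(imph) * .atomic_weight[["H"]]
  no_idx <- which(el %in% c("N", "O"))
  hba <- length(no_idx)
  adj <- .mol_adjacency(mol)
  exph <- vapply(adj, function(nb) sum(el[nb] == "H"), numeric(1))
  hbd <- sum(exph[no_idx] + imph[no_idx])
  logp <- mol$properties$logp
  if (is.null(logp)) {
    if (is.null(logp_estimator))
      stop("no logp property present and no estimator configured")
    logp <- logp_estimator(mol)
  }
  logp <- as.numeric(logp)
  violated <- character(0)
  if (!(mw < 500)) violated <- c(violated, "MW")
  if (!(logp < 5)) violated <- c(violated, "LOGP")
  if (!(hba <= 10)) violated <- c(violated, "HBA")
  if (!(hbd <= 5)) violated <- c(violated, "HBD")
  structure(list(mw = unname(mw), logp = logp, hba = hba, hbd = hbd,
                 passes = length(violated) == 0L, violated_rules = violated),
            class = "LipinskiReport")
}

#' @export
print.LipinskiReport <- function(x, ...) {
  cat(sprintf("Lipinski: MW %.2f Da, logP %.2f, HBA %d, HBD %d -> %s%s\n",
              x$mw, x$logp, x$hba, x$hbd,
              if (x$passes) "pass" else "FAIL",
              if (x$passes) "" else paste0(" (", paste(x$violated_rules,
                                                       collapse = ", "), ")")))
  invisible(x)
}
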