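# SmallMolecule: bonded small-molecule topology with one or more 3D
# conformers and a free-form property map. SDF parsing is delegated to
# ChemmineR (V2000); formal charges come from the `M  CHG` property lines.

#' Construct a SmallMolecule
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame/matrix with columns `i`, `j`, `order` (1-based
#'   atom indices; order 1, 2, 3).
#' @param conformers list of n_atoms x 3 coordinate matrices (Angstrom), or a
#'   single matrix.
#' @param formal_charge integer vector per atom (default 0).
#' @param properties named list of molecule-level properties (e.g. a
#'   precomputed `logp`).
#' @param name molecule identifier.
#' @return object of class `SmallMolecule`.
#' @export
small_molecule <- function(elements, bonds, conformers,
                           formal_charge = NULL, properties = list(),
                           name = "mol") {
  n <- length(elements)
  stopifnot(n >= 1L)
  if (is.matrix(conformers)) conformers <- list(conformers)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    names(bonds)[1:3] <- c("i", "j", "order")
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoints must be valid atom indices")
  } else bonds <- data.frame(i = integer(), j = integer(), order = integer())
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3L)
      stop("conformer ", k, " must be an n_atoms x 3 coordinate matrix")
  }
  if (is.null(formal_charge)) formal_charge <- integer(n)
  stopifnot(length(formal_charge) == n)
  structure(list(name = name, elements = toupper(elements),
                 formal_charge = as.integer(formal_charge),
                 bonds = bonds, conformers = conformers,
                 properties = properties),
            class = "SmallMolecule")
}

#' @export
print.SmallMolecule <- function(x, ...) {
  cat(sprintf("SmallMolecule '%s': %d atoms, %d bonds, %d conformer(s)\n",
              x$name, length(x$elements), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

# adjacency list from the bond table
.mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Read molecules from an SDF/MOL file
#'
#' V2000 connection tables are parsed with ChemmineR; all `> <tag>` data
#' fields are kept in `properties` (a `LOGP`/`logP` field is normalized to
#' the `logp` property as a number), and formal charges are read from
#' `M  CHG` lines.
#'
#' @param source file path (plain or gzipped), connection, or SDF text.
#' @return list of [small_molecule()] objects.
#' @export
read_sdf <- function(source) {
  lines <- .open_text(source)
  if (!length(lines)) stop("empty SDF input")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  # split raw text per record for M CHG supplements
  recs <- split(lines, cumsum(c(0L, head(grepl("^\\$\\$\\$\\$", lines), -1L))))
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    m <- sdfs[[k]]
    ab <- ChemmineR::atomblock(m)
    bb <- ChemmineR::bondblock(m)
    raw <- recs[[k]]
    cnt_line <- raw[4L]
    na_decl <- suppressWarnings(as.integer(substr(cnt_line, 1, 3)))
    nb_decl <- suppressWarnings(as.integer(substr(cnt_line, 4, 6)))
    mend <- grep("^M  END", raw)[1]
    if (is.na(mend)) mend <- length(raw) + 1L
    avail <- mend - 5L  # connection-table lines present
    if (!is.na(na_decl) && !is.na(nb_decl) &&
        (na_decl + nb_decl > avail || na_decl != nrow(ab) ||
           nb_decl != NROW(bb)))
      stop("record ", k, ": atom/bond count mismatch with connection table")
    if (NROW(bb) && anyNA(bb[, 1:3]))
      stop("record ", k, ": atom/bond count mismatch with connection table")
    elements <- sub("_.*$", "", rownames(ab))
    conf <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- if (NROW(bb)) data.frame(i = as.integer(bb[, 1]),
                                      j = as.integer(bb[, 2]),
                                      order = as.integer(bb[, 3]))
             else data.frame(i = integer(), j = integer(), order = integer())
    fc <- integer(length(elements))
    for (chg in grep("^M  CHG", raw, value = TRUE)) {
      toks <- as.integer(strsplit(trimws(substr(chg, 7, nchar(chg))),
                                  "[[:space:]]+")[[1]])
      npair <- toks[1]
      for (p in seq_len(npair)) fc[toks[2 * p]] <- toks[2 * p + 1]
    }
    db <- tryCatch(ChemmineR::datablock(m), error = function(e) character(0))
    props <- as.list(db)
    lg <- names(props)[toupper(names(props)) %in% c("LOGP", "LOG_P", "XLOGP")]
    if (length(lg)) props$logp <- as.numeric(props[[lg[1]]])
    nm <- raw[1L]
    if (!nzchar(trimws(nm))) nm <- paste0("mol", k)
    out[[k]] <- small_molecule(elements, bonds, conf, fc, props, trimws(nm))
  }
  out
}

#' Write molecules to SDF (V2000) text
#'
#' @param mols a `SmallMolecule` or list of them.
#' @param path output file, or NULL to return lines.
#' @param conformer conformer index to write per molecule.
#' @return character lines, invisibly.
#' @export
write_sdf <- function(mols, path = NULL, conformer = 1L) {
  if (inherits(mols, "SmallMolecule")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    cf <- mol$conformers[[conformer]]
    n <- n_atoms(mol)
    nb <- nrow(mol$bonds)
    hdr <- c(mol$name, "  ppiscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          cf[, 1], cf[, 2], cf[, 3], mol$elements)
    bond_lines <- if (nb) sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                                  mol$bonds$order) else character(0)
    chg_idx <- which(mol$formal_charge != 0L)
    chg_lines <- if (length(chg_idx))
      sprintf("M  CHG%3d%s", length(chg_idx),
              paste0(sprintf("%4d%4d", chg_idx, mol$formal_charge[chg_idx]),
                     collapse = ""))
      else character(0)
    dat <- character(0)
    for (nm in names(mol$properties)) {
      dat <- c(dat, sprintf(">  <%s>", nm),
               as.character(mol$properties[[nm]]), "")
    }
    out <- c(out, hdr, atom_lines, bond_lines, chg_lines, "M  END", dat, "$$$$")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
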