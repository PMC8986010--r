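# Domain containers: MolecularStructure (protein-side atoms with coordinates
# and optional per-atom parameters) and TrajectoryEnsemble (frame series over
# a fixed topology).  All lengths are in Angstrom, times in ns.

#' Construct a MolecularStructure
#'
#' A `MolecularStructure` is an ordered table of atom records: serial, atom
#' name, element, residue identity (3-letter name, sequence number, insertion
#' code, chain), Cartesian coordinates in Angstrom, formal charge, and
#' optional per-atom force-field parameters (partial charge, Lennard-Jones
#' epsilon/Rmin half, generalized-Born radius).
#'
#' @param atoms data.frame with at least columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `x`, `y`, `z`. Optional columns `icode`,
#'   `formal_charge`, `occupancy`, `is_ligand`, `partial_charge`,
#'   `lj_epsilon`, `lj_rmin_half`, `gb_radius` are filled with defaults when
#'   absent.
#' @return object of class `MolecularStructure`.
#' @export
molecular_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("a MolecularStructure needs at least one atom")
  need <- c("serial", "name", "element", "resname", "resseq", "chain", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  defaults <- list(icode = "", formal_charge = 0L, occupancy = 1,
                   is_ligand = FALSE, partial_charge = NA_real_,
                   lj_epsilon = NA_real_, lj_rmin_half = NA_real_,
                   gb_radius = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resseq, icode, name): ",
         key[duplicated(key)][1L])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "MolecularStructure")
}

#' @export
print.MolecularStructure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("MolecularStructure: %d atoms, %d residues, chains %s\n",
              nrow(a), nrow(unique(a[, c("chain", "resseq", "icode")])),
              paste(unique(a$chain), collapse = "")))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure a `MolecularStructure`.
#' @param which optional integer/logical atom selection.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure, which = NULL) {
  a <- structure$atoms
  m <- cbind(x = a$x, y = a$y, z = a$z)
  if (!is.null(which)) m <- m[which, , drop = FALSE]
  m
}

#' Residue index of a structure
#'
#' @param structure a `MolecularStructure`.
#' @return data.frame with one row per residue (`chain`, `resseq`, `icode`,
#'   `resname`) and a list-column `atom_idx` of atom row indices.
#' @export
residue_index <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resseq, a$icode, sep = "\r")
  idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             icode = a$icode[first], resname = a$resname[first],
             atom_idx = I(unname(idx)), stringsAsFactors = FALSE)
}

# Select atom rows of one residue; error with residue label when absent.
residue_atoms_idx <- function(structure, chain, resseq, icode = "") {
  a <- structure$atoms
  hit <- which(a$chain == chain & a$resseq == resseq & a$icode == icode)
  if (!length(hit))
    stop(sprintf("residue %s:%d%s not found in structure", chain, resseq, icode))
  hit
}

.open_text <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (length(source) == 1L && file.exists(source)) {
    con <- if (grepl("\\.gz$", source)) gzfile(source, "rt") else file(source, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  # fall back: treat as literal text (possibly with embedded newlines)
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

.num_field <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  if (any(is.na(v)))
    stop(sprintf("parse error at line %d: malformed %s field '%s'",
                 lineno[is.na(v)][1L], what, trimws(txt[is.na(v)][1L])))
  v
}

.element_from_name <- function(name) {
  lead <- sub("[^A-Za-z].*$", "", sub("^[0-9]*", "", trimws(name)))
  two <- toupper(substr(lead, 1, 2))
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "SE")
  ifelse(two %in% known2 & nchar(lead) >= 2, two, toupper(substr(lead, 1, 1)))
}

#' Read a PDB file into a MolecularStructure
#'
#' Parses ATOM/HETATM records (fixed columns). Insertion codes are preserved
#' as part of the residue identity. Alternate locations are resolved to the
#' highest-occupancy conformation, ties broken by first occurrence. HETATM
#' records whose residue name matches `ligand_resname` are flagged as ligand
#' atoms.
#'
#' @param source file path (plain or gzipped), connection, or PDB text.
#' @param ligand_resname residue name(s) flagged as ligand (default "LIG").
#' @param model for multi-model files, which MODEL to read (default 1).
#' @return a [molecular_structure()].
#' @export
read_pdb <- function(source, ligand_resname = "LIG", model = 1L) {
  lines <- .open_text(source)
  if (!length(lines)) stop("empty PDB input")
  # restrict to the requested model when MODEL records are present
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    ends <- grep("^ENDMDL", lines)
    if (model > length(model_starts)) stop("model ", model, " not present")
    lo <- model_starts[model]
    hi <- if (length(ends) >= model) ends[model] else length(lines)
    keep <- seq(lo, hi)
  } else keep <- seq_along(lines)
  sel <- keep[grepl("^(ATOM  |HETATM)", lines[keep])]
  if (!length(sel)) stop("no ATOM/HETATM records in PDB input")
  ln <- lines[sel]
  pad <- function(s, n) formatC(s, width = -n)
  ln <- vapply(ln, pad, "", n = 80L, USE.NAMES = FALSE)
  field <- function(a, b) substr(ln, a, b)
  occ_txt <- trimws(field(55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ) | !nzchar(occ_txt)] <- 1
  element <- trimws(field(77, 78))
  name <- trimws(field(13, 16))
  element <- ifelse(nzchar(element), toupper(element), .element_from_name(name))
  atoms <- data.frame(
    record = trimws(field(1, 6)),
    serial = as.integer(.num_field(trimws(field(7, 11)), sel, "serial")),
    name = name,
    altloc = trimws(field(17, 17)),
    resname = trimws(field(18, 20)),
    chain = trimws(field(22, 22)),
    resseq = as.integer(.num_field(trimws(field(23, 26)), sel, "residue number")),
    icode = trimws(field(27, 27)),
    x = .num_field(trimws(field(31, 38)), sel, "coordinate"),
    y = .num_field(trimws(field(39, 46)), sel, "coordinate"),
    z = .num_field(trimws(field(47, 54)), sel, "coordinate"),
    occupancy = occ,
    element = element,
    stringsAsFactors = FALSE
  )
  # altLoc resolution: highest occupancy, tie -> first seen
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
  keep_row <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                            function(i) i[which.max(atoms$occupancy[i])]),
                     use.names = FALSE)
  atoms <- atoms[sort(keep_row), , drop = FALSE]
  atoms$is_ligand <- atoms$resname %in% ligand_resname
  atoms$formal_charge <- 0L
  atoms$altloc <- NULL
  atoms$record <- NULL
  molecular_structure(atoms)
}

#' Write a MolecularStructure as PDB text
#'
#' @param structure a `MolecularStructure`.
#' @param path output file, or `NULL` to return the lines invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(structure, path = NULL) {
  a <- structure$atoms
  fmt_name <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
                     paste0(" ", a$name), a$name)
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_ligand, "HETATM", "ATOM"),
                   a$serial %% 100000L, fmt_name, "", a$resname, a$chain,
                   a$resseq %% 10000L, a$icode, a$x, a$y, a$z,
                   a$occupancy, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Construct a TrajectoryEnsemble
#'
#' @param topology `MolecularStructure` of the full system (ligand atoms
#'   flagged via `is_ligand`).
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param frame_times numeric vector of times in ns, strictly increasing;
#'   default `stride * (1:N)` (first saved frame at one save interval).
#' @param stride frame save interval in ns used when `frame_times` is NULL
#'   (default 0.01 ns).
#' @return object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(topology, frames, frame_times = NULL, stride = 0.01) {
  stopifnot(inherits(topology, "MolecularStructure"), length(frames) >= 1L)
  nat <- nrow(topology$atoms)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || nrow(f) != nat || ncol(f) != 3L)
      stop("frame ", k, " has ", NROW(f), " atoms; topology has ", nat)
  }
  if (is.null(frame_times)) frame_times <- stride * seq_along(frames)
  if (length(frame_times) != length(frames) || any(diff(frame_times) <= 0))
    stop("frame_times must match frame count and be strictly increasing")
  structure(list(topology = topology, frames = frames,
                 frame_times = as.numeric(frame_times)),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms, %.2f-%.2f ns\n",
              length(x$frames), nrow(x$topology$atoms),
              x$frame_times[1], x$frame_times[length(x$frame_times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `TrajectoryEnsemble`.
#' @return integer frame count (the N of the occupancy formula).
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a multi-frame trajectory
#'
#' Two plain-text dialects are supported: multi-model PDB (MODEL/ENDMDL
#' blocks; the primary dialect because it carries residue identity) and XYZ
#' frame series. Every frame must match the topology's atom count.
#'
#' @param topology `MolecularStructure` describing all atoms.
#' @param source file path (plain or gzipped), connection, or text.
#' @param dialect `"multi-model-pdb"` or `"xyz-frames"`.
#' @param stride frame save interval in ns (default 0.01).
#' @return a [trajectory_ensemble()].
#' @export
read_trajectory <- function(topology, source,
                            dialect = c("multi-model-pdb", "xyz-frames"),
                            stride = 0.01) {
  dialect <- match.arg(dialect)
  lines <- .open_text(source)
  nat <- nrow(topology$atoms)
  frames <- list()
  if (dialect == "multi-model-pdb") {
    starts <- grep("^MODEL", lines)
    if (!length(starts)) starts <- 1L
    ends <- grep("^ENDMDL", lines)
    if (!length(ends)) ends <- length(lines)
    for (k in seq_along(starts)) {
      blk <- lines[starts[k]:ends[min(k, length(ends))]]
      rec <- blk[grepl("^(ATOM  |HETATM)", blk)]
      if (length(rec) != nat)
        stop("frame ", k, " has ", length(rec), " atoms; topology has ", nat)
      rec <- formatC(rec, width = -54L)
      m <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
      if (any(is.na(m))) stop("frame ", k, ": malformed coordinate field")
      frames[[k]] <- m
    }
  } else {
    i <- 1L
    k <- 0L
    lines <- lines[nzchar(trimws(lines)) | seq_along(lines) > 0]  # keep layout
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      k <- k + 1L
      if (is.na(n)) stop("frame ", k, ": malformed atom-count line")
      if (n != nat)
        stop("frame ", k, " has ", n, " atoms; topology has ", nat)
      body <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(body), "[[:space:]]+")
      m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      if (any(is.na(m))) stop("frame ", k, ": malformed coordinate field")
      frames[[k]] <- m
      i <- i + 2L + n
    }
  }
  trajectory_ensemble(topology, frames, stride = stride)
}

#' Write a trajectory as multi-model PDB or XYZ frames
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param path output file, or NULL to return lines.
#' @param dialect `"multi-model-pdb"` or `"xyz-frames"`.
#' @return character lines, invisibly.
#' @export
write_trajectory <- function(traj, path = NULL,
                             dialect = c("multi-model-pdb", "xyz-frames")) {
  dialect <- match.arg(dialect)
  topo <- traj$topology
  out <- character(0)
  if (dialect == "multi-model-pdb") {
    for (k in seq_along(traj$frames)) {
      s <- topo
      s$atoms$x <- traj$frames[[k]][, 1]
      s$atoms$y <- traj$frames[[k]][, 2]
      s$atoms$z <- traj$frames[[k]][, 3]
      body <- write_pdb(s)
      out <- c(out, sprintf("MODEL %8d", k), body[body != "END"], "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    el <- topo$atoms$element
    for (k in seq_along(traj$frames)) {
      f <- traj$frames[[k]]
      out <- c(out, as.character(nrow(f)), sprintf("frame %d", k),
               sprintf("%-2s %12.6f %12.6f %12.6f", el, f[, 1], f[, 2], f[, 3]))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
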