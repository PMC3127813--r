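# PDB reading/writing, delegated to bio3d with validation and selection
# on top. Author numbering and insertion codes are preserved verbatim;
# coordinates round-trip at the fixed-format precision (3 decimals).

# scan raw PDB text for unparseable ATOM/HETATM records; returns invisibly
# or stops naming the first offending line number
check_pdb_records <- function(lines, path) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in '", path, "'")
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    bad <- nchar(ln) < 54L ||
      is.na(suppressWarnings(as.numeric(substr(ln, 23, 26)))) ||
      anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                          substr(ln, 39, 46),
                                          substr(ln, 47, 54)))))
    if (bad)
      stop("malformed fixed-width PDB record at line ", i, " of '", path, "'")
  }
  invisible(idx)
}

# bio3d atom table -> Structure atom table
bio3d_atoms <- function(atom) {
  element <- atom$elesy
  no_elem <- is.na(element) | !nzchar(trimws(element))
  if (any(no_elem)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom$elety))
    element[no_elem] <- guess[no_elem]
  }
  data.frame(
    type = atom$type,
    serial = atom$eleno,
    name = trimws(atom$elety),
    resn = trimws(atom$resid),
    chain = ifelse(is.na(atom$chain), "", atom$chain),
    resno = atom$resno,
    insert = ifelse(is.na(atom$insert), "", atom$insert),
    x = atom$x, y = atom$y, z = atom$z,
    occ = ifelse(is.na(atom$o), 1, atom$o),
    b = ifelse(is.na(atom$b), 0, atom$b),
    element = trimws(element),
    stringsAsFactors = FALSE)
}

# first-altloc filter: within (chain, resno, insert, name) keep the first
# occurrence only
drop_altlocs <- function(atoms, alt) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  atoms[!duplicated(key), , drop = FALSE]
}

#' Read a structure from a PDB file
#'
#' Parses a fixed-width PDB file (via bio3d) into a [Structure()]. When
#' the file holds several MODELs, MODEL 1 is used; see [read_trajectory()]
#' for multi-model ingestion. Alternate locations are resolved to the
#' first conformer per atom name. HETATM records are kept by default
#' because docked ligands are usually non-standard chemistry.
#'
#' @param path PDB file path.
#' @param chain optional chain filter (character vector).
#' @param resno optional residue-number filter (integer vector).
#' @param het logical or NA: TRUE keeps only HETATM, FALSE only ATOM,
#'   NA (default) keeps both.
#' @param id identifier for the structure (defaults to the file name).
#' @return a [Structure()].
#' @examples
#' cfg <- generator_config(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_receptor(cfg), f)
#' s <- read_structure(f)
#' n_atoms(s)
#' @export
read_structure <- function(path, chain = NULL, resno = NULL, het = NA,
                           id = basename(path)) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  check_pdb_records(lines, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  atoms <- drop_altlocs(bio3d_atoms(pdb$atom))
  s <- Structure(atoms, id = id)
  keep <- seq_len(nrow(s$atoms))
  if (!is.null(chain)) keep <- intersect(keep, atom_select(s, chain = chain))
  if (!is.null(resno)) keep <- intersect(keep, atom_select(s, resno = resno))
  if (!is.na(het)) keep <- intersect(keep, atom_select(s, het = het))
  if (length(keep) == 0L)
    stop("empty selection: no atoms of '", path, "' match the requested ",
         "chain/residue/het filter")
  subset_structure(s, keep, id = id)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Each MODEL becomes one frame, in MODEL order; the topology (atom
#' identities) is taken from MODEL 1. All models must contain the same
#' number of atom records.
#'
#' @param path multi-model PDB file path.
#' @param frame_interval time between frames, ps (metadata; default 4.8).
#' @return a [Trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 4.8) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  check_pdb_records(lines, path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(grepl("^(ATOM  |HETATM)", lines[bounds[k]:(bounds[k + 1L] - 1L)]))
    }, integer(1))
    off <- which(counts != counts[1L])
    if (length(off))
      stop("inconsistent atom count in MODEL ", off[1L], " (",
           counts[off[1L]], " atoms vs ", counts[1L], " in MODEL 1)")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  atoms <- bio3d_atoms(pdb$atom)
  topo <- Structure(atoms, id = basename(path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  Trajectory(topo, xyz, frame_interval = frame_interval)
}

#' Write a Structure to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (via bio3d) terminated by END.
#' Coordinates are written at the format's 3-decimal precision, so a
#' write-then-read round trip reproduces them to within 0.001 angstrom.
#'
#' @param x a [Structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "Structure"))
  if (n_atoms(x) > 99999L)
    stop("PDB fixed format supports at most 99999 atoms; structure has ",
         n_atoms(x))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(x))),
                   type = a$type, eleno = a$serial, elety = a$name,
                   resid = a$resn, chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

#' Write a Trajectory to a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, atom records as in
#' [write_structure()].
#'
#' @param x a [Trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "Trajectory"))
  a <- x$topology$atoms
  if (nrow(a) > 99999L)
    stop("PDB fixed format supports at most 99999 atoms; topology has ",
         nrow(a))
  bio3d::write.pdb(file = path,
                   xyz = x$xyz,
                   type = a$type, eleno = a$serial, elety = a$name,
                   resid = a$resn, chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}
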