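#' Molecular structure container
#'
#' A `Structure` holds the atoms of one molecule (or complex) as a flat
#' atom table grouped into residues in file order. It is the common
#' currency of every analysis in the package: contact profiling, SASA and
#' trajectory analysis all consume it.
#'
#' @param atoms data frame with one row per atom and columns `type`
#'   ("ATOM"/"HETATM"), `serial`, `name`, `resn` (3-letter residue name),
#'   `chain` (single character), `resno` (author residue number),
#'   `insert` (insertion code, "" if none), `x`, `y`, `z` (angstrom),
#'   `occ`, `b`, `element`.
#' @param id character identifier for the structure.
#'
#' @return An object of class `Structure`: a list with elements `id` and
#'   `atoms` (the validated atom table).
#'
#' @details Residue identity is the triple (chain, residue number +
#'   insertion code, residue name), kept in author (PDB) numbering
#'   throughout; profiles produced downstream are indexed on exactly this
#'   key. Coordinates must be finite and elements non-empty.
#'
#' @examples
#' s <- Structure(data.frame(
#'   type = "ATOM", serial = 1:2, name = c("CA", "CB"), resn = "ALA",
#'   chain = "A", resno = 1, insert = "", x = c(0, 1.5), y = 0, z = 0,
#'   occ = 1, b = 0, element = "C"))
#' n_atoms(s)
#' residue_table(s)
#' @export
Structure <- function(atoms, id = "structure") {
  required <- c("type", "serial", "name", "resn", "chain", "resno",
                "insert", "x", "y", "z", "occ", "b", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, required]
  if (nrow(atoms) == 0L) stop("a Structure must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol on atom serial ",
         atoms$serial[which(!nzchar(atoms$element))[1]])
  rownames(atoms) <- NULL
  structure(list(id = as.character(id), atoms = atoms), class = "Structure")
}

#' Number of atoms in a Structure
#' @param x a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "Structure"))
  nrow(x$atoms)
}

#' Atom coordinates as a matrix
#' @param x a `Structure`.
#' @return numeric matrix, one row per atom, columns x/y/z (angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "Structure"))
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param x a `Structure`.
#' @param value numeric n_atoms x 3 matrix.
#' @return the modified `Structure`.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "Structure"))
  value <- as.matrix(value)
  if (!all(dim(value) == c(nrow(x$atoms), 3L)))
    stop("replacement coordinates must be n_atoms x 3")
  if (!all(is.finite(value))) stop("non-finite atom coordinates")
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

# residue key strings in atom order (one entry per atom)
atom_residue_keys <- function(x) {
  a <- x$atoms
  paste0(a$chain, ":", a$resno, a$insert, ":", a$resn)
}

#' Residue table of a Structure
#'
#' @param x a `Structure`.
#' @return data frame with one row per residue, in order of first
#'   appearance in the atom table (file order): columns `key`
#'   ("chain:resno(insert):resn"), `chain`, `resno`, `insert`, `resn`,
#'   `n_atoms`.
#' @export
residue_table <- function(x) {
  stopifnot(inherits(x, "Structure"))
  keys <- atom_residue_keys(x)
  first <- !duplicated(keys)
  a <- x$atoms[first, c("chain", "resno", "insert", "resn")]
  data.frame(key = keys[first], a,
             n_atoms = as.integer(table(keys)[keys[first]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure '", x$id, "': ", nrow(x$atoms), " atoms, ",
      nrow(rt), " residues, chains ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Select atoms of a Structure
#'
#' Resolves a simple selection (chain, residue-number range, atom name,
#' element, record type) to atom indices.
#'
#' @param x a `Structure`.
#' @param chain optional chain identifier(s).
#' @param resno optional residue numbers (vector; ranges via `a:b`).
#' @param elety optional atom name(s) (e.g. "CA").
#' @param element optional element symbol(s).
#' @param het logical or NA: TRUE restricts to HETATM records, FALSE to
#'   ATOM records, NA (default) keeps both.
#' @return integer vector of atom indices (possibly empty).
#' @examples
#' s <- make_receptor(generator_config(seed = 1))
#' length(atom_select(s, resno = 84:127))
#' @export
atom_select <- function(x, chain = NULL, resno = NULL, elety = NULL,
                        element = NULL, het = NA) {
  stopifnot(inherits(x, "Structure"))
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$name %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.na(het)) keep <- keep & (a$type == if (het) "HETATM" else "ATOM")
  which(keep)
}

#' Extract a sub-Structure by atom indices
#' @param x a `Structure`.
#' @param indices integer atom indices (in file order).
#' @param id identifier for the new structure.
#' @return a `Structure` containing the selected atoms.
#' @export
subset_structure <- function(x, indices, id = x$id) {
  stopifnot(inherits(x, "Structure"))
  if (length(indices) == 0L) stop("empty selection")
  Structure(x$atoms[sort(unique(indices)), , drop = FALSE], id = id)
}

#' Merge two Structures into one complex
#'
#' Concatenates atom tables (receptor first), renumbering serials.
#' @param a,b `Structure` objects.
#' @param id identifier for the complex.
#' @return a `Structure`; atoms of `a` precede atoms of `b`.
#' @export
merge_structures <- function(a, b, id = paste0(a$id, "+", b$id)) {
  at <- rbind(a$atoms, b$atoms)
  at$serial <- seq_len(nrow(at))
  Structure(at, id = id)
}

#' Trajectory container
#'
#' Ordered coordinate frames of a fixed-topology molecular system, as
#' recorded e.g. every few picoseconds by a molecular dynamics engine.
#'
#' @param topology a `Structure` giving atom identities (frame 1 ordering).
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   bio3d order (x1,y1,z1,x2,...), angstrom.
#' @param frame_interval time between frames, picoseconds (metadata).
#' @return an object of class `Trajectory`.
#' @export
Trajectory <- function(topology, xyz, frame_interval = 4.8) {
  stopifnot(inherits(topology, "Structure"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("frame width (", ncol(xyz) / 3, " atoms) does not match topology (",
         n_atoms(topology), " atoms)")
  if (nrow(xyz) < 1L) stop("a Trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval = as.numeric(frame_interval)),
            class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param x a `Trajectory`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "Trajectory"))
  nrow(x$xyz)
}

#' Coordinates of one trajectory frame
#' @param x a `Trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 coordinate matrix.
#' @export
frame_coords <- function(x, i) {
  stopifnot(inherits(x, "Trajectory"))
  if (i < 1 || i > nrow(x$xyz)) stop("frame index out of range: ", i)
  matrix(x$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Frame times of a Trajectory
#' @param x a `Trajectory`.
#' @return numeric vector of times in ps, starting at 0.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "Trajectory"))
  (seq_len(nrow(x$xyz)) - 1) * x$frame_interval
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory: ", n_frames(x), " frames x ", n_atoms(x$topology),
      " atoms, interval ", x$frame_interval, " ps (",
      round(max(frame_times(x)), 2), " ps total)\n", sep = "")
  invisible(x)
}

#' Extract one trajectory frame as a Structure
#'
#' Useful for cross-checking trajectory statistics against the pose-based
#' profiling functions on identical coordinates.
#' @param x a `Trajectory`.
#' @param i frame index.
#' @param id identifier for the resulting structure.
#' @return a `Structure` with the topology's atoms at frame `i` positions.
#' @export
frame_structure <- function(x, i, id = paste0(x$topology$id, "_f", i)) {
  s <- x$topology
  coords(s) <- frame_coords(x, i)
  s$id <- id
  s
}
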