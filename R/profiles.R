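# Per-residue interaction profiling of docking pose ensembles: the
# count-of-contacts fingerprint, its energy-weighted variant, differential
# (test minus negative-control) profiles, residue ranking and
# entrance-window enrichment.

#' Docking pose ensemble
#'
#' Bundles a receptor with the ligand poses retained from a rigid-docking
#' run (e.g. the lowest-energy solutions of each ligand conformation) and,
#' optionally, one interaction energy per pose (arbitrary units, more
#' negative = more favourable).
#'
#' @param receptor a [Structure()].
#' @param poses list of [Structure()] objects (ligand only), all sharing
#'   one topology (same atoms in the same order).
#' @param energies optional numeric vector, one energy per pose.
#' @param label ensemble label (e.g. "glycosylated", "unmodified").
#' @return an object of class `PoseEnsemble`.
#' @export
PoseEnsemble <- function(receptor, poses, energies = NULL,
                         label = "ensemble") {
  stopifnot(inherits(receptor, "Structure"), is.list(poses))
  if (length(poses) < 1L) stop("a PoseEnsemble needs at least one pose")
  ok <- vapply(poses, inherits, logical(1), what = "Structure")
  if (!all(ok)) stop("pose ", which(!ok)[1L], " is not a Structure")
  if (!is.null(energies) && length(energies) != length(poses))
    stop("energies (", length(energies), ") and poses (", length(poses),
         ") differ in length")
  structure(list(receptor = receptor, poses = poses,
                 energies = if (is.null(energies)) NULL else
                   as.numeric(energies),
                 label = as.character(label)),
            class = "PoseEnsemble")
}

#' @export
print.PoseEnsemble <- function(x, ...) {
  cat("PoseEnsemble '", x$label, "': ", length(x$poses), " poses vs ",
      nrow(residue_table(x$receptor)), "-residue receptor '",
      x$receptor$id, "'",
      if (!is.null(x$energies)) " (with energies)", "\n", sep = "")
  invisible(x)
}

#' Read a pose ensemble from multi-model PDB files
#'
#' Each file contributes its MODELs as poses, in file then MODEL order —
#' e.g. 20 files of 20 saved solutions each yield a 400-pose ensemble.
#'
#' @param paths character vector of multi-model (or single) PDB files.
#' @param receptor the receptor [Structure()].
#' @param energies optional: numeric vector (one per pose, in pose order)
#'   or the path of an energy table TSV (columns `pose_id`, `energy`).
#' @param label ensemble label.
#' @return a [PoseEnsemble()].
#' @export
read_pose_ensemble <- function(paths, receptor, energies = NULL,
                               label = "ensemble") {
  poses <- list()
  for (p in paths) {
    tr <- read_trajectory(p)
    for (i in seq_len(n_frames(tr)))
      poses[[length(poses) + 1L]] <-
        frame_structure(tr, i, id = paste0(basename(p), "#", i))
  }
  if (is.character(energies) && length(energies) == 1L)
    energies <- read_energy_table(energies)$energy
  PoseEnsemble(receptor, poses, energies = energies, label = label)
}

#' Write a pose ensemble as a multi-model PDB file
#'
#' One MODEL per pose, in ensemble order; the companion energy table, if
#' present, is written next to it when `energy_path` is given.
#'
#' @param ensemble a [PoseEnsemble()].
#' @param path output PDB path.
#' @param energy_path optional TSV path for the per-pose energies.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path, energy_path = NULL) {
  stopifnot(inherits(ensemble, "PoseEnsemble"))
  xyz <- do.call(rbind, lapply(ensemble$poses, function(p)
    as.vector(t(coords(p)))))
  write_trajectory(Trajectory(ensemble$poses[[1L]], xyz), path)
  if (!is.null(energy_path) && !is.null(ensemble$energies))
    write_energy_table(ensemble$energies, energy_path)
  invisible(path)
}

#' Read / write a per-pose energy table
#'
#' TSV with columns `pose_id` and `energy` (arbitrary docking-score
#' units; more negative = more favourable).
#'
#' @param path TSV file path.
#' @return `read_energy_table`: data frame with columns `pose_id`,
#'   `energy`.
#' @export
read_energy_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pose_id", "energy") %in% names(d)))
    stop("energy table must have columns pose_id, energy")
  d
}

#' @rdname read_energy_table
#' @param energies numeric vector of per-pose energies.
#' @param pose_id optional pose identifiers (default 1..n).
#' @export
write_energy_table <- function(energies, path,
                               pose_id = seq_along(energies)) {
  utils::write.table(data.frame(pose_id = pose_id, energy = energies),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- moiety labelling ------------------------------------------------

#' Named ligand-atom subsets (moiety labelling)
#'
#' A moiety labelling maps moiety names (e.g. "glucosamine",
#' "carboxylate") to sets of ligand atoms, identified by chain, residue
#' number and atom name against the reference ligand topology shared by
#' all poses. Each residue within a moiety is one "unit" (e.g. one
#' glucosamine) for engaged-unit counting. An optional `role` column
#' ("donor"/"acceptor"/"") declares hydrogen-bonding roles.
#'
#' @param df data frame with columns `moiety`, `chain`, `resno`, `atom`
#'   and optionally `role`.
#' @return an object of class `MoietyLabeling` (a validated data frame).
#' @export
moiety_labeling <- function(df) {
  need <- c("moiety", "chain", "resno", "atom")
  if (!all(need %in% names(df)))
    stop("moiety labelling needs columns ", paste(need, collapse = ", "))
  if (is.null(df$role)) df$role <- ""
  df <- as.data.frame(df)[, c(need, "role")]
  df$resno <- as.integer(df$resno)
  class(df) <- c("MoietyLabeling", "data.frame")
  df
}

#' @rdname moiety_labeling
#' @param path TSV path; columns `moiety`, `resi_key` ("chain:resno"),
#'   `atom_name`, `role`.
#' @export
read_moiety_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("moiety", "resi_key", "atom_name") %in% names(d)))
    stop("moiety table must have columns moiety, resi_key, atom_name")
  parts <- strsplit(d$resi_key, ":", fixed = TRUE)
  moiety_labeling(data.frame(
    moiety = d$moiety,
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    atom = d$atom_name,
    role = if (is.null(d$role)) "" else d$role,
    stringsAsFactors = FALSE))
}

#' @rdname moiety_labeling
#' @param labeling a `MoietyLabeling`.
#' @export
write_moiety_table <- function(labeling, path) {
  utils::write.table(
    data.frame(moiety = labeling$moiety,
               resi_key = paste0(labeling$chain, ":", labeling$resno),
               atom_name = labeling$atom, role = labeling$role),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve a moiety to atom indices of a structure
#'
#' @param labeling a [moiety_labeling()].
#' @param x the ligand [Structure()] (reference topology).
#' @param name moiety name to resolve.
#' @return integer vector of atom indices into `x`, with a `units`
#'   attribute giving the moiety-unit (residue) id of each atom.
#' @export
resolve_moiety <- function(labeling, x, name) {
  stopifnot(inherits(labeling, "MoietyLabeling"), inherits(x, "Structure"))
  rows <- labeling[labeling$moiety == name, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("moiety '", name, "' not present in the labelling")
  a <- x$atoms
  akey <- paste(a$chain, a$resno, a$name, sep = ":")
  rkey <- paste(rows$chain, rows$resno, rows$atom, sep = ":")
  idx <- match(rkey, akey)
  if (anyNA(idx))
    stop("moiety atom '", rkey[which(is.na(idx))[1L]],
         "' does not resolve in structure '", x$id, "'")
  structure(idx, units = paste(rows$chain, rows$resno, sep = ":"))
}

# ---- profiles --------------------------------------------------------

# profile constructor: zero-filled track over the receptor's residues
new_profile <- function(receptor, values, cutoff, contact_mode, count_mode,
                        weighting = "none", label = "", pose_count = 1L,
                        differential = FALSE) {
  rt <- residue_table(receptor)
  stopifnot(length(values) == nrow(rt))
  p <- data.frame(key = rt$key, chain = rt$chain, resno = rt$resno,
                  insert = rt$insert, resn = rt$resn,
                  value = as.numeric(values), stringsAsFactors = FALSE)
  attr(p, "receptor_id") <- receptor$id
  attr(p, "cutoff") <- cutoff
  attr(p, "contact_mode") <- contact_mode
  attr(p, "count_mode") <- count_mode
  attr(p, "weighting") <- weighting
  attr(p, "label") <- label
  attr(p, "pose_count") <- as.integer(pose_count)
  attr(p, "differential") <- differential
  class(p) <- c("ResidueProfile", "data.frame")
  p
}

profile_meta <- function(p)
  attributes(p)[c("receptor_id", "cutoff", "contact_mode", "count_mode",
                  "weighting", "label", "pose_count", "differential")]

#' @export
print.ResidueProfile <- function(x, ...) {
  cat("ResidueProfile '", attr(x, "label"), "' over ", nrow(x),
      " residues of '", attr(x, "receptor_id"), "'\n",
      "  cutoff ", attr(x, "cutoff"), " A (", attr(x, "contact_mode"),
      "), ", attr(x, "count_mode"), " counts, weighting ",
      attr(x, "weighting"), ", ", attr(x, "pose_count"), " pose(s)",
      if (isTRUE(attr(x, "differential"))) ", differential", "\n",
      "  total ", signif(sum(x$value), 6), ", nonzero residues ",
      sum(x$value != 0), "\n", sep = "")
  invisible(x)
}

# shared precomputation for repeated counting against one receptor
receptor_index <- function(receptor) {
  rt <- residue_table(receptor)
  list(xyz = coords(receptor),
       radii = suppressWarnings(vdw_radii(receptor$atoms$element)),
       res_of_atom = match(atom_residue_keys(receptor), rt$key),
       n_res = nrow(rt))
}

# per-residue contact counts of one pose against a precomputed receptor
# index; returns a numeric vector of length n_res
pose_residue_counts <- function(rix, pose, cutoff, surface, count_mode,
                                moiety = NULL) {
  lig_idx <- if (is.null(moiety)) seq_len(n_atoms(pose)) else moiety
  if (length(lig_idx) == 0L) stop("empty ligand atom selection")
  B <- coords(pose)[lig_idx, , drop = FALSE]
  rb <- if (surface)
    suppressWarnings(vdw_radii(pose$atoms$element[lig_idx])) else NULL
  pr <- contact_pairs(rix$xyz, B, cutoff, surface = surface,
                      ra = rix$radii, rb = rb)
  counts <- numeric(rix$n_res)
  if (nrow(pr) == 0L) return(counts)
  res <- rix$res_of_atom[pr[, "i"]]
  if (count_mode == "atom") {
    keep <- !duplicated(paste(res, pr[, "j"]))
    res <- res[keep]
  }
  tab <- tabulate(res, nbins = rix$n_res)
  counts + tab
}

#' Per-residue contact counts between a ligand pose and a receptor
#'
#' The core interaction fingerprint: for each receptor residue, the
#' number of (ligand atom, receptor atom) pairs at distance strictly
#' below `cutoff`. In `count_mode = "atom"` each distinct ligand atom is
#' counted at most once per residue instead.
#'
#' @param receptor receptor [Structure()].
#' @param pose ligand pose [Structure()].
#' @param cutoff contact distance cutoff, angstrom (strict `<`).
#' @param moiety optional integer vector of ligand atom indices (see
#'   [resolve_moiety()]) restricting which ligand atoms may count.
#' @param count_mode `"pair"` (default; every atom pair counts once) or
#'   `"atom"` (distinct ligand atoms per residue).
#' @param contact_mode `"center"` (atom-centre distance), `"surface"`
#'   (vdW-gap distance: centre distance minus both radii), or `"auto"`
#'   (surface when `cutoff < 2`, else center; announced via a message).
#' @return a `ResidueProfile`: data frame with columns `key`, `chain`,
#'   `resno`, `insert`, `resn`, `value`, one row per receptor residue in
#'   sequence order (zero-filled), with the counting parameters stored as
#'   attributes.
#' @examples
#' cfg <- generator_config(seed = 7, n_poses = 4)
#' rec <- make_receptor(cfg)
#' lig <- make_ligand(cfg)
#' ens <- make_pose_ensemble(rec, lig$structure, lig$labeling, cfg)$ensemble
#' p <- count_contacts(rec, ens$poses[[1]], cutoff = 3)
#' sum(p$value)
#' @export
count_contacts <- function(receptor, pose, cutoff = 3, moiety = NULL,
                           count_mode = c("pair", "atom"),
                           contact_mode = c("auto", "center", "surface")) {
  stopifnot(inherits(receptor, "Structure"), inherits(pose, "Structure"),
            cutoff > 0)
  count_mode <- match.arg(count_mode)
  mode <- resolve_contact_mode(match.arg(contact_mode), cutoff)
  rix <- receptor_index(receptor)
  v <- pose_residue_counts(rix, pose, cutoff, mode == "surface",
                           count_mode, moiety)
  new_profile(receptor, v, cutoff, mode, count_mode,
              label = pose$id, pose_count = 1L)
}

#' Summed contact profile of a pose ensemble
#'
#' Elementwise sum of [count_contacts()] over all poses; the profile's
#' `pose_count` attribute records how many solutions were aggregated.
#'
#' @inheritParams count_contacts
#' @param ensemble a [PoseEnsemble()].
#' @return a `ResidueProfile` (see [count_contacts()]).
#' @export
ensemble_profile <- function(ensemble, cutoff = 3, moiety = NULL,
                             count_mode = c("pair", "atom"),
                             contact_mode = c("auto", "center", "surface")) {
  stopifnot(inherits(ensemble, "PoseEnsemble"), cutoff > 0)
  count_mode <- match.arg(count_mode)
  mode <- resolve_contact_mode(match.arg(contact_mode), cutoff)
  rix <- receptor_index(ensemble$receptor)
  v <- numeric(rix$n_res)
  for (k in seq_along(ensemble$poses)) {
    v <- v + tryCatch(
      pose_residue_counts(rix, ensemble$poses[[k]], cutoff,
                          mode == "surface", count_mode, moiety),
      error = function(e) stop("pose ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  new_profile(ensemble$receptor, v, cutoff, mode, count_mode,
              label = ensemble$label,
              pose_count = length(ensemble$poses))
}

#' Energy-weighted contact profile of a pose ensemble
#'
#' Each pose's per-residue counts are multiplied by that pose's
#' interaction energy before summing, so that favourable solutions
#' dominate the profile. With `weighting = "abs"` (default) the absolute
#' energy is used, making more-negative (stronger) energies produce
#' larger profile values; `"signed"` keeps the raw sign.
#'
#' @inheritParams ensemble_profile
#' @param weighting `"abs"` or `"signed"`.
#' @return a `ResidueProfile` with `weighting` recorded in its attributes.
#' @export
energy_weighted_profile <- function(ensemble, cutoff = 3, moiety = NULL,
                                    weighting = c("abs", "signed"),
                                    count_mode = c("pair", "atom"),
                                    contact_mode = c("auto", "center",
                                                     "surface")) {
  stopifnot(inherits(ensemble, "PoseEnsemble"), cutoff > 0)
  if (is.null(ensemble$energies))
    stop("ensemble '", ensemble$label, "' has no energies; supply a ",
         "per-pose energy table to weight the profile")
  weighting <- match.arg(weighting)
  count_mode <- match.arg(count_mode)
  mode <- resolve_contact_mode(match.arg(contact_mode), cutoff)
  rix <- receptor_index(ensemble$receptor)
  w <- if (weighting == "abs") abs(ensemble$energies) else ensemble$energies
  v <- numeric(rix$n_res)
  for (k in seq_along(ensemble$poses)) {
    v <- v + w[k] * tryCatch(
      pose_residue_counts(rix, ensemble$poses[[k]], cutoff,
                          mode == "surface", count_mode, moiety),
      error = function(e) stop("pose ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  new_profile(ensemble$receptor, v, cutoff, mode, count_mode,
              weighting = paste0(weighting, "_energy"),
              label = ensemble$label,
              pose_count = length(ensemble$poses))
}

#' Differential profile between two ensembles
#'
#' Elementwise `a - b`, isolating moiety-attributable binding when `b` is
#' the negative-control ligand's profile. Both profiles must be over the
#' same receptor with identical counting parameters.
#'
#' @param a,b `ResidueProfile` objects (e.g. test ligand and negative
#'   control).
#' @return a `ResidueProfile` flagged as differential; its label records
#'   both inputs as `"a - b"`.
#' @export
differential_profile <- function(a, b) {
  stopifnot(inherits(a, "ResidueProfile"), inherits(b, "ResidueProfile"))
  for (f in c("receptor_id", "cutoff", "contact_mode", "count_mode",
              "weighting")) {
    if (!identical(attr(a, f), attr(b, f)))
      stop("profiles differ in ", f, ": '", attr(a, f), "' vs '",
           attr(b, f), "'")
  }
  mism <- which(a$key != b$key)
  if (length(mism))
    stop("profiles differ in residue keys, first mismatch: '",
         a$key[mism[1L]], "' vs '", b$key[mism[1L]], "'")
  p <- new_profile_like(a, a$value - b$value)
  attr(p, "label") <- paste(attr(a, "label"), "-", attr(b, "label"))
  attr(p, "pose_count") <- attr(a, "pose_count") + attr(b, "pose_count")
  attr(p, "differential") <- TRUE
  p
}

# copy a profile's shape and meta with new values
new_profile_like <- function(p, values) {
  q <- p
  q$value <- as.numeric(values)
  q
}

#' Highest-value residues of a profile
#'
#' @param profile a `ResidueProfile`.
#' @param k number of residues to return (`k <=` number of residues).
#' @return data frame of the `k` residues with the largest values, ties
#'   broken by ascending residue number (then chain); deterministic.
#' @export
top_residues <- function(profile, k) {
  stopifnot(inherits(profile, "ResidueProfile"))
  if (k < 1 || k > nrow(profile))
    stop("k must be between 1 and the number of residues (", nrow(profile),
         ")")
  ord <- order(-profile$value, profile$chain, profile$resno)
  out <- profile[ord[seq_len(k)],
                 c("key", "chain", "resno", "resn", "value")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Fraction of profile mass inside a residue window
#'
#' The enrichment of contacts in a region of interest (e.g. the residues
#' lining the entrance of the receptor's binding pocket): the summed
#' profile values at residues whose number falls inside `window`, divided
#' by the total. For differential profiles only the positive part of each
#' value contributes, so the statistic reads "how much of the
#' test-specific excess lies in the window".
#'
#' @param profile a `ResidueProfile`.
#' @param window length-2 numeric `c(first, last)` residue numbers
#'   (inclusive), or an integer vector of residue numbers.
#' @return a single number in `[0, 1]`.
#' @export
window_enrichment <- function(profile, window) {
  stopifnot(inherits(profile, "ResidueProfile"))
  win <- if (length(window) == 2L) seq(window[1L], window[2L]) else window
  if (!any(profile$resno %in% win))
    stop("window contains no receptor residues")
  v <- profile$value
  if (isTRUE(attr(profile, "differential"))) v <- pmax(v, 0)
  tot <- sum(v)
  if (tot <= 0) stop("empty profile: total profile mass is zero")
  sum(v[profile$resno %in% win]) / tot
}

#' Write / read a residue profile as annotated TSV
#'
#' Tab-separated columns `chain`, `resi`, `resn`, `value` preceded by a
#' '#'-prefixed header block recording the counting parameters.
#'
#' @param profile a `ResidueProfile`.
#' @param path output TSV path.
#' @return `path` (write) or a reconstructed `ResidueProfile` (read),
#'   invisibly for the writer.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ResidueProfile"))
  m <- profile_meta(profile)
  hdr <- sprintf("# %s=%s", names(m),
                 vapply(m, function(x) as.character(x), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("chain\tresi\tresn\tvalue", con)
  writeLines(sprintf("%s\t%s\t%s\t%.10g", profile$chain,
                     paste0(profile$resno, profile$insert), profile$resn,
                     profile$value), con)
  invisible(path)
}

#' @rdname write_profile
#' @param receptor the receptor [Structure()] the profile was computed
#'   against (restores the residue key frame).
#' @export
read_profile <- function(path, receptor) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", hdr)
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  d <- utils::read.delim(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE,
                         colClasses = c(resi = "character"))
  rt <- residue_table(receptor)
  if (nrow(d) != nrow(rt))
    stop("profile rows (", nrow(d), ") do not match receptor residues (",
         nrow(rt), ")")
  new_profile(receptor, d$value,
              cutoff = as.numeric(meta[["cutoff"]]),
              contact_mode = meta[["contact_mode"]],
              count_mode = meta[["count_mode"]],
              weighting = meta[["weighting"]],
              label = meta[["label"]],
              pose_count = as.integer(meta[["pose_count"]]),
              differential = identical(meta[["differential"]], "TRUE"))
}

#' Bar plot of a residue profile
#'
#' @param x a `ResidueProfile`.
#' @param window optional residue-number window highlighted in grey.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ResidueProfile <- function(x, window = NULL, ...) {
  graphics::barplot(x$value, names.arg = x$resno, border = NA,
                    xlab = "residue", ylab = "profile value",
                    main = attr(x, "label"), ...)
  if (!is.null(window)) {
    win <- if (length(window) == 2L) seq(window[1], window[2]) else window
    graphics::rug(which(x$resno %in% win) * 1.2 - 0.5, col = "grey40")
  }
  invisible(x)
}
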