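# Seeded synthetic-data generators: a coarse receptor whose entrance
# window rings a concave pocket mouth, a branched dendrimer-like ligand
# with labelled glucosamine and carboxylate moieties, docking-pose
# ensembles with a planted binding interface, scripted approach
# trajectories and planted hydrogen-bond frames. Every generator draws
# from a single RNG stream seeded from the config, so outputs are
# byte-identical across runs.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study system: a 160-residue receptor whose
#' pocket-entrance window spans residues 84-127, a generation-3.5-like
#' branched ligand carrying 64 carboxylate branch terminals and 8
#' glucosamine units, pose ensembles in which planted solutions bind the
#' entrance window with more favourable energies, and a 4.8 ps-per-frame
#' approach trajectory.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param n_residues receptor length (default 160).
#' @param entrance_window `c(first, last)` residue numbers of the pocket
#'   entrance (default `c(84, 127)`).
#' @param n_glucosamine_units glucosamine moiety units on the ligand
#'   (default 8; 0 gives the unmodified negative-control ligand).
#' @param n_branch_terminals carboxylate branch terminals (default 64).
#' @param n_poses poses per generated ensemble (default 100).
#' @param planted_fraction fraction of poses planted at the entrance
#'   window (default 0.5).
#' @param enrichment_ratio target ratio of a planted pose's
#'   entrance-window contact-pair count to the mean background per-pose
#'   count (default 5).
#' @param energy_model list with numeric `planted = c(mean, sd)` and
#'   `background = c(mean, sd)` docking energies, arbitrary units, more
#'   negative = more favourable (defaults -8 +/- 1 and -4 +/- 1).
#' @param contact_cutoff cutoff (angstrom, centre distance) at which
#'   planting is calibrated (default 3).
#' @param trajectory_cutoff close-contact cutoff (angstrom, vdW-gap) the
#'   trajectory schedules are expressed against (default 1.3).
#' @param n_frames trajectory frames (default 100).
#' @param frame_interval trajectory frame spacing, ps (default 4.8).
#' @param approach_schedule optional non-increasing numeric vector
#'   (length `n_frames`) of ligand-receptor gaps, angstrom; default
#'   linear 20 to 0.
#' @param engaged_schedule optional integer vector (length `n_frames`)
#'   of glucosamine units engaged per frame; default steps 3 to 4 at
#'   half time, mirroring a binding rearrangement.
#' @param jitter standard deviation (angstrom) of per-frame coordinate
#'   noise on non-scripted ligand atoms (default 0: fully scripted).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, n_residues = 160,
                             entrance_window = c(84, 127),
                             n_glucosamine_units = 8,
                             n_branch_terminals = 64,
                             n_poses = 100, planted_fraction = 0.5,
                             enrichment_ratio = 5,
                             energy_model = list(planted = c(-8, 1),
                                                 background = c(-4, 1)),
                             contact_cutoff = 3,
                             trajectory_cutoff = 1.3,
                             n_frames = 100, frame_interval = 4.8,
                             approach_schedule = NULL,
                             engaged_schedule = NULL,
                             jitter = 0) {
  stopifnot(length(entrance_window) == 2L,
            entrance_window[1] >= 1,
            entrance_window[2] <= n_residues,
            entrance_window[1] <= entrance_window[2],
            n_residues >= diff(entrance_window) + 1,
            planted_fraction >= 0, planted_fraction <= 1,
            enrichment_ratio >= 1, n_poses >= 1,
            contact_cutoff > 0, trajectory_cutoff > 0,
            n_frames >= 1, frame_interval > 0, jitter >= 0,
            n_glucosamine_units >= 0, n_branch_terminals >= 0)
  if (planted_fraction > 0 && planted_fraction * n_poses < 1)
    stop("planting requested but planted_fraction * n_poses < 1")
  cfg <- list(seed = as.integer(seed), n_residues = as.integer(n_residues),
              entrance_window = as.integer(entrance_window),
              n_glucosamine_units = as.integer(n_glucosamine_units),
              n_branch_terminals = as.integer(n_branch_terminals),
              n_poses = as.integer(n_poses),
              planted_fraction = planted_fraction,
              enrichment_ratio = enrichment_ratio,
              energy_model = energy_model,
              contact_cutoff = contact_cutoff,
              trajectory_cutoff = trajectory_cutoff,
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              approach_schedule = approach_schedule,
              engaged_schedule = engaged_schedule,
              jitter = jitter)
  class(cfg) <- "generator_config"
  cfg
}

# ---- small geometry helpers -----------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

# robust tangential frame for a unit vector (any orientation, including
# the poles)
tangent_frame <- function(u) {
  e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- unit3(c(u[2] * e[3] - u[3] * e[2],
                u[3] * e[1] - u[1] * e[3],
                u[1] * e[2] - u[2] * e[1]))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {             # antiparallel: rotate about any axis
    ax <- if (abs(a[1]) < 0.9) unit3(c(a[2], -a[1], 0) + c(0, a[3], -a[2]))
          else unit3(c(-a[3], 0, a[1]))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# uniform random rotation matrix (quaternion method, uses current RNG)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

min_pair_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

n_pairs_within <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(d2 < cutoff^2)
}

# translate rotated ligand coordinates L along direction u so that the
# minimum centre-centre distance to ref equals target (angstrom);
# fixed-point iteration, deterministic. When `hard` (full receptor
# coordinates) is given the pose is additionally backed off so that no
# atom comes closer than `hard_floor` to any receptor atom: rigid poses
# rest on the surface instead of interpenetrating it.
place_rigid <- function(L, u, ref, target, hard = NULL, hard_floor = 0.8) {
  t <- max(ref %*% u) + target - min(L %*% u)
  for (i in 1:8) {
    P <- sweep(L, 2, t * u, "+")
    m <- min_pair_dist(P, ref)
    if (abs(m - target) < 1e-3) break
    t <- t + (target - m)
  }
  if (!is.null(hard)) {
    for (i in 1:10) {
      P <- sweep(L, 2, t * u, "+")
      m <- min_pair_dist(P, hard)
      if (m >= hard_floor - 1e-3) break
      t <- t + (hard_floor - m)
    }
  }
  sweep(L, 2, t * u, "+")
}

# ---- receptor --------------------------------------------------------

#' Generate a synthetic receptor with a pocket-entrance window
#'
#' Places `n_residues` coarse residues (4 pseudo-atoms each: N, CA, C, O)
#' at uniform surface density on a sphere zone whose empty polar cap is
#' the concave pocket mouth; the residues ringing the cap rim are the
#' entrance window and carry the window residue numbers. Deterministic
#' per seed.
#'
#' @param config a [generator_config()].
#' @return a [Structure()] (chain "A") with attributes
#'   `entrance_window` (residue-number range), `mouth_center` (the cap
#'   centre, on the sphere surface) and `mouth_axis` (unit vector).
#' @export
make_receptor <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_residues
  win <- seq(config$entrance_window[1], config$entrance_window[2])
  wlen <- length(win)
  R <- 25
  cap_cos <- cos(12 * pi / 180)      # empty polar cap = the pocket mouth
  n_wall <- 0L
  # uniform zone lattice: golden-angle start, then tangential repulsion
  # so residue spacing is even everywhere (a plain spiral clusters at
  # the zone ends, which would bias per-residue contact opportunity);
  # small seeded jitter keeps seeds distinguishable
  nz <- n - n_wall
  i <- seq_len(nz) - 0.5
  z <- cap_cos - i / nz * (cap_cos + 1)
  phi <- pi * (3 - sqrt(5)) * (seq_len(nz) - 1) + stats::rnorm(nz, 0, 0.05)
  z <- pmin(pmax(z + stats::rnorm(nz, 0, 0.01), -1), cap_cos)
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(phi), rho * sin(phi), z)
  d_rep <- sqrt(2 * (cap_cos + 1) / nz) * 1.2  # target spacing (unit sphere)
  for (it in 1:60) {
    d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * pts %*% t(pts)
    diag(d2) <- Inf
    shift <- matrix(0, nz, 3)
    close_ij <- which(d2 < d_rep^2, arr.ind = TRUE)
    if (nrow(close_ij) == 0L) break
    for (q in seq_len(nrow(close_ij))) {
      a <- close_ij[q, 1]; b <- close_ij[q, 2]
      dv <- pts[a, ] - pts[b, ]
      dn <- sqrt(sum(dv^2))
      shift[a, ] <- shift[a, ] + dv / max(dn, 1e-6) * (d_rep - dn) * 0.25
    }
    pts <- pts + shift
    pts <- pts / sqrt(rowSums(pts^2))
    pts[, 3] <- pmin(pts[, 3], cap_cos)
    pts <- pts / sqrt(rowSums(pts^2))
  }
  ord0 <- order(-pts[, 3])
  centers <- R * pts[ord0, , drop = FALSE]
  # residue numbering: the wlen residues nearest the rim (largest z, i.e.
  # the first rows) are the entrance window; the rest fill the remaining
  # author numbers in order
  resno <- integer(n)
  resno[seq_len(wlen)] <- win
  resno[(wlen + 1):n] <- setdiff(seq_len(n), win)
  names_pal <- c("N", "CA", "C", "O")
  elem_pal <- c("N", "C", "C", "O")
  resn_pal <- c("ALA", "SER", "LYS", "TYR", "ARG", "ASN", "GLY", "THR")
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    u <- unit3(centers[k, ])
    tf <- tangent_frame(u)
    t1 <- tf$t1; t2 <- tf$t2
    off <- rbind(0.9 * t1, c(0, 0, 0), 0.9 * t2, -0.9 * t1) +
      matrix(stats::rnorm(12, 0, 0.15), 4) +
      outer(c(0.2, 0, -0.2, 0.2), u)
    xyz <- sweep(off, 2, centers[k, ], "+")
    rows[[k]] <- data.frame(
      type = "ATOM", serial = 0L, name = names_pal,
      resn = resn_pal[(resno[k] - 1) %% length(resn_pal) + 1],
      chain = "A", resno = resno[k], insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = 0, element = elem_pal, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows[order(resno)])   # author-number order
  atoms$serial <- seq_len(nrow(atoms))
  s <- Structure(atoms, id = sprintf("synthetic_receptor_seed%d",
                                     config$seed))
  attr(s, "entrance_window") <- config$entrance_window
  attr(s, "mouth_center") <- c(0, 0, R)
  attr(s, "mouth_axis") <- c(0, 0, 1)
  s
}

# ---- ligand ----------------------------------------------------------

#' Generate a synthetic dendrimer-like ligand with moiety labels
#'
#' A star-topology pseudo-molecule: a core scaffold,
#' `n_branch_terminals` carboxylate terminals (residues `CBX`, atoms C,
#' O1, O2) on a 12-angstrom shell and `n_glucosamine_units` glucosamine
#' units (residues `GCS`, 8 atoms each) on a 13-angstrom shell. Atom
#' elements are real (C/N/O) so radius tables and hydrogen-bond roles
#' apply, but no covalent geometry is enforced: the analyses consume
#' only coordinates, elements and labels.
#'
#' @param config a [generator_config()].
#' @return list with `structure` (a [Structure()], chain "L", HETATM
#'   records) and `labeling` (a [moiety_labeling()] with moieties
#'   `glucosamine` - absent when `n_glucosamine_units = 0` - and
#'   `carboxylate`; glucosamine N atoms are donors, O atoms acceptors).
#' @export
make_ligand <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  rows <- list()
  lab <- list()
  add <- function(resno, resn, names, elems, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "HETATM", serial = 0L, name = names, resn = resn,
      chain = "L", resno = resno, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      element = elems, stringsAsFactors = FALSE)
  }
  # core scaffold: one residue, centre + 8 shell atoms
  core_dirs <- sphere_points(8)
  add(1L, "DEN", c("C1", paste0("C", 2:9)), rep("C", 9),
      rbind(c(0, 0, 0), 6 * core_dirs))
  # carboxylate terminals
  nt <- config$n_branch_terminals
  if (nt > 0) {
    dirs <- sphere_points(nt)
    # branch lengths vary: a dendrimer surface is bumpy, so a pose
    # touches the receptor through a few protruding tips rather than a
    # smooth shell
    tip_r <- stats::runif(nt, 7.5, 13)
    for (k in seq_len(nt)) {
      u <- dirs[k, ]
      t1 <- tangent_frame(u)$t1
      ctr <- tip_r[k] * u
      xyz <- rbind(ctr, ctr + 0.8 * t1 + 0.4 * u, ctr - 0.8 * t1 + 0.4 * u) +
        matrix(stats::rnorm(9, 0, 0.05), 3)
      add(100L + k, "CBX", c("C", "O1", "O2"), c("C", "O", "O"), xyz)
      lab[[length(lab) + 1L]] <- data.frame(
        moiety = "carboxylate", chain = "L", resno = 100L + k,
        atom = c("C", "O1", "O2"), role = c("", "acceptor", "acceptor"))
    }
  }
  # glucosamine units: 8 atoms each, tangential spread wide enough to
  # straddle neighbouring receptor residues when docked
  ng <- config$n_glucosamine_units
  if (ng > 0) {
    gd <- if (ng > 1) sphere_points(ng) else matrix(c(0, 0, 1), 1)
    gnames <- c("C1", "C2", "C3", "O3", "O4", "N2", "O6", "C6")
    gelems <- c("C", "C", "C", "O", "O", "N", "O", "C")
    groles <- c("", "", "", "acceptor", "acceptor", "donor", "acceptor", "")
    for (k in seq_len(ng)) {
      u <- gd[k, ]
      tf <- tangent_frame(u)
      t1 <- tf$t1; t2 <- tf$t2
      spread <- 1.5 * cbind(c(0, 1.8, -1.8, 2.6, -2.6, 0.9, -0.9, 0),
                            c(0, 0.9, -0.9, -1.3, 1.3, 2.4, -2.4, 1.6))
      ctr <- 14.5 * u              # longest branches: conjugated on tips
      xyz <- sweep(spread[, 1] %o% t1 + spread[, 2] %o% t2 +
                     outer(c(0.8, 0.3, 0.3, -0.2, -0.2, 0.5, 0.5, 1.0), u) +
                     matrix(stats::rnorm(24, 0, 0.05), 8),
                   2, ctr, "+")
      add(200L + k, "GCS", gnames, gelems, xyz)
      lab[[length(lab) + 1L]] <- data.frame(
        moiety = "glucosamine", chain = "L", resno = 200L + k,
        atom = gnames, role = groles)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  lig <- Structure(atoms, id = sprintf(
    "synthetic_ligand_%s_seed%d",
    if (ng > 0) "glycosylated" else "unmodified", config$seed))
  labeling <- moiety_labeling(do.call(rbind, lab))
  list(structure = lig, labeling = labeling)
}

# ---- pose ensemble ---------------------------------------------------

#' Generate a docking-pose ensemble with a planted binding interface
#'
#' Background poses touch a uniformly chosen receptor residue in a
#' random orientation (contact mass approximately uniform per residue);
#' planted poses dock a glucosamine unit onto a uniformly chosen
#' entrance-window residue, at a depth calibrated so each planted pose
#' makes at least `enrichment_ratio` times the mean background per-pose
#' contact-pair count inside the window (capped by geometry). Planted
#' poses draw more favourable energies. Fully seeded and reproducible.
#'
#' @param receptor a receptor from [make_receptor()].
#' @param ligand ligand [Structure()] from [make_ligand()].
#' @param labeling the ligand's [moiety_labeling()].
#' @param config a [generator_config()]; `n_poses`, `planted_fraction`,
#'   `enrichment_ratio`, `energy_model` and `contact_cutoff` apply.
#'   Planting requires a glucosamine moiety (use `planted_fraction = 0`
#'   for the unmodified control).
#' @param label ensemble label; default "glycosylated" when the ligand
#'   carries glucosamines, else "unmodified".
#' @return list with `ensemble` (a [PoseEnsemble()]) and `truth` (data
#'   frame `pose_id`, `planted`, `anchor_resno`, `energy`).
#' @export
make_pose_ensemble <- function(receptor, ligand, labeling, config,
                               label = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  has_glc <- "glucosamine" %in% labeling$moiety
  if (is.null(label)) label <- if (has_glc) "glycosylated" else "unmodified"
  n <- config$n_poses
  n_pl <- round(config$planted_fraction * n)
  if (n_pl > 0 && !has_glc)
    stop("planting requested but the ligand has no glucosamine moiety")
  planted <- rep(FALSE, n)
  if (n_pl > 0) planted[sample.int(n, n_pl)] <- TRUE
  rec_xyz <- coords(receptor)
  rt <- residue_table(receptor)
  res_keys <- atom_residue_keys(receptor)
  res_centers <- t(vapply(rt$key, function(k)
    colMeans(rec_xyz[res_keys == k, , drop = FALSE]), numeric(3)))
  win <- seq(config$entrance_window[1], config$entrance_window[2])
  win_rows <- which(rt$resno %in% win)
  win_atoms <- rec_xyz[res_keys %in% rt$key[win_rows], , drop = FALSE]
  L <- coords(ligand)
  Lc <- sweep(L, 2, colMeans(L))       # centred ligand
  glc_idx <- if (has_glc) as.integer(resolve_moiety(labeling, ligand,
                                                    "glucosamine"))
  glc_units <- if (has_glc) attr(resolve_moiety(labeling, ligand,
                                                "glucosamine"), "units")
  em <- config$energy_model
  energies <- ifelse(planted,
                     stats::rnorm(n, em$planted[1], em$planted[2]),
                     stats::rnorm(n, em$background[1], em$background[2]))
  anchor <- integer(n)
  poses <- vector("list", n)
  # background poses touch the receptor through a random carboxylate
  # branch terminal - the surface chemistry both ligands share - so the
  # non-specific contact process is identical for test and control
  # ensembles and cancels in the differential
  cbx_dirs <- NULL
  if ("carboxylate" %in% labeling$moiety) {
    ci <- resolve_moiety(labeling, ligand, "carboxylate")
    cu <- attr(ci, "units")
    cbx_dirs <- t(vapply(unique(cu), function(uu)
      unit3(colMeans(Lc[as.integer(ci)[cu == uu], , drop = FALSE])),
      numeric(3)))
  }
  spin_about <- function(dir, angle) {
    ax <- rotation_between(c(0, 0, 1), dir)
    ax %*% matrix(c(cos(angle), -sin(angle), 0,
                    sin(angle), cos(angle), 0, 0, 0, 1), 3,
                  byrow = TRUE) %*% t(ax)
  }
  # background placements first (their typical contact count calibrates
  # the planted depth); draws stay in pose order for reproducibility
  bg_pairs <- c()
  for (k in which(!planted)) {
    anchor[k] <- sample.int(nrow(rt), 1L)
    u <- unit3(res_centers[anchor[k], ])
    Q <- if (is.null(cbx_dirs)) random_rotation() else {
      tip <- cbx_dirs[sample.int(nrow(cbx_dirs), 1L), ]
      rotation_between(tip, -u) %*% spin_about(tip, stats::runif(1, 0,
                                                                 2 * pi))
    }
    ref <- rec_xyz[res_keys == rt$key[anchor[k]], , drop = FALSE]
    # standardize the non-specific contact intensity: approach until the
    # pose makes a small per-pose-drawn number of contacts with its
    # anchor residue, so test and control backgrounds share one
    # intensity distribution and cancel in the differential
    bg_target <- sample(2:4, 1L)
    Lr <- Lc %*% t(Q)
    P <- NULL
    for (gap in seq(2.8, 1.8, by = -0.2)) {
      P <- place_rigid(Lr, u, ref, gap, hard = rec_xyz)
      if (n_pairs_within(P, ref, config$contact_cutoff) >= bg_target)
        break
    }
    poses[[k]] <- P
    bg_pairs <- c(bg_pairs, n_pairs_within(P, ref, config$contact_cutoff))
  }
  b_bar <- if (length(bg_pairs)) max(1, mean(bg_pairs)) else 5
  target <- config$enrichment_ratio * b_bar
  unit_ids <- if (has_glc) unique(glc_units)
  # planted anchors cycle a shuffled permutation of the window, so the
  # planted truth covers the rim evenly (docking clusters line the rim
  # rather than piling onto one residue)
  win_cycle <- win_rows[sample.int(length(win_rows))]
  j_pl <- 0L
  mouth_axis <- attr(receptor, "mouth_axis")
  if (is.null(mouth_axis)) mouth_axis <- c(0, 0, 1)
  for (k in which(planted)) {
    j_pl <- j_pl + 1L
    anchor_row <- win_cycle[(j_pl - 1L) %% length(win_cycle) + 1L]
    anchor[k] <- anchor_row
    u <- unit3(res_centers[anchor_row, ])
    # approach over the pocket mouth: the ligand body overhangs the
    # empty opening while the chosen unit reaches its rim anchor
    u <- unit3(u + 0.45 * mouth_axis)
    uid <- unit_ids[sample.int(length(unit_ids), 1L)]
    gatoms <- glc_idx[glc_units == uid]
    gdir <- unit3(colMeans(Lc[gatoms, , drop = FALSE]))
    spin <- stats::runif(1, 0, 2 * pi)
    # spin about the unit direction, then point the unit at the anchor
    ax <- rotation_between(c(0, 0, 1), gdir)
    Sp <- ax %*% matrix(c(cos(spin), -sin(spin), 0,
                          sin(spin), cos(spin), 0, 0, 0, 1), 3,
                        byrow = TRUE) %*% t(ax)
    Q <- rotation_between(gdir, -u) %*% Sp
    Lr <- Lc %*% t(Q)
    ref <- rec_xyz[res_keys == rt$key[anchor_row], , drop = FALSE]
    chosen <- NULL
    reached <- FALSE
    for (gap in seq(2.6, 0.2, by = -0.2)) {
      P <- place_rigid(Lr, u, ref, gap, hard = rec_xyz, hard_floor = 0.6)
      chosen <- P
      if (n_pairs_within(P, ref, config$contact_cutoff) >= target) {
        reached <- TRUE
        break
      }
    }
    if (!reached) {
      # geometry saturated at touching distance: press the unit onto its
      # anchor in fixed steps until the target rate is met or depth runs
      # out
      for (push in seq(0.3, 3.0, by = 0.3)) {
        P <- sweep(chosen, 2, push * u)
        if (n_pairs_within(P, ref, config$contact_cutoff) >= target)
          break
      }
      chosen <- P
    }
    poses[[k]] <- chosen
  }
  pose_structs <- vector("list", n)
  for (k in seq_len(n)) {
    s <- ligand
    coords(s) <- poses[[k]]
    s$id <- sprintf("%s_pose%03d", label, k)
    pose_structs[[k]] <- s
  }
  truth <- data.frame(pose_id = seq_len(n), planted = planted,
                      anchor_resno = rt$resno[anchor], energy = energies)
  list(ensemble = PoseEnsemble(receptor, pose_structs, energies, label),
       truth = truth)
}

#' Write ensemble ground truth as a sidecar TSV
#' @param truth the `truth` element of [make_pose_ensemble()].
#' @param path output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- trajectory ------------------------------------------------------

#' Generate a scripted approach trajectory of the complex
#'
#' Frames move the ligand from distant to docked above the pocket mouth
#' following `approach_schedule` (minimum ligand-receptor centre
#' distance per frame), while the number of glucosamine units in close
#' contact with the entrance window follows `engaged_schedule` exactly:
#' engaged units are pinned at a fixed sub-cutoff vdW gap against their
#' target window residues, and the remaining units are kept clear of the
#' receptor. With `jitter = 0` the engaged-unit count per frame equals
#' the schedule by construction.
#'
#' @inheritParams make_pose_ensemble
#' @return list with `trajectory` (a [Trajectory()] of the complex,
#'   receptor atoms first), `truth` (data frame `frame`, `time_ps`,
#'   `gap`, `engaged`) and `selections` (list with `receptor` and
#'   `ligand` atom-index vectors into the topology).
#' @export
make_trajectory <- function(receptor, ligand, labeling, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 3L)
  nf <- config$n_frames
  gaps <- config$approach_schedule
  if (is.null(gaps)) gaps <- seq(20, 0, length.out = nf)
  if (length(gaps) != nf)
    stop("approach_schedule must have one gap per frame")
  if (any(diff(gaps) > 1e-9))
    stop("approach_schedule must be non-increasing")
  has_glc <- "glucosamine" %in% labeling$moiety
  eng <- config$engaged_schedule
  if (is.null(eng)) {
    eng <- if (has_glc)
      c(rep(3L, floor(nf / 2)), rep(4L, nf - floor(nf / 2)))
    else rep(0L, nf)
    eng <- pmin(eng, config$n_glucosamine_units)
  }
  if (length(eng) == 1L) eng <- rep(as.integer(eng), nf)
  if (length(eng) != nf)
    stop("engaged_schedule must have one value per frame")
  if (any(eng > config$n_glucosamine_units))
    stop("engaged_schedule exceeds the number of glucosamine units")
  rec_xyz <- coords(receptor)
  rt <- residue_table(receptor)
  res_keys <- atom_residue_keys(receptor)
  win <- seq(config$entrance_window[1], config$entrance_window[2])
  win_atoms_idx <- which(res_keys %in% rt$key[rt$resno %in% win])
  win_xyz <- rec_xyz[win_atoms_idx, , drop = FALSE]
  rec_radii <- suppressWarnings(vdw_radii(receptor$atoms$element))
  lig_radii <- suppressWarnings(vdw_radii(ligand$atoms$element))
  L <- coords(ligand)
  Lc <- sweep(L, 2, colMeans(L))
  axis <- c(0, 0, 1)
  # orient glucosamine unit 1 (if any) towards the receptor
  glc_idx <- integer(0); glc_units <- character(0)
  if (has_glc) {
    gi <- resolve_moiety(labeling, ligand, "glucosamine")
    glc_idx <- as.integer(gi); glc_units <- attr(gi, "units")
    g1 <- glc_idx[glc_units == unique(glc_units)[1]]
    Lc <- Lc %*% t(rotation_between(unit3(colMeans(Lc[g1, , drop = FALSE])),
                                    -axis))
  }
  unit_ids <- unique(glc_units)
  # fixed engagement sites: spread the units' target window residues
  # around the rim
  if (length(unit_ids)) {
    win_rows <- which(rt$resno %in% win)
    site_rows <- win_rows[round(seq(1, length(win_rows),
                                    length.out = length(unit_ids)))]
    site_xyz <- lapply(site_rows, function(r) {
      idx <- which(res_keys == rt$key[r])
      rec_xyz[idx, , drop = FALSE]
    })
    site_radii <- lapply(site_rows, function(r)
      rec_radii[which(res_keys == rt$key[r])])
  }
  # ligand altitude as a monotone function of requested gap, tabulated
  # once so the approach is monotone by construction
  t_grid <- seq(0, 60, by = 0.25)
  m_grid <- vapply(t_grid, function(t)
    min_pair_dist(sweep(Lc, 2, t * axis, "+"),
                  rbind(win_xyz, rec_xyz[seq(1, nrow(rec_xyz), by = 7), ,
                                         drop = FALSE])),
    numeric(1))
  m_grid <- cummax(m_grid)
  t_of_gap <- stats::approx(m_grid, t_grid, xout = pmax(gaps, min(m_grid)),
                            rule = 2, ties = "ordered")$y
  complex_atoms <- merge_structures(receptor, ligand,
                                    id = sprintf("synthetic_complex_seed%d",
                                                 config$seed))
  n_rec <- n_atoms(receptor)
  n_lig <- n_atoms(ligand)
  xyz <- matrix(NA_real_, nf, 3L * (n_rec + n_lig))
  for (f in seq_len(nf)) {
    P <- sweep(Lc, 2, t_of_gap[f] * axis, "+")
    if (config$jitter > 0)
      P <- P + matrix(stats::rnorm(length(P), 0, config$jitter),
                      nrow(P))
    if (length(unit_ids)) {
      k_eng <- eng[f]
      for (ju in seq_along(unit_ids)) {
        uatoms <- which(glc_units == unit_ids[ju])
        ui <- glc_idx[uatoms]
        if (ju <= k_eng) {
          # pin the unit at a fixed sub-cutoff vdW gap from its site:
          # first atom exactly at gap 0.4, the rest fanned out behind
          sx <- site_xyz[[ju]]; sr <- site_radii[[ju]]
          nrm <- unit3(colMeans(sx))
          a1 <- sx[1, ] + (sr[1] + lig_radii[ui[1]] + 0.4) * nrm
          P[ui, ] <- matrix(a1, length(ui), 3, byrow = TRUE) +
            outer((seq_along(ui) - 1) * 1.1, nrm)
        } else {
          # keep the unit clear: lift it along the axis until every atom
          # is at least 6 A (centre) from every receptor atom
          repeat {
            if (min_pair_dist(P[ui, , drop = FALSE], rec_xyz) >= 6) break
            P[ui, ] <- sweep(P[ui, , drop = FALSE], 2, 4 * axis, "+")
          }
        }
      }
    }
    xyz[f, ] <- as.vector(t(rbind(rec_xyz, P)))
  }
  traj <- Trajectory(complex_atoms, xyz,
                     frame_interval = config$frame_interval)
  truth <- data.frame(frame = seq_len(nf) - 1L,
                      time_ps = (seq_len(nf) - 1) * config$frame_interval,
                      gap = gaps, engaged = as.integer(eng))
  list(trajectory = traj, truth = truth,
       selections = list(receptor = seq_len(n_rec),
                         ligand = n_rec + seq_len(n_lig)))
}

# ---- planted hydrogen-bond frame ------------------------------------

#' Generate a frame with a known number of ideal hydrogen bonds
#'
#' Builds well-separated donor-hydrogen-acceptor triplets: `n_bonds`
#' with ideal geometry (collinear, donor-acceptor 2.9 angstrom) plus
#' `n_decoys` that satisfy the distance criterion but violate a
#' 120-degree angle criterion (60 degrees at the hydrogen), and
#' `n_far` pairs beyond any distance criterion. Groups are 10 angstrom
#' apart so no cross-group pair can count.
#'
#' @param n_bonds planted ideal-geometry bonds.
#' @param n_decoys angle-violating decoys.
#' @param n_far distance-violating decoys (donor-acceptor 5 angstrom).
#' @param seed RNG seed (orientation of each group).
#' @return list with `structure` (a [Structure()]), `donors`,
#'   `acceptors` (atom-index vectors) and `n_planted`.
#' @export
make_hbond_frame <- function(n_bonds = 4, n_decoys = 3, n_far = 2,
                             seed = 1) {
  set.seed(seed)
  total <- n_bonds + n_decoys + n_far
  rows <- list(); donors <- integer(0); acceptors <- integer(0)
  serial <- 0L
  for (g in seq_len(total)) {
    base <- c(10 * g, 0, 0)
    Q <- random_rotation()
    d <- base
    h <- base + Q %*% c(1, 0, 0)
    kind <- if (g <= n_bonds) "ideal"
            else if (g <= n_bonds + n_decoys) "angle" else "far"
    a <- switch(kind,
                ideal = base + Q %*% c(2.9, 0, 0),
                # 60 degrees at the hydrogen, donor-acceptor still < 3.5
                angle = base + Q %*% (c(1, 0, 0) +
                                        1.9 * c(-cos(pi / 3), sin(pi / 3),
                                                0)),
                far = base + Q %*% c(5, 0, 0))
    xyz <- rbind(as.vector(d), as.vector(h), as.vector(a))
    rows[[g]] <- data.frame(
      type = "HETATM", serial = serial + 1:3,
      name = c("OD", "HD", "OA"), resn = "HBX", chain = "X",
      resno = g, insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = 0, element = c("O", "H", "O"),
      stringsAsFactors = FALSE)
    donors <- c(donors, serial + 1L)
    acceptors <- c(acceptors, serial + 3L)
    serial <- serial + 3L
  }
  s <- Structure(do.call(rbind, rows), id = sprintf("hbond_frame_seed%d",
                                                    seed))
  list(structure = s, donors = donors, acceptors = acceptors,
       n_planted = as.integer(n_bonds))
}
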