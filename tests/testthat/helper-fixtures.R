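# Shared fixtures and independent oracles for the test suite.

# quick atom-table builder with sensible defaults
atoms_df <- function(x, y, z, name = NULL, element = "C", resno = 1L,
                     resn = "LIG", chain = "X", type = "HETATM") {
  n <- length(x)
  if (is.null(name)) name <- paste0("C", seq_len(n))
  data.frame(type = type, serial = seq_len(n), name = name, resn = resn,
             chain = chain, resno = resno, insert = "", x = x, y = y,
             z = z, occ = 1, b = 0, element = element,
             stringsAsFactors = FALSE)
}

tiny_structure <- function(x, y, z, ...) Structure(atoms_df(x, y, z, ...))

# random blob structure: n atoms spread in a box, several residues
random_structure <- function(n, seed, spread = 10, chain = "A",
                             type = "ATOM") {
  set.seed(seed)
  Structure(atoms_df(runif(n, 0, spread), runif(n, 0, spread),
                     runif(n, 0, spread),
                     element = sample(c("C", "N", "O", "S"), n, TRUE),
                     resno = rep(seq_len(max(1, n %/% 3)), each = 3,
                                 length.out = n),
                     resn = "RES", chain = chain, type = type))
}

# independent all-pairs brute-force per-residue contact oracle
oracle_profile <- function(receptor, pose, cutoff, surface = FALSE,
                           count_mode = "pair", moiety = NULL) {
  A <- coords(receptor)
  lig_idx <- if (is.null(moiety)) seq_len(n_atoms(pose)) else moiety
  B <- coords(pose)[lig_idx, , drop = FALSE]
  rt <- residue_table(receptor)
  keys <- paste0(receptor$atoms$chain, ":", receptor$atoms$resno,
                 receptor$atoms$insert, ":", receptor$atoms$resn)
  ra <- suppressWarnings(vdw_radii(receptor$atoms$element))
  rb <- suppressWarnings(vdw_radii(pose$atoms$element[lig_idx]))
  out <- stats::setNames(numeric(nrow(rt)), rt$key)
  if (count_mode == "pair") {
    for (i in seq_len(nrow(A))) {
      d <- sqrt(colSums((t(B) - A[i, ])^2))
      if (surface) d <- d - ra[i] - rb
      out[keys[i]] <- out[keys[i]] + sum(d < cutoff)
    }
  } else {
    for (k in rt$key) {
      touched <- logical(nrow(B))
      for (i in which(keys == k)) {
        d <- sqrt(colSums((t(B) - A[i, ])^2))
        if (surface) d <- d - ra[i] - rb
        touched <- touched | (d < cutoff)
      }
      out[k] <- sum(touched)
    }
  }
  unname(out)
}

# rigid rotation matrix from Euler-ish angles (deterministic)
rot3 <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}

transform_structure <- function(s, Q, shift) {
  coords(s) <- sweep(coords(s) %*% t(Q), 2, shift, "+")
  s
}

# analytic SASA of two overlapping equal/unequal spheres (solvent-expanded
# radii R1, R2, centre distance d): accessible area of each sphere loses a
# spherical cap
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

two_sphere_buried <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}

# small standard scenario shared across tests (kept small for speed)
default_scenario <- function(seed, n_poses = 30) {
  cfg <- generator_config(seed = seed, n_poses = n_poses)
  rec <- make_receptor(cfg)
  lig <- make_ligand(cfg)
  cfg0 <- generator_config(seed = seed, n_poses = n_poses,
                           planted_fraction = 0, n_glucosamine_units = 0)
  lig0 <- make_ligand(cfg0)
  list(cfg = cfg, cfg0 = cfg0, receptor = rec, lig = lig, lig0 = lig0)
}
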