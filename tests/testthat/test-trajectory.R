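# Time-resolved contact, hydrogen-bond and engaged-unit analysis.

test_that("frame contacts count inter-selection pairs under the cutoff", {
  topo <- Structure(atoms_df(c(0, 0.5, 50), 0, 0,
                             resn = c("R", "L", "L"),
                             chain = c("A", "L", "L"),
                             resno = c(1L, 2L, 3L)))
  expect_equal(frame_contacts(topo, ligand_sel = 2:3, receptor_sel = 1,
                              cutoff = 1.3, contact_mode = "center"), 1L)
  far <- Structure(atoms_df(c(0, 50), 0, 0, resn = c("R", "L"),
                            chain = c("A", "L"), resno = 1:2))
  expect_equal(frame_contacts(far, ligand_sel = 2, receptor_sel = 1,
                              cutoff = 1.3, contact_mode = "center"), 0L)
  expect_error(frame_contacts(topo, ligand_sel = integer(0),
                              receptor_sel = 1, cutoff = 1.3,
                              contact_mode = "center"),
               "empty selection")
  expect_error(frame_contacts(topo, ligand_sel = 1:2, receptor_sel = 1,
                              cutoff = 1.3, contact_mode = "center"),
               "overlap")
})

test_that("frame contacts match the all-pairs oracle on planted frames", {
  for (i in 1:10) {
    rec <- random_structure(80, seed = 900 + i)
    lig <- random_structure(40, seed = 950 + i, chain = "L",
                            type = "HETATM")
    topo <- merge_structures(rec, lig)
    got <- frame_contacts(topo, ligand_sel = 81:120, receptor_sel = 1:80,
                          cutoff = 2.5, contact_mode = "center")
    expect_equal(got, sum(oracle_profile(rec, lig, 2.5)))
  }
})

test_that("a distant ligand gives an all-zero series", {
  rec <- random_structure(30, seed = 61)
  lig <- random_structure(12, seed = 62, chain = "L", type = "HETATM")
  coords(lig) <- coords(lig) + 500
  topo <- merge_structures(rec, lig)
  xyz <- rbind(as.vector(t(coords(topo))), as.vector(t(coords(topo))))
  tr <- Trajectory(topo, xyz)
  cs <- suppressMessages(contact_series(tr, ligand_sel = 31:42,
                                        receptor_sel = 1:30,
                                        cutoff = 1.3, criteria = NULL))
  expect_equal(nrow(cs), 2L)
  expect_true(all(cs$contacts_all == 0))
})

test_that("approach trajectories give monotone per-frame oracle counts", {
  cfg <- generator_config(seed = 63, n_frames = 25)
  sc <- make_trajectory(make_receptor(cfg),
                        make_ligand(cfg)$structure,
                        make_ligand(cfg)$labeling, cfg)
  tr <- sc$trajectory
  cs <- suppressMessages(contact_series(
    tr, sc$selections$ligand, sc$selections$receptor, cutoff = 1.3,
    labeling = make_ligand(cfg)$labeling, criteria = NULL))
  expect_equal(nrow(cs), 25L)
  expect_true(all(diff(cs$contacts_all) >= 0))
  # per-frame equality with the pose-level counter on identical coords
  for (f in c(1, 13, 25)) {
    topo <- tr$topology
    got <- suppressMessages(frame_contacts(
      topo, frame_coords(tr, f), sc$selections$ligand,
      sc$selections$receptor, cutoff = 1.3, contact_mode = "surface"))
    expect_equal(cs$contacts_all[f], got)
  }
})

test_that("moiety contacts partition the whole-ligand count per frame", {
  cfg <- generator_config(seed = 64, n_frames = 8)
  lig <- make_ligand(cfg)
  sc <- make_trajectory(make_receptor(cfg), lig$structure,
                        lig$labeling, cfg)
  # extend the labelling so the moieties cover every ligand atom
  lig_atoms <- lig$structure$atoms
  covered <- paste(lig$labeling$chain, lig$labeling$resno,
                   lig$labeling$atom)
  rest <- lig_atoms[!paste(lig_atoms$chain, lig_atoms$resno,
                           lig_atoms$name) %in% covered, ]
  full <- moiety_labeling(rbind(
    as.data.frame(lig$labeling),
    data.frame(moiety = "scaffold", chain = rest$chain,
               resno = rest$resno, atom = rest$name, role = "")))
  cs <- suppressMessages(contact_series(
    sc$trajectory, sc$selections$ligand, sc$selections$receptor,
    cutoff = 1.3, labeling = full, criteria = NULL))
  expect_equal(cs$contacts_glucosamine + cs$contacts_carboxylate +
                 cs$contacts_scaffold, cs$contacts_all)
  expect_true(all(cs$contacts_glucosamine <= cs$contacts_all))
})

test_that("trajectory totals equal pose-profile totals on an exported frame", {
  cfg <- generator_config(seed = 65, n_frames = 6)
  lig <- make_ligand(cfg)
  sc <- make_trajectory(make_receptor(cfg), lig$structure,
                        lig$labeling, cfg)
  tr <- sc$trajectory
  f <- 6
  frame <- frame_structure(tr, f)
  rec_part <- subset_structure(frame, sc$selections$receptor)
  lig_part <- subset_structure(frame, sc$selections$ligand)
  prof <- count_contacts(rec_part, lig_part, cutoff = 1.3,
                         contact_mode = "surface")
  got <- frame_contacts(tr$topology, frame_coords(tr, f),
                        sc$selections$ligand, sc$selections$receptor,
                        cutoff = 1.3, contact_mode = "surface")
  expect_equal(sum(prof$value), got)
})

test_that("hydrogen bonds obey distance and angle criteria", {
  # collinear donor-H-acceptor at 2.9 A
  ideal <- Structure(atoms_df(c(0, 1, 2.9), 0, 0,
                              name = c("OD", "HD", "OA"),
                              element = c("O", "H", "O"),
                              resno = c(1L, 1L, 2L),
                              chain = c("D", "D", "A")))
  expect_equal(hydrogen_bonds(ideal, donors = 1, acceptors = 3,
                              criteria = hbond_criteria(3.5, 120)), 1L)
  # too far
  far <- Structure(atoms_df(c(0, 1, 5), 0, 0,
                            name = c("OD", "HD", "OA"),
                            element = c("O", "H", "O"),
                            resno = c(1L, 1L, 2L),
                            chain = c("D", "D", "A")))
  expect_equal(hydrogen_bonds(far, donors = 1, acceptors = 3), 0L)
  # good distance, bad angle (60 degrees at the hydrogen)
  a <- c(1, 0, 0) + 1.9 * c(-cos(pi / 3), sin(pi / 3), 0)
  bent <- Structure(atoms_df(c(0, 1, a[1]), c(0, 0, a[2]), c(0, 0, a[3]),
                             name = c("OD", "HD", "OA"),
                             element = c("O", "H", "O"),
                             resno = c(1L, 1L, 2L),
                             chain = c("D", "D", "A")))
  expect_equal(hydrogen_bonds(bent, donors = 1, acceptors = 3), 0L)
})

test_that("planted frames recover exactly the ideal-geometry bonds", {
  for (s in c(3, 17)) {
    hb <- make_hbond_frame(n_bonds = 5, n_decoys = 4, n_far = 3,
                           seed = s)
    expect_equal(hydrogen_bonds(hb$structure, donors = hb$donors,
                                acceptors = hb$acceptors),
                 hb$n_planted)
  }
})

test_that("hydrogen-less structures fall back to heavy-atom distance", {
  noh <- Structure(atoms_df(c(0, 3.0), 0, 0, name = c("OD", "OA"),
                            element = c("O", "O"), resno = 1:2,
                            chain = c("D", "A")))
  expect_error(hydrogen_bonds(noh, donors = 1, acceptors = 2,
                              mode = "angle"), "no hydrogens")
  expect_message(n <- hydrogen_bonds(noh, donors = 1, acceptors = 2),
                 "heavy-atom")
  expect_equal(n, 1L)
})

test_that("engaged units follow the scripted schedule exactly", {
  cfg <- generator_config(seed = 66, n_frames = 20, jitter = 0)
  lig <- make_ligand(cfg)
  sc <- make_trajectory(make_receptor(cfg), lig$structure,
                        lig$labeling, cfg)
  cs <- suppressMessages(contact_series(
    sc$trajectory, sc$selections$ligand, sc$selections$receptor,
    cutoff = 1.3, labeling = lig$labeling, criteria = NULL))
  expect_identical(cs$engaged_units, sc$truth$engaged)
  expect_identical(cs$engaged_units,
                   c(rep(3L, 10), rep(4L, 10)))
  expect_equal(attr(cs, "n_units"), 8L)
})

test_that("per-frame contacts are monotone in the cutoff", {
  cfg <- generator_config(seed = 67, n_frames = 5)
  lig <- make_ligand(cfg)
  sc <- make_trajectory(make_receptor(cfg), lig$structure,
                        lig$labeling, cfg)
  tr <- sc$trajectory
  for (ct in list(c(0.8, 1.3), c(1.3, 1.9))) {
    a <- suppressMessages(contact_series(tr, sc$selections$ligand,
                                         sc$selections$receptor,
                                         cutoff = ct[1],
                                         criteria = NULL))
    b <- suppressMessages(contact_series(tr, sc$selections$ligand,
                                         sc$selections$receptor,
                                         cutoff = ct[2],
                                         criteria = NULL))
    expect_true(all(b$contacts_all >= a$contacts_all))
  }
})
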