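# The seeded synthetic generators: determinism, configuration echo,
# planted ground truth and geometric structure.

test_that("generator configs validate their geometry", {
  expect_error(generator_config(entrance_window = c(84, 200)))
  expect_error(generator_config(planted_fraction = 1.5))
  expect_error(generator_config(n_poses = 10, planted_fraction = 0.01),
               "planted_fraction")
  cfg <- generator_config(seed = 5)
  expect_equal(cfg$n_residues, 160L)
  expect_equal(cfg$entrance_window, c(84L, 127L))
  expect_equal(cfg$n_glucosamine_units, 8L)
  expect_equal(cfg$n_branch_terminals, 64L)
})

test_that("receptors have the configured size and flagged window", {
  cfg <- generator_config(seed = 11)
  rec <- make_receptor(cfg)
  expect_equal(nrow(residue_table(rec)), 160L)
  expect_equal(attr(rec, "entrance_window"), c(84L, 127L))
  expect_equal(sort(unique(rec$atoms$resno)), 1:160)
})

test_that("the same seed reproduces byte-identical receptor files", {
  cfg <- generator_config(seed = 12)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structure(make_receptor(cfg), f1)
  write_structure(make_receptor(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    coords(make_receptor(generator_config(seed = 13))),
    coords(make_receptor(cfg))))
})

test_that("window residues ring the pocket mouth", {
  cfg <- generator_config(seed = 14)
  rec <- make_receptor(cfg)
  mouth <- attr(rec, "mouth_center")
  rt <- residue_table(rec)
  keys <- paste0(rec$atoms$chain, ":", rec$atoms$resno, ":",
                 rec$atoms$resn)
  centers <- t(vapply(rt$key, function(k)
    colMeans(coords(rec)[keys == k, , drop = FALSE]), numeric(3)))
  dmouth <- sqrt(colSums((t(centers) - mouth)^2))
  win <- rt$resno %in% 84:127
  expect_lt(mean(dmouth[win]), mean(dmouth[!win]))
  # every window residue is nearer the mouth than the median body residue
  expect_true(max(dmouth[win]) < stats::median(dmouth[!win]))
})

test_that("ligands carry the configured moiety inventory", {
  cfg <- generator_config(seed = 15)
  lig <- make_ligand(cfg)
  lab <- lig$labeling
  glc_units <- unique(lab$resno[lab$moiety == "glucosamine"])
  cbx_units <- unique(lab$resno[lab$moiety == "carboxylate"])
  expect_length(glc_units, 8L)
  expect_length(cbx_units, 64L)
  # moiety sets resolve and are disjoint
  gi <- resolve_moiety(lab, lig$structure, "glucosamine")
  ci <- resolve_moiety(lab, lig$structure, "carboxylate")
  expect_length(intersect(as.integer(gi), as.integer(ci)), 0L)
  # negative-control ligand has no glucosamine
  lig0 <- make_ligand(generator_config(seed = 15,
                                       n_glucosamine_units = 0))
  expect_false("glucosamine" %in% lig0$labeling$moiety)
  expect_error(resolve_moiety(lig0$labeling, lig0$structure,
                              "glucosamine"), "not present")
})

test_that("pose ensembles are reproducible and energy-ordered", {
  sc <- default_scenario(16, n_poses = 12)
  a <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                          sc$lig$labeling, sc$cfg)
  b <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                          sc$lig$labeling, sc$cfg)
  expect_identical(a$ensemble$energies, b$ensemble$energies)
  expect_identical(coords(a$ensemble$poses[[7]]),
                   coords(b$ensemble$poses[[7]]))
  tr <- a$truth
  expect_equal(nrow(tr), 12L)
  expect_equal(sum(tr$planted), 6L)
  # planted poses draw from the more favourable energy model
  expect_lt(mean(tr$energy[tr$planted]), mean(tr$energy[!tr$planted]))
  # planted anchors lie inside the entrance window
  expect_true(all(tr$anchor_resno[tr$planted] %in% 84:127))
})

test_that("planting without glucosamine is refused", {
  sc <- default_scenario(17)
  expect_error(make_pose_ensemble(sc$receptor, sc$lig0$structure,
                                  sc$lig0$labeling, sc$cfg),
               "glucosamine")
})

test_that("planted ensembles enrich the window; null ensembles do not", {
  enr_p <- enr_n <- numeric(0)
  for (s in 18:21) {
    sc <- default_scenario(s, n_poses = 40)
    pe <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                             sc$lig$labeling, sc$cfg)$ensemble
    pe0 <- make_pose_ensemble(sc$receptor, sc$lig0$structure,
                              sc$lig0$labeling, sc$cfg0)$ensemble
    enr_p <- c(enr_p, window_enrichment(
      ensemble_profile(pe, 3, contact_mode = "center"), c(84, 127)))
    enr_n <- c(enr_n, window_enrichment(
      ensemble_profile(pe0, 3, contact_mode = "center"), c(84, 127)))
  }
  expect_gt(mean(enr_p), mean(enr_n) + 0.3)
})

test_that("trajectories follow their schedules with zero jitter", {
  cfg <- generator_config(seed = 23, n_frames = 10, jitter = 0,
                          engaged_schedule = c(rep(2L, 4), rep(5L, 6)))
  lig <- make_ligand(cfg)
  sc <- make_trajectory(make_receptor(cfg), lig$structure,
                        lig$labeling, cfg)
  cs <- suppressMessages(contact_series(
    sc$trajectory, sc$selections$ligand, sc$selections$receptor,
    cutoff = 1.3, labeling = lig$labeling, criteria = NULL))
  expect_identical(cs$engaged_units, c(rep(2L, 4), rep(5L, 6)))
  expect_identical(sc$truth$engaged, c(rep(2L, 4), rep(5L, 6)))
})

test_that("trajectory schedules are validated", {
  cfg <- generator_config(seed = 24, n_frames = 5,
                          approach_schedule = c(1, 2, 3, 4, 5))
  lig <- make_ligand(cfg)
  expect_error(make_trajectory(make_receptor(cfg), lig$structure,
                               lig$labeling, cfg), "non-increasing")
  cfg2 <- generator_config(seed = 24, n_frames = 5,
                           engaged_schedule = rep(9L, 5))
  expect_error(make_trajectory(make_receptor(cfg2), lig$structure,
                               lig$labeling, cfg2),
               "exceeds the number of glucosamine units")
})

test_that("ground truth writes as a sidecar TSV", {
  sc <- default_scenario(25, n_poses = 8)
  out <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                            sc$lig$labeling, sc$cfg)
  f <- tempfile(fileext = ".tsv")
  write_truth_table(out$truth, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 8L)
  expect_equal(back$planted, out$truth$planted)
})

test_that("generated artefacts round-trip through the PDB layer", {
  cfg <- generator_config(seed = 26, n_poses = 5)
  rec <- make_receptor(cfg)
  lig <- make_ligand(cfg)
  pe <- make_pose_ensemble(rec, lig$structure, lig$labeling, cfg)
  f <- tempfile(fileext = ".pdb"); e <- tempfile(fileext = ".tsv")
  write_pose_ensemble(pe$ensemble, f, e)
  rec_f <- tempfile(fileext = ".pdb")
  write_structure(rec, rec_f)
  ens <- read_pose_ensemble(f, read_structure(rec_f), energies = e)
  expect_equal(length(ens$poses), 5L)
  expect_equal(ens$energies, pe$ensemble$energies, tolerance = 1e-6)
  expect_lt(max(abs(coords(ens$poses[[3]]) -
                      coords(pe$ensemble$poses[[3]]))), 0.001)
})
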