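# The per-residue interaction fingerprint: counting semantics, energy
# weighting, differentials, ranking and window enrichment.

test_that("a pose entirely beyond the cutoff yields an all-zero profile", {
  rec <- tiny_structure(c(0, 1), c(0, 0), c(0, 0), type = "ATOM",
                        chain = "A")
  pose <- tiny_structure(100, 100, 100)
  p <- count_contacts(rec, pose, cutoff = 3, contact_mode = "center")
  expect_true(all(p$value == 0))
})

test_that("a coincident ligand atom counts once for its residue", {
  rec <- Structure(atoms_df(c(0, 50), 0, 0, resno = c(5L, 6L),
                            chain = "A", type = "ATOM"))
  pose <- tiny_structure(0, 0, 0)
  p <- count_contacts(rec, pose, cutoff = 3, contact_mode = "center")
  expect_equal(p$value[p$resno == 5], 1)
  expect_equal(p$value[p$resno == 6], 0)
})

test_that("the cutoff boundary is strict", {
  rec <- tiny_structure(0, 0, 0, type = "ATOM", chain = "A")
  pose <- tiny_structure(3, 0, 0)
  expect_equal(sum(count_contacts(rec, pose, 3,
                                  contact_mode = "center")$value), 0)
  expect_equal(sum(count_contacts(rec, pose, 3 + 1e-9,
                                  contact_mode = "center")$value), 1)
})

test_that("cell-list counting matches the brute-force oracle exactly", {
  for (i in 1:100) {
    rec <- random_structure(sample(20:300, 1), seed = 1000 + i)
    pose <- random_structure(sample(10:200, 1), seed = 2000 + i,
                             chain = "L", type = "HETATM")
    cutoff <- runif(1, 1, 6)
    p <- count_contacts(rec, pose, cutoff, contact_mode = "center")
    expect_identical(p$value, oracle_profile(rec, pose, cutoff))
  }
})

test_that("surface-gap and distinct-atom modes also match the oracle", {
  for (i in 1:15) {
    rec <- random_structure(120, seed = 300 + i)
    pose <- random_structure(60, seed = 400 + i, chain = "L",
                             type = "HETATM")
    ps <- count_contacts(rec, pose, 1.3, contact_mode = "surface")
    expect_identical(ps$value, oracle_profile(rec, pose, 1.3,
                                              surface = TRUE))
    pa <- count_contacts(rec, pose, 3, count_mode = "atom",
                         contact_mode = "center")
    expect_identical(pa$value, oracle_profile(rec, pose, 3,
                                              count_mode = "atom"))
  }
})

test_that("ensemble profiles are the sum of per-pose oracle profiles", {
  sc <- default_scenario(31, n_poses = 20)
  pe <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                           sc$lig$labeling, sc$cfg)$ensemble
  p <- ensemble_profile(pe, 3, contact_mode = "center")
  expect_equal(attr(p, "pose_count"), 20L)
  acc <- numeric(nrow(p))
  for (pose in pe$poses)
    acc <- acc + oracle_profile(sc$receptor, pose, 3)
  expect_identical(p$value, acc)
  p1 <- count_contacts(sc$receptor, pe$poses[[1]], 3,
                       contact_mode = "center")
  e1 <- ensemble_profile(PoseEnsemble(sc$receptor, pe$poses[1]), 3,
                         contact_mode = "center")
  expect_identical(e1$value, p1$value)
})

test_that("reading 20 files of 20 models gives a 400-pose ensemble", {
  rec <- tiny_structure(c(0, 4), 0, 0, type = "ATOM", chain = "A")
  lig <- tiny_structure(c(10, 11, 12), 0, 0)
  dirn <- tempfile(); dir.create(dirn)
  paths <- character(20)
  for (f in 1:20) {
    xyz <- do.call(rbind, lapply(1:20, function(m)
      as.vector(t(coords(lig))) + m))
    paths[f] <- file.path(dirn, sprintf("conf%02d.pdb", f))
    write_trajectory(Trajectory(lig, xyz), paths[f])
  }
  ens <- read_pose_ensemble(paths, rec, label = "glycosylated")
  expect_equal(length(ens$poses), 400L)
  p <- ensemble_profile(ens, 3, contact_mode = "center")
  expect_equal(attr(p, "pose_count"), 400L)
})

test_that("energy weighting multiplies counts by per-pose energy", {
  rec <- Structure(atoms_df(c(0, 40), 0, 0, resno = c(1L, 2L),
                            chain = "A", type = "ATOM"))
  # pose 1 touches r1 once; pose 2 touches r1 twice and r2 once
  pose1 <- tiny_structure(0.5, 0, 0)
  pose2 <- tiny_structure(c(0.5, -0.5, 40.5), 0, 0)
  ens <- PoseEnsemble(rec, list(pose1, pose2), energies = c(-2, -3))
  w <- energy_weighted_profile(ens, 3, contact_mode = "center")
  expect_equal(w$value[w$resno == 1], 1 * 2 + 2 * 3)   # = 8
  expect_equal(w$value[w$resno == 2], 3)
  ens1 <- PoseEnsemble(rec, list(pose1, pose2), energies = c(1, 1))
  expect_identical(
    energy_weighted_profile(ens1, 3, contact_mode = "center")$value,
    ensemble_profile(ens1, 3, contact_mode = "center")$value)
  ens0 <- PoseEnsemble(rec, list(pose1, pose2), energies = c(0, 0))
  expect_true(all(energy_weighted_profile(
    ens0, 3, contact_mode = "center")$value == 0))
  ensna <- PoseEnsemble(rec, list(pose1, pose2))
  expect_error(energy_weighted_profile(ensna, 3,
                                       contact_mode = "center"),
               "energy table")
})

test_that("differential profiles subtract elementwise and antisymmetrically", {
  sc <- default_scenario(32, n_poses = 10)
  pe <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                           sc$lig$labeling, sc$cfg)$ensemble
  pe0 <- make_pose_ensemble(sc$receptor, sc$lig0$structure,
                            sc$lig0$labeling, sc$cfg0)$ensemble
  a <- ensemble_profile(pe, 3, contact_mode = "center")
  b <- ensemble_profile(pe0, 3, contact_mode = "center")
  expect_true(all(differential_profile(a, a)$value == 0))
  d1 <- differential_profile(a, b)
  d2 <- differential_profile(b, a)
  expect_identical(d1$value, -d2$value)
  expect_identical(d1$value, a$value - b$value)
  expect_true(attr(d1, "differential"))
})

test_that("differentials refuse mismatched counting parameters", {
  rec <- tiny_structure(0, 0, 0, type = "ATOM", chain = "A")
  pose <- tiny_structure(1, 0, 0)
  a <- count_contacts(rec, pose, 3, contact_mode = "center")
  b <- count_contacts(rec, pose, 4, contact_mode = "center")
  expect_error(differential_profile(a, b), "cutoff")
})

test_that("top_residues ranks by value with residue-number tie-break", {
  rec <- random_structure(30, seed = 77)
  pose <- tiny_structure(1000, 0, 0)
  zero <- count_contacts(rec, pose, 3, contact_mode = "center")
  t3 <- top_residues(zero, 3)
  expect_equal(t3$resno, sort(zero$resno)[1:3])
  one <- zero
  one$value[7] <- 5
  expect_equal(top_residues(one, 1)$key, one$key[7])
  expect_error(top_residues(zero, nrow(zero) + 1), "between 1")
})

test_that("window enrichment is the in-window mass fraction", {
  rec <- Structure(atoms_df(1:10, 0, 0, resno = 1:10, chain = "A",
                            type = "ATOM"))
  prof <- count_contacts(rec, tiny_structure(1000, 0, 0), 3,
                         contact_mode = "center")
  prof$value <- rep(1, 10)
  expect_equal(window_enrichment(prof, c(1, 10)), 1.0)
  prof$value <- c(3, rep(0, 4), 7, rep(0, 4))
  expect_equal(window_enrichment(prof, c(1, 3)), 0.3)
  prof$value <- rep(2, 10)
  expect_equal(window_enrichment(prof, c(4, 7)), 0.4)
  prof$value <- rep(0, 10)
  expect_error(window_enrichment(prof, c(1, 5)), "empty profile")
})

test_that("uniform profiles give enrichment = window fraction", {
  cfg <- generator_config(seed = 1)
  rec <- make_receptor(cfg)
  prof <- count_contacts(rec, tiny_structure(1000, 0, 0), 3,
                         contact_mode = "center")
  prof$value <- rep(1, nrow(prof))
  expect_equal(window_enrichment(prof, c(84, 127)), 44 / 160)
})

test_that("differential enrichment uses only the positive part", {
  rec <- Structure(atoms_df(1:4, 0, 0, resno = 1:4, chain = "A",
                            type = "ATOM"))
  base <- count_contacts(rec, tiny_structure(1000, 0, 0), 3,
                         contact_mode = "center")
  a <- base; a$value <- c(4, 0, 0, 0)
  b <- base; b$value <- c(0, 0, 6, 0)
  d <- differential_profile(a, b)       # values 4,0,-6,0
  expect_equal(window_enrichment(d, c(1, 2)), 1.0)
})

test_that("profile values are non-decreasing in the cutoff", {
  for (i in 1:10) {
    rec <- random_structure(100, seed = 500 + i)
    pose <- random_structure(50, seed = 600 + i, chain = "L",
                             type = "HETATM")
    cuts <- sort(runif(4, 0.5, 8))
    prev <- NULL
    for (ct in cuts) {
      p <- count_contacts(rec, pose, ct, contact_mode = "center")
      if (!is.null(prev)) expect_true(all(p$value >= prev))
      prev <- p$value
    }
  }
})

test_that("moiety restriction is subadditive and partitions sum", {
  sc <- default_scenario(33, n_poses = 6)
  pe <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                           sc$lig$labeling, sc$cfg)$ensemble
  lig <- sc$lig$structure
  glc <- resolve_moiety(sc$lig$labeling, lig, "glucosamine")
  cbx <- resolve_moiety(sc$lig$labeling, lig, "carboxylate")
  rest <- setdiff(seq_len(n_atoms(lig)), c(glc, cbx))
  whole <- ensemble_profile(pe, 3, contact_mode = "center")
  pg <- ensemble_profile(pe, 3, moiety = as.integer(glc),
                         contact_mode = "center")
  pc <- ensemble_profile(pe, 3, moiety = as.integer(cbx),
                         contact_mode = "center")
  pr <- ensemble_profile(pe, 3, moiety = rest, contact_mode = "center")
  expect_true(all(pg$value <= whole$value))
  expect_true(all(pc$value <= whole$value))
  expect_identical(pg$value + pc$value + pr$value, whole$value)
})

test_that("unresolvable moiety atoms are named in the error", {
  sc <- default_scenario(34)
  bad <- moiety_labeling(data.frame(moiety = "glucosamine", chain = "L",
                                    resno = 999L, atom = "ZZ",
                                    role = ""))
  expect_error(resolve_moiety(bad, sc$lig$structure, "glucosamine"),
               "L:999:ZZ")
  expect_error(resolve_moiety(sc$lig$labeling, sc$lig$structure,
                              "phosphate"), "not present")
})

test_that("profiles are invariant under rigid motion of the complex", {
  rec <- random_structure(100, seed = 91)
  pose <- random_structure(50, seed = 92, chain = "L", type = "HETATM")
  Q <- rot3(0.3, -1.1, 2.2)
  shift <- c(13.7, -4.2, 8.8)
  p0 <- count_contacts(rec, pose, 3, contact_mode = "center")
  p1 <- count_contacts(transform_structure(rec, Q, shift),
                       transform_structure(pose, Q, shift), 3,
                       contact_mode = "center")
  expect_identical(p0$value, p1$value)
})

test_that("profile TSVs round-trip values and metadata", {
  sc <- default_scenario(35, n_poses = 4)
  pe <- make_pose_ensemble(sc$receptor, sc$lig$structure,
                           sc$lig$labeling, sc$cfg)$ensemble
  p <- ensemble_profile(pe, 3, contact_mode = "center")
  f <- tempfile(fileext = ".tsv")
  write_profile(p, f)
  q <- read_profile(f, sc$receptor)
  expect_equal(q$value, p$value)
  expect_equal(attr(q, "cutoff"), attr(p, "cutoff"))
  expect_equal(attr(q, "label"), attr(p, "label"))
  expect_equal(attr(q, "pose_count"), attr(p, "pose_count"))
})
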