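# End-to-end orchestration: ingest two pose ensembles (test ligand and
# negative control), compute raw / energy-weighted / differential
# profiles, receptor SASA and the profile-vs-SASA selectivity table,
# rank residues, compute entrance-window enrichment, and run the
# trajectory contact analysis - emitting TSV tables plus a manifest.

#' Run configuration for the analysis pipelines
#'
#' @param receptor path of the receptor PDB.
#' @param ensemble_a,ensemble_b character vectors of pose PDB paths
#'   (multi-model files allowed) for the test ligand and the
#'   negative-control ligand.
#' @param energies_a,energies_b optional energy-table TSV paths.
#' @param label_a,label_b ensemble labels (defaults "glycosylated",
#'   "unmodified"); the differential is reported as `label_a - label_b`.
#' @param moiety_table optional moiety TSV path (see
#'   [read_moiety_table()]).
#' @param trajectory optional multi-model PDB path of the complex
#'   trajectory.
#' @param ligand_chain chain id of the ligand within the trajectory
#'   complex (default "L").
#' @param profile_cutoff contact cutoff for profiles, angstrom
#'   (default 3).
#' @param trajectory_cutoff close-contact cutoff for the trajectory,
#'   angstrom (default 1.3).
#' @param contact_mode,count_mode switches as in [count_contacts()].
#' @param entrance_window `c(first, last)` residue numbers (default
#'   `c(84, 127)`).
#' @param top_k residues to rank (default the window length).
#' @param hbond an [hbond_criteria()].
#' @param frame_interval trajectory frame spacing, ps.
#' @param area_stride compute the buried contact area on every
#'   `area_stride`-th frame (default 10; the area is the costly step).
#' @param area_points sphere points per atom for the trajectory
#'   contact-area series (default 240).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for any stochastic step.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(receptor, ensemble_a = NULL, ensemble_b = NULL,
                       energies_a = NULL, energies_b = NULL,
                       label_a = "glycosylated", label_b = "unmodified",
                       moiety_table = NULL, trajectory = NULL,
                       ligand_chain = "L",
                       profile_cutoff = 3, trajectory_cutoff = 1.3,
                       contact_mode = "auto", count_mode = "pair",
                       entrance_window = c(84, 127), top_k = NULL,
                       hbond = hbond_criteria(), frame_interval = 4.8,
                       area_stride = 10, area_points = 240,
                       out_dir = "contactprof_out", seed = 1) {
  paths <- c(receptor, ensemble_a, ensemble_b, energies_a, energies_b,
             moiety_table, trajectory)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  stopifnot(profile_cutoff > 0, trajectory_cutoff > 0,
            length(entrance_window) == 2L)
  if (is.null(top_k)) top_k <- diff(entrance_window) + 1
  cfg <- list(receptor = receptor, ensemble_a = ensemble_a,
              ensemble_b = ensemble_b, energies_a = energies_a,
              energies_b = energies_b, label_a = label_a,
              label_b = label_b, moiety_table = moiety_table,
              trajectory = trajectory, ligand_chain = ligand_chain,
              profile_cutoff = profile_cutoff,
              trajectory_cutoff = trajectory_cutoff,
              contact_mode = contact_mode, count_mode = count_mode,
              entrance_window = as.integer(entrance_window),
              top_k = as.integer(top_k), hbond = hbond,
              frame_interval = frame_interval,
              area_stride = as.integer(area_stride),
              area_points = as.integer(area_points),
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat keys matching the arguments of [run_config()]; entries given as
#' `...` override file values.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  if (!is.null(vals$hbond) && !inherits(vals$hbond, "HBondCriteria"))
    vals$hbond <- do.call(hbond_criteria, vals$hbond)
  do.call(run_config, vals)
}

log_stage <- function(...) message("[contactprof] ", ...)

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), marker)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_manifest <- function(out_dir, config_echo, extra = list()) {
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- c(list(
    package = "contactprof",
    version = as.character(utils::packageVersion("contactprof")),
    r_version = R.version.string,
    config = config_echo,
    checksums = as.list(tools::md5sum(files))), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_echo <- function(config)
  lapply(unclass(config), function(x) if (inherits(x, "HBondCriteria"))
    unclass(x) else x)

#' Run the profile pipeline
#'
#' Executes the ensemble analysis end to end: (1) ingest the receptor
#' and two pose ensembles, (2) compute raw and (when energies are
#' available) energy-weighted per-residue profiles, (3) compute the
#' differential profile `label_a - label_b`, (4) compute receptor SASA
#' and the selectivity table contrasting exposure with contact counts,
#' (5) rank residues and compute the entrance-window enrichment. All
#' tables are written under `config$out_dir` together with a manifest
#' recording the configuration and file checksums.
#'
#' @param config a [run_config()] with both ensembles set.
#' @return an object of class `ReportBundle`: list with the computed
#'   profiles, SASA, selectivity table, `top` ranking, `enrichment`,
#'   `processed_poses` and the output paths.
#' @export
run_profile_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ensemble_a) || is.null(config$ensemble_b))
    stop("both ensembles must be configured for the profile pipeline")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  set.seed(config$seed)
  od <- config$out_dir
  receptor <- run_stage("read_receptor", od,
                        read_structure(config$receptor))
  log_stage("receptor '", receptor$id, "': ", n_atoms(receptor),
            " atoms, ", nrow(residue_table(receptor)), " residues")
  ens_a <- run_stage("read_ensemble_a", od, read_pose_ensemble(
    config$ensemble_a, receptor, config$energies_a, config$label_a))
  ens_b <- run_stage("read_ensemble_b", od, read_pose_ensemble(
    config$ensemble_b, receptor, config$energies_b, config$label_b))
  processed <- length(ens_a$poses) + length(ens_b$poses)
  log_stage("ingested ", length(ens_a$poses), " + ", length(ens_b$poses),
            " = ", processed, " docking solutions")
  cutoff <- config$profile_cutoff
  log_stage("profiles at cutoff ", cutoff, " A, ", config$count_mode,
            " counts, contact mode ", config$contact_mode)
  prof_a <- run_stage("profile_a", od, suppressMessages(
    ensemble_profile(ens_a, cutoff, count_mode = config$count_mode,
                     contact_mode = config$contact_mode)))
  prof_b <- run_stage("profile_b", od, suppressMessages(
    ensemble_profile(ens_b, cutoff, count_mode = config$count_mode,
                     contact_mode = config$contact_mode)))
  write_profile(prof_a, file.path(od, "profile_a_raw.tsv"))
  write_profile(prof_b, file.path(od, "profile_b_raw.tsv"))
  wprof_a <- wprof_b <- wdiff <- NULL
  if (!is.null(ens_a$energies) && !is.null(ens_b$energies)) {
    wprof_a <- run_stage("weighted_profile_a", od, suppressMessages(
      energy_weighted_profile(ens_a, cutoff,
                              count_mode = config$count_mode,
                              contact_mode = config$contact_mode)))
    wprof_b <- run_stage("weighted_profile_b", od, suppressMessages(
      energy_weighted_profile(ens_b, cutoff,
                              count_mode = config$count_mode,
                              contact_mode = config$contact_mode)))
    write_profile(wprof_a, file.path(od, "profile_a_weighted.tsv"))
    write_profile(wprof_b, file.path(od, "profile_b_weighted.tsv"))
    wdiff <- differential_profile(wprof_a, wprof_b)
    write_profile(wdiff, file.path(od, "profile_diff_weighted.tsv"))
  }
  diff <- run_stage("differential", od,
                    differential_profile(prof_a, prof_b))
  write_profile(diff, file.path(od, "profile_diff_raw.tsv"))
  sasa <- run_stage("sasa", od, shrake_rupley(receptor))
  utils::write.table(sasa$per_residue, file.path(od, "sasa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # selectivity: residues contacted out of proportion to their exposure
  sel <- data.frame(prof_a[, c("key", "chain", "resno", "resn")],
                    sasa = sasa$per_residue$sasa,
                    contacts = prof_a$value,
                    weighted = if (is.null(wprof_a)) NA else
                      wprof_a$value)
  sel$sasa_rank <- rank(-sel$sasa, ties.method = "min")
  sel$contact_rank <- rank(-sel$contacts, ties.method = "min")
  sel$selective <- sel$contact_rank < sel$sasa_rank
  utils::write.table(sel, file.path(od, "selectivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rank_profile <- if (!is.null(wdiff)) wdiff else diff
  top <- run_stage("ranking", od, top_residues(rank_profile,
                                               config$top_k))
  utils::write.table(top, file.path(od, "top_residues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  enr <- if (sum(pmax(diff$value, 0)) == 0) {
    log_stage("differential has no positive mass; enrichment undefined")
    NA_real_
  } else {
    run_stage("enrichment", od,
              window_enrichment(diff, config$entrance_window))
  }
  log_stage("entrance-window [", config$entrance_window[1], "-",
            config$entrance_window[2], "] enrichment of differential: ",
            round(enr, 4))
  bundle <- list(receptor = receptor,
                 profiles = list(a = prof_a, b = prof_b,
                                 a_weighted = wprof_a,
                                 b_weighted = wprof_b),
                 differential = diff, differential_weighted = wdiff,
                 sasa = sasa, selectivity = sel, top = top,
                 enrichment = enr, processed_poses = processed,
                 out_dir = od)
  class(bundle) <- "ReportBundle"
  write_manifest(od, config_echo(config),
                 list(processed_poses = processed,
                      window_enrichment = enr))
  bundle
}

#' Run the trajectory pipeline
#'
#' Computes the per-frame contact series (whole-ligand, per-moiety,
#' hydrogen bonds, engaged units) and the buried contact-area series on
#' a frame stride, writing both as TSV plus a manifest.
#'
#' @param config a [run_config()] with `trajectory` set; the complex is
#'   split into ligand (`ligand_chain`) and receptor (all other chains).
#' @return a `ReportBundle` list with `series` (a `ContactSeries`),
#'   `area` (data frame `frame`, `time_ps`, `area_A2`) and output paths.
#' @export
run_trajectory_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$trajectory))
    stop("config$trajectory must be set for the trajectory pipeline")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  od <- config$out_dir
  traj <- run_stage("read_trajectory", od, read_trajectory(
    config$trajectory, frame_interval = config$frame_interval))
  topo <- traj$topology
  lig_sel <- atom_select(topo, chain = config$ligand_chain)
  rec_sel <- setdiff(seq_len(n_atoms(topo)), lig_sel)
  if (!length(lig_sel) || !length(rec_sel))
    stop("stage 'selections' failed: ligand chain '", config$ligand_chain,
         "' does not split the complex")
  labeling <- if (!is.null(config$moiety_table))
    run_stage("read_moieties", od, read_moiety_table(config$moiety_table))
  log_stage("trajectory: ", n_frames(traj), " frames, ligand ",
            length(lig_sel), " atoms, receptor ", length(rec_sel),
            " atoms, cutoff ", config$trajectory_cutoff, " A")
  series <- run_stage("contact_series", od, suppressMessages(
    contact_series(traj, lig_sel, rec_sel,
                   cutoff = config$trajectory_cutoff,
                   labeling = labeling, criteria = config$hbond,
                   count_mode = config$count_mode,
                   contact_mode = config$contact_mode)))
  write_contact_series(series, file.path(od, "contact_series.tsv"))
  frames <- seq(1, n_frames(traj), by = config$area_stride)
  log_stage("contact area on ", length(frames), " frames (stride ",
            config$area_stride, ", ", config$area_points,
            " sphere points)")
  area <- run_stage("contact_area", od, vapply(frames, function(f)
    contact_area(frame_structure(traj, f), rec_sel, lig_sel,
                 n_sphere_points = config$area_points), numeric(1)))
  area_df <- data.frame(frame = frames - 1L,
                        time_ps = (frames - 1) * traj$frame_interval,
                        area_A2 = area)
  utils::write.table(area_df, file.path(od, "contact_area.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bundle <- list(series = series, area = area_df, out_dir = od)
  class(bundle) <- "ReportBundle"
  write_manifest(od, config_echo(config),
                 list(n_frames = n_frames(traj)))
  bundle
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle in '", x$out_dir, "'\n", sep = "")
  if (!is.null(x$processed_poses))
    cat("  processed poses: ", x$processed_poses,
        "; window enrichment of differential: ",
        round(x$enrichment, 4), "\n", sep = "")
  if (!is.null(x$series))
    cat("  trajectory frames: ", nrow(x$series), "; contact-area frames: ",
        nrow(x$area), "\n", sep = "")
  invisible(x)
}
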