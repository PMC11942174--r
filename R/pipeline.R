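.config_schema <- list(
  top = c("seed", "out_dir", "log_level", "stages", "simulate", "efflux",
          "triage", "pocketdyn", "pore"),
  simulate = c("plate", "library", "trajectory", "pore"),
  simulate.plate = c("top", "bottom", "ic50", "slope", "doses",
                     "n_technical", "n_biological", "noise_cv",
                     "background_fraction", "total_rb"),
  simulate.library = c("n_compounds", "n_bits", "cluster_plan",
                       "known_binder_seeds", "n_on"),
  simulate.trajectory = c("n_runs", "n_frames", "pocket_residues",
                          "fragment_sigmas", "contact_plan",
                          "global_drift"),
  simulate.pore = c("geometry", "wall_radius", "constriction_radius",
                    "constriction_z", "constriction_width", "z_range",
                    "atom_radius", "atom_spacing"),
  efflux = c("plate_csv", "reference_condition", "reference_dose"),
  triage = c("library_tsv", "known_binders_tsv", "novelty_cutoff",
             "cluster_cutoff", "top_n", "n_select", "use_lipinski"),
  pocketdyn = c("pdb", "trajectories", "ligand_resname",
                "align_selection", "cutoff", "inclusion_fraction",
                "run_quorum", "display_threshold"),
  pore = c("pdb", "axis", "z_min", "z_max", "z_step", "max_probe")
)

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "),
         " (strict schema; fix or remove them)")
}

#' Read and validate a pipeline configuration
#'
#' One YAML file configures the whole pipeline: a global seed, an output
#' directory, the stage list and per-stage sub-configurations.  The
#' schema is strict -- unknown keys are fatal, so a mistyped threshold
#' (`0.3` vs `0.03` under a misspelled name) cannot pass silently.
#' Coordinates are Angstrom and concentrations µM throughout.
#'
#' @param path YAML config file.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .config_schema$top, "config")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("config must list at least one stage")
  known_stages <- c("simulate", "efflux", "triage", "pocketdyn", "pore")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(cfg), known_stages)) {
    .check_keys(cfg[[sec]], .config_schema[[sec]], sec)
    if (sec == "simulate") {
      for (sub in names(cfg$simulate))
        .check_keys(cfg$simulate[[sub]],
                    .config_schema[[paste0("simulate.", sub)]],
                    paste0("simulate.", sub))
    }
  }
  cfg$source_path <- path
  class(cfg) <- "pipeline_config"
  cfg
}

.log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[katpscreen] ", ...)
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order, writing per-stage reports into
#' `out_dir` plus a provenance manifest (`manifest.json`: package
#' version, seed, config digest, per-output file digests).  Referenced
#' input files are checked before any stage runs; a stage error aborts
#' the run naming the stage.  Identical config + seed yields identical
#' report digests.
#'
#' @param config a [read_pipeline_config()] result or a YAML path.
#' @return manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # pre-flight: every referenced input must exist before any stage runs
  inputs <- as.character(c(config$efflux$plate_csv,
                           config$triage$library_tsv,
                           config$triage$known_binders_tsv,
                           config$pocketdyn$pdb,
                           unlist(config$pocketdyn$trajectories),
                           config$pore$pdb))
  sim_outputs <- character(0)
  if ("simulate" %in% config$stages) {
    # files the simulate stage itself will produce are not required upfront
    sim_outputs <- file.path(out_dir,
                             c("plate.csv", "library.tsv",
                               "known_binders.tsv", "pore.pdb",
                               "trajectory.pdb",
                               sprintf("traj_run%d.xyz", 1:99)))
  }
  missing_in <- setdiff(inputs[!file.exists(inputs)], sim_outputs)
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))

  outputs <- character(0)
  seed <- as.integer(config$seed)
  for (stage in config$stages) {
    .log_msg(config, "stage: ", stage)
    res <- tryCatch(
      switch(stage,
             simulate = .stage_simulate(config, out_dir, seed),
             efflux = .stage_efflux(config, out_dir),
             triage = .stage_triage(config, out_dir),
             pocketdyn = .stage_pocketdyn(config, out_dir),
             pore = .stage_pore(config, out_dir)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    outputs <- c(outputs, res)
  }
  manifest <- list(
    package = "katpscreen",
    version = as.character(utils::packageVersion("katpscreen")),
    seed = seed,
    config_digest = unname(tools::md5sum(config$source_path)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.stage_simulate <- function(config, out_dir, seed) {
  sc <- config$simulate
  outs <- character(0)
  if (!is.null(sc$plate) || is.null(sc)) {
    spec <- do.call(plate_spec, c(sc$plate, list(seed = seed)))
    plate <- gen_plate(spec)
    outs <- c(outs, write_plate_csv(plate$wells,
                                    file.path(out_dir, "plate.csv")))
  }
  if (!is.null(sc$library)) {
    spec <- do.call(library_spec, c(sc$library, list(seed = seed)))
    lib <- gen_library(spec)
    outs <- c(outs,
              write_fingerprint_tsv(lib$library,
                                    file.path(out_dir, "library.tsv")))
    kb <- fp_library(sprintf("KB%03d", seq_along(lib$known_binders)),
                     lib$known_binders,
                     rep(0, length(lib$known_binders)))
    outs <- c(outs,
              write_fingerprint_tsv(kb, file.path(out_dir,
                                                  "known_binders.tsv")))
  }
  if (!is.null(sc$trajectory)) {
    args <- sc$trajectory
    if (!is.null(args$fragment_sigmas))
      args$fragment_sigmas <- unlist(args$fragment_sigmas)
    if (!is.null(args$contact_plan))
      args$contact_plan <- as.data.frame(
        do.call(rbind, lapply(args$contact_plan, as.data.frame)))
    spec <- do.call(trajectory_spec, c(args, list(seed = seed)))
    tr <- gen_trajectory(spec)
    outs <- c(outs,
              write_pdb_topology(tr$topology, tr$ensemble$runs[[1]][1, , ],
                                 file.path(out_dir, "trajectory.pdb")),
              write_xyz_frames(tr$ensemble, tr$topology, out_dir))
  }
  if (!is.null(sc$pore)) {
    args <- sc$pore
    if (!is.null(args$z_range)) args$z_range <- unlist(args$z_range)
    spec <- do.call(pore_spec, c(args, list(seed = seed)))
    pore <- gen_pore(spec)
    outs <- c(outs, write_pdb_topology(pore$topology, pore$coords,
                                       file.path(out_dir, "pore.pdb")))
  }
  outs
}

.stage_efflux <- function(config, out_dir) {
  ec <- config$efflux
  plate_csv <- if (!is.null(ec$plate_csv)) ec$plate_csv
               else file.path(out_dir, "plate.csv")
  wells <- read_plate_csv(plate_csv)
  ref <- if (!is.null(ec$reference_condition)) ec$reference_condition
         else "WT"
  ref_dose <- if (!is.null(ec$reference_dose)) ec$reference_dose else 0
  tab <- preprocess_efflux(wells, ref, ref_dose)
  res <- ic50_with_sem(tab)
  report <- list(reference_condition = ref,
                 mean_ic50_uM = res$mean_ic50,
                 sem_ic50_uM = res$sem_ic50,
                 n_replicates = res$n_replicates,
                 replicate_fits = lapply(res$fits, unclass))
  out <- file.path(out_dir, "efflux_fit.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  out
}

.stage_triage <- function(config, out_dir) {
  tc <- config$triage
  lib_tsv <- if (!is.null(tc$library_tsv)) tc$library_tsv
             else file.path(out_dir, "library.tsv")
  lib <- read_fingerprint_tsv(lib_tsv)
  kb <- list()
  kb_tsv <- if (!is.null(tc$known_binders_tsv)) tc$known_binders_tsv
            else file.path(out_dir, "known_binders.tsv")
  if (file.exists(kb_tsv)) kb <- read_fingerprint_tsv(kb_tsv)$bits
  cfg_args <- tc[intersect(names(tc),
                           c("novelty_cutoff", "cluster_cutoff", "top_n",
                             "n_select"))]
  if (isTRUE(tc$use_lipinski))
    cfg_args$filter_predicates <- lipinski_predicates()
  report <- run_triage(lib, kb, do.call(triage_config, cfg_args))
  out <- file.path(out_dir, "triage_report.json")
  jsonlite::write_json(
    list(selected = report$selected,
         stage_counts = as.list(report$stage_counts),
         filter_rejections = as.list(report$filter_rejections),
         novelty_excluded = report$novelty_excluded),
    out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out
}

.stage_pocketdyn <- function(config, out_dir) {
  pc <- config$pocketdyn
  pdb <- if (!is.null(pc$pdb)) pc$pdb
         else file.path(out_dir, "trajectory.pdb")
  top <- read_pdb_topology(pdb)$topology
  trajs <- if (!is.null(pc$trajectories)) unlist(pc$trajectories)
           else sort(Sys.glob(file.path(out_dir, "traj_run*.xyz")))
  ens <- read_xyz_frames(trajs, top)
  lig_resname <- if (!is.null(pc$ligand_resname)) pc$ligand_resname
                 else "LIG"
  lig_ids <- top$atoms$atom_id[top$atoms$resname == lig_resname]
  if (!length(lig_ids)) stop("no atoms with resname '", lig_resname, "'")
  ca_ids <- top$atoms$atom_id[top$atoms$name == "CA" &
                                top$atoms$resname != lig_resname]
  top$selections <- list(pocket_ca = ca_ids, ligand = lig_ids)
  aligned <- align_ensemble(ens, top, "pocket_ca")
  cutoff <- if (!is.null(pc$cutoff)) pc$cutoff else 3.5
  rep_ <- contact_fractions(aligned, top, "ligand", cutoff = cutoff)
  incl <- if (!is.null(pc$inclusion_fraction)) pc$inclusion_fraction
          else 0.30
  retained <- aggregate_contacts(rep_, incl, pc$run_quorum)
  disp <- if (!is.null(pc$display_threshold)) pc$display_threshold
          else 0.40
  freq <- frequency_report(rep_, disp)
  out_csv <- file.path(out_dir, "contact_fractions.csv")
  utils::write.csv(rep_$fractions, out_csv, row.names = FALSE)
  out_json <- file.path(out_dir, "pocketdyn_report.json")
  jsonlite::write_json(list(retained_residues = retained,
                            frequency_table = freq,
                            cutoff = cutoff,
                            inclusion_fraction = incl),
                       out_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(out_csv, out_json)
}

.stage_pore <- function(config, out_dir) {
  pc <- config$pore
  pdb <- if (!is.null(pc$pdb)) pc$pdb else file.path(out_dir, "pore.pdb")
  p <- read_pdb_topology(pdb)
  axis <- if (!is.null(pc$axis)) unlist(pc$axis) else c(0, 0, 1)
  zr <- if (!is.null(pc$z_min)) c(pc$z_min, pc$z_max) else NULL
  zs <- if (!is.null(pc$z_step)) pc$z_step else 0.5
  mp <- if (!is.null(pc$max_probe)) pc$max_probe else 5
  prof <- pore_profile(p$coords, p$topology$atoms$element, axis = axis,
                       z_range = zr, z_step = zs, max_probe = mp)
  out_csv <- file.path(out_dir, "pore_profile.csv")
  utils::write.csv(prof$profile[c("z", "radius")], out_csv,
                   row.names = FALSE)
  out_json <- file.path(out_dir, "pore_minimum.json")
  jsonlite::write_json(prof$minimum, out_json, auto_unbox = TRUE,
                       digits = NA)
  c(out_csv, out_json)
}
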