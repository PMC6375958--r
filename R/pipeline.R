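# End-to-end run configuration and report bundle.

RUN_CONFIG_KEYS <- c("topology", "trajectory", "dt_ps", "d_cut", "regions",
                     "ref_atoms", "stable_threshold", "strong_threshold",
                     "min_event_ns", "species", "rdf_r_max", "rdf_dr",
                     "chain_groups", "out_dir", "seed")

#' Build a run configuration
#'
#' Collects every tunable of the full pipeline with validated defaults.
#' Unknown keys are rejected, so a config file cannot silently misspell a
#' parameter.
#'
#' @param topology,trajectory input file paths (PDB; DCD or MTRAJ).
#' @param dt_ps frame spacing in ps (required for DCD input).
#' @param d_cut contact cutoff in Angstrom.
#' @param regions named list of residue-number vectors; default
#'   [raf_regions()].
#' @param ref_atoms RDF reference selection: list with `resnum` and
#'   `atom_name` vectors (default the polybasic-cluster basic nitrogens:
#'   NZ of Lys 399, NE of Arg 391/398/401).
#' @param stable_threshold,strong_threshold stable-contact thresholds
#'   (defaults 0.5 and 0.8).
#' @param min_event_ns long-event threshold in ns (default 40).
#' @param species lipid species for residence/RDF/enrichment (default
#'   `"POPA"`).
#' @param rdf_r_max,rdf_dr RDF range and bin width (Angstrom).
#' @param chain_groups optional list of chain-id vectors for replica
#'   averaging.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the summary.
#' @return a validated `run_config` list.
#' @export
run_config <- function(topology, trajectory, dt_ps = NULL, d_cut = 4.0,
                       regions = raf_regions(),
                       ref_atoms = list(resnum = c(391L, 398L, 399L, 401L),
                                        atom_name = c("NE", "NZ")),
                       stable_threshold = 0.5, strong_threshold = 0.8,
                       min_event_ns = 40, species = "POPA",
                       rdf_r_max = 12, rdf_dr = 0.2, chain_groups = NULL,
                       out_dir = "memlipid_out", seed = 1L) {
  for (thr in c(stable_threshold, strong_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      abort("Thresholds must lie strictly between 0 and 1.")
    }
  }
  check_scalar_number(d_cut, "d_cut", positive = TRUE)
  if (min_event_ns < 0) abort("`min_event_ns` must be >= 0.")
  structure(
    list(topology = topology, trajectory = trajectory, dt_ps = dt_ps,
         d_cut = d_cut, regions = regions, ref_atoms = ref_atoms,
         stable_threshold = stable_threshold,
         strong_threshold = strong_threshold, min_event_ns = min_event_ns,
         species = species, rdf_r_max = rdf_r_max, rdf_dr = rdf_dr,
         chain_groups = chain_groups, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat keys and nested sections mirror the [run_config()] arguments; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

pipeline_stage <- function(name, expr, log_con, out_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
               log_con)
    writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full contact / residence / lipid-statistics pipeline
#'
#' Executes contact detection, contact probabilities, dwell events,
#' RDF, enrichment and salt-bridge/multivalency analyses over one trajectory,
#' writing tidy CSVs per stage plus a machine-readable `summary.json` and a
#' log of every resolved parameter. The summary is a pure function of the
#' inputs and the configuration.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  writeLines(sprintf("resolved config: %s",
                     jsonlite::toJSON(config[setdiff(names(config), "regions")],
                                      auto_unbox = TRUE)), log_con)
  writeLines(sprintf("regions: %s",
                     jsonlite::toJSON(config$regions)), log_con)
  od <- config$out_dir

  top <- pipeline_stage("read_topology",
                        read_topology(config$topology), log_con, od)
  traj <- pipeline_stage("read_trajectory",
                         read_trajectory(top, config$trajectory,
                                         dt = config$dt_ps), log_con, od)
  params <- contact_params(d_cut = config$d_cut)
  series <- pipeline_stage("contacts", contact_series(traj, params),
                           log_con, od)
  summ <- pipeline_stage("contact_probability",
                         contact_probability(series, config$chain_groups),
                         log_con, od)
  utils::write.csv(as.data.frame(summ),
                   file.path(od, "contact_probability.csv"),
                   row.names = FALSE)
  stable <- stable_residues(summ, config$stable_threshold)
  strong <- stable_residues(summ, config$strong_threshold)
  regions <- pipeline_stage("region_summary",
                            region_summary(summ, config$regions,
                                           config$stable_threshold),
                            log_con, od)
  events <- pipeline_stage("residence",
                           dwell_events(series, species = config$species,
                                        residues = "all"), log_con, od)
  utils::write.csv(as.data.frame(events), file.path(od, "dwell_events.csv"),
                   row.names = FALSE)
  res_sum <- residence_summary(events,
                               min_event_ps = config$min_event_ns * 1000)
  rdf <- pipeline_stage("rdf", {
    ids <- select_atoms(top, resnum = config$ref_atoms$resnum,
                        atom_name = config$ref_atoms$atom_name)
    if (length(ids)) {
      rdf2d(traj, ids, species = config$species,
            r_max = config$rdf_r_max, dr = config$rdf_dr)
    } else NULL
  }, log_con, od)
  if (!is.null(rdf)) {
    utils::write.csv(as.data.frame(rdf), file.path(od, "rdf.csv"),
                     row.names = FALSE)
  }
  enr <- pipeline_stage("enrichment", {
    basic <- config$regions[["basic"]] %||% config$regions[[1]]
    enrichment(traj, basic, params, species = config$species)
  }, log_con, od)
  sb <- pipeline_stage("salt_bridges",
                       suppressWarnings(salt_bridges(traj, d_sb = config$d_cut)),
                       log_con, od)
  mv <- multivalent_episodes(sb)
  shared <- pipeline_stage("shared_lipids",
                           shared_lipid_regions(series, config$regions),
                           log_con, od)
  utils::write.csv(as.data.frame(shared),
                   file.path(od, "shared_lipid_episodes.csv"),
                   row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_frames = traj$n_frames,
    dt_ps = traj$dt,
    stable_residues = residue_labels(stable),
    strong_residues = residue_labels(strong),
    regions = lapply(seq_len(nrow(regions)), function(i) {
      list(region = regions$region[i], mean_p = regions$mean_p[i],
           stable = regions$stable[[i]])
    }),
    residence = list(
      n_events = nrow(events),
      n_long = res_sum$n_long,
      t_res_max_ps = if (nrow(events)) max(events$t_res_ps) else NA,
      per_residue = res_sum$per_residue
    ),
    enrichment = list(local = enr$local_fraction, global = enr$global_fraction,
                      undefined = enr$undefined),
    multivalent_intervals = nrow(mv)
  )
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines("pipeline completed", log_con)
  invisible(summary)
}
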