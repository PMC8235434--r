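# Orchestration of the end-to-end analysis: pose triage, conformational
# classification, MM-GB/SA scoring and thermodynamic integration, each
# driven by a validated config (YAML file or R list) and writing TSV
# detail files plus a JSON report with a provenance block. The functions
# are the package's command surface; a thin Rscript wrapper around them
# (inst/scripts/helixbind-pipeline.R) exposes the same stages to a shell
# with exit codes 0 (success), 2 (input/config error), 3 (numerical
# failure).

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config(sprintf("config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML file path or a list.")
  config
}

check_paths_exist <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop_config(sprintf("input path(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

sel_from_config <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "atom_selection")) return(x)
  resid <- x$resid
  if (!is.null(x$resid_start)) resid <- seq(x$resid_start, x$resid_end)
  atom_selection(chain = x$chain, resid = resid, atoms = x$atom_names %||% "heavy")
}

provenance_block <- function(config, seed) {
  list(
    config_hash = rlang::hash(config),
    package = "helixbind",
    package_version = as.character(utils::packageVersion("helixbind")),
    seed = seed,
    config = config
  )
}

write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate an analysis report against the shipped schema
#'
#' Reports written by the `run_*` stages follow the JSON schema shipped at
#' `inst/schema/report-schema.json`. This checks the structural
#' requirements of that schema (required keys and their types).
#'
#' @param report A report list, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_report <- function(report) {
  if (is.character(report) && length(report) == 1L) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  if (!is.list(report)) stop_config("report must be a list or a JSON file path.")
  for (key in c("stage", "provenance", "results")) {
    if (is.null(report[[key]])) stop_config(sprintf("report lacks required key '%s'.", key))
  }
  for (key in c("config_hash", "package", "package_version")) {
    if (is.null(report$provenance[[key]])) {
      stop_config(sprintf("report provenance lacks required key '%s'.", key))
    }
  }
  if (!is.character(report$stage) && !is.null(report$stage)) {
    stop_config("report 'stage' must be a string.")
  }
  invisible(TRUE)
}

ensure_outdir <- function(config) {
  out <- config$output_dir
  if (is.null(out)) stop_config("config needs `output_dir`.")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run docking-pose contact triage
#'
#' For every configured pose, reads the complex PDB, measures minimum
#' heavy-atom distances to the key binding-site residues and writes a
#' per-pose contact TSV plus a combined JSON report. All inputs are
#' validated before anything is written, so a bad path produces no partial
#' output.
#'
#' Config keys: `output_dir`; `triage$poses` (list of `name`, `pdb`,
#' `ligand_resname`); optional `triage$key_resids`, `triage$cutoff`.
#'
#' @param config YAML path or list.
#' @return Tibble with one row per pose (`pose`, `label`) plus the contact
#'   details, invisibly the written report path in attribute `report`.
#' @export
run_triage <- function(config) {
  config <- read_config(config)
  out <- ensure_outdir(config)
  tc <- config$triage
  if (is.null(tc$poses) || length(tc$poses) == 0L) stop_config("triage config needs `poses`.")
  check_paths_exist(purrr::map_chr(tc$poses, "pdb"))
  key_resids <- as.integer(tc$key_resids %||% c(353L, 394L, 524L))
  cutoff <- tc$cutoff %||% 4.0
  reports <- purrr::map(tc$poses, function(p) {
    cx <- as_structure(parse_pdb(p$pdb))
    pose_contacts(cx, p$ligand_resname, key_resids = key_resids, cutoff = cutoff)
  })
  names(reports) <- purrr::map_chr(tc$poses, "name")
  detail <- purrr::imap_dfr(reports, function(r, nm) {
    dplyr::mutate(tidy(r), pose = nm, label = r$label, .before = 1)
  })
  purrr::iwalk(reports, function(r, nm) {
    write_tsv(tidy(r), file.path(out, sprintf("triage_%s.tsv", nm)))
  })
  report <- list(
    stage = "triage",
    provenance = provenance_block(config, seed = NULL),
    results = purrr::imap(reports, function(r, nm) {
      list(pose = nm, label = r$label, cutoff = r$cutoff,
           contacts = as.data.frame(r$contacts))
    })
  )
  path <- write_report(report, file.path(out, "triage.json"))
  attr(detail, "report") <- path
  detail
}

#' Run the conformational classification chain
#'
#' Full chain per ligand: per-frame backbone RMSD against the
#' antagonist-bound reference, kernel density estimation, then the
#' three-way tendency classification of the query against the agonist and
#' antagonist controls. Writes per-ligand RMSD and density-grid TSVs plus a
#' JSON report.
#'
#' Config keys: `output_dir`; `classify$reference_pdb` (antagonist-bound
#' reference); `classify$query`, `classify$agonist_ctrl`,
#' `classify$antagonist_ctrl` (each `name` + `trajectory_pdb`); optional
#' `classify$selection` (`chain`, `resid_start`, `resid_end`,
#' `atom_names`), `classify$bandwidth`, `classify$margin`.
#'
#' @param config YAML path or list.
#' @return The `tendency_report`, with the per-ligand RMSD tibbles in
#'   attribute `rmsd` and the report path in attribute `report`.
#' @export
run_classify <- function(config) {
  config <- read_config(config)
  out <- ensure_outdir(config)
  cc <- config$classify
  roles <- c("query", "agonist_ctrl", "antagonist_ctrl")
  if (is.null(cc$reference_pdb) || !all(roles %in% names(cc))) {
    stop_config("classify config needs reference_pdb, query, agonist_ctrl, antagonist_ctrl.")
  }
  check_paths_exist(c(cc$reference_pdb, purrr::map_chr(cc[roles], "trajectory_pdb")))
  sel <- sel_from_config(cc$selection) %||% atom_selection(atoms = "backbone")
  reference <- as_structure(parse_pdb(cc$reference_pdb))
  series <- purrr::map(cc[roles], function(x) {
    rmsd_series(parse_pdb(x$trajectory_pdb), reference, fit_sel = sel)
  })
  dens <- purrr::map(series, function(s) {
    density_estimate(s, bandwidth = cc$bandwidth %||% "auto")
  })
  verdict <- classify_tendency(dens$query, dens$agonist_ctrl,
                               dens$antagonist_ctrl,
                               margin = cc$margin %||% 0.1)
  purrr::iwalk(series, function(s, role) {
    nm <- cc[[role]]$name %||% role
    write_tsv(s, file.path(out, sprintf("rmsd_%s.tsv", nm)))
    write_tsv(dens[[role]]$grid, file.path(out, sprintf("density_%s.tsv", nm)))
  })
  report <- list(
    stage = "classify",
    provenance = provenance_block(config, seed = NULL),
    results = list(
      verdict = verdict$verdict,
      margin = verdict$margin,
      medians = as.data.frame(verdict$medians),
      ordering = as.data.frame(verdict$ordering)
    )
  )
  path <- write_report(report, file.path(out, "classify.json"))
  attr(verdict, "rmsd") <- series
  attr(verdict, "report") <- path
  verdict
}

#' Run MM-GB/SA scoring and the reference-relative table
#'
#' Scores each ligand's complex trajectory with the single-trajectory
#' MM-GB/SA estimator and expresses every mean as a difference from the
#' configured reference ligand (positive difference = weaker binding than
#' the reference). Writes per-ligand per-frame TSVs plus a JSON report with
#' the relative table.
#'
#' Config keys: `output_dir`; `mmgbsa$forcefield` (TSV path);
#' `mmgbsa$ligands` (list of `name`, `trajectory_pdb`, `ligand_sel`,
#' `receptor_sel` selection blocks); `mmgbsa$reference` (ligand name);
#' optional `mmgbsa$solvent` overrides for [solvent_model()].
#'
#' @param config YAML path or list.
#' @return Tibble from [relative_binding()], with the per-ligand
#'   `binding_result`s in attribute `results` and the report path in
#'   attribute `report`.
#' @export
run_mmgbsa <- function(config) {
  config <- read_config(config)
  out <- ensure_outdir(config)
  mc <- config$mmgbsa
  if (is.null(mc$ligands) || is.null(mc$reference) || is.null(mc$forcefield)) {
    stop_config("mmgbsa config needs forcefield, ligands and reference.")
  }
  check_paths_exist(c(mc$forcefield, purrr::map_chr(mc$ligands, "trajectory_pdb")))
  ff <- read_forcefield(mc$forcefield)
  solvent <- do.call(solvent_model, mc$solvent %||% list())
  results <- purrr::map(mc$ligands, function(lg) {
    traj <- parse_pdb(lg$trajectory_pdb)
    mmgbsa_binding(traj, sel_from_config(lg$ligand_sel),
                   sel_from_config(lg$receptor_sel), ff, solvent)
  })
  names(results) <- purrr::map_chr(mc$ligands, "name")
  rel <- relative_binding(results, mc$reference)
  purrr::iwalk(results, function(r, nm) {
    write_tsv(tidy(r), file.path(out, sprintf("mmgbsa_%s.tsv", nm)))
  })
  report <- list(
    stage = "mmgbsa",
    provenance = provenance_block(config, seed = NULL),
    results = list(
      reference = mc$reference,
      solvent = unclass(solvent),
      per_ligand = purrr::imap(results, function(r, nm) {
        c(list(ligand = nm), as.list(glance(r)))
      }),
      relative = as.data.frame(rel)
    )
  )
  path <- write_report(report, file.path(out, "mmgbsa.json"))
  attr(rel, "results") <- results
  attr(rel, "report") <- path
  rel
}

#' Run staged alchemical decoupling with thermodynamic integration
#'
#' Builds toy complex/solvent legs from the configured specs, samples
#' `dH/dlambda` at every schedule node with the Metropolis sampler,
#' integrates by the trapezoidal rule and pools the replicates (default 4).
#' Mode `"double"` returns the double-decoupling binding estimate; mode
#' `"complex_only"` the complex-leg decoupling free energy alone.
#'
#' Config keys: `output_dir`; `ti$seed`; optional `ti$mode`,
#' `ti$n_charge_steps` (5), `ti$n_vdw_steps` (12), `ti$n_replicates` (4),
#' `ti$n_sweeps`, `ti$burn_in`, `ti$step`, and `ti$complex` / `ti$solvent`
#' specs passed to [gen_toy_complex()].
#'
#' @param config YAML path or list.
#' @return A `decoupling_result` (mode `"double"`) or pooled `ti_result`
#'   (mode `"complex_only"`), with the report path in attribute `report`.
#' @export
run_ti <- function(config) {
  config <- read_config(config)
  out <- ensure_outdir(config)
  tc <- config$ti %||% list()
  if (is.null(tc$seed)) stop_config("ti config needs an explicit `seed`.")
  mode <- tc$mode %||% "double"
  n_rep <- tc$n_replicates %||% 4L
  if (n_rep < 2L) stop_config("ti needs >= 2 replicates (pooled SE undefined otherwise).")
  schedule <- build_schedule(tc$n_charge_steps %||% 5L, tc$n_vdw_steps %||% 12L)
  n_sweeps <- tc$n_sweeps %||% 300L
  burn_in <- tc$burn_in %||% 100L
  step <- tc$step %||% 0.3
  mk <- function(spec, restrain) {
    spec <- spec %||% list()
    spec$restraint_k <- spec$restraint_k %||% if (restrain) 2 else 0
    do.call(gen_toy_complex, spec)$system
  }
  sys_complex <- mk(tc$complex, restrain = TRUE)
  res <- if (identical(mode, "double")) {
    sys_solvent <- mk(tc$solvent %||% tc$complex, restrain = TRUE)
    decoupling_free_energy(sys_complex, sys_solvent, schedule,
                           n_replicates = n_rep, seed = tc$seed,
                           n_sweeps = n_sweeps, burn_in = burn_in, step = step)
  } else {
    seeds <- derive_seeds(tc$seed, n_rep)
    reps <- purrr::map(seeds, function(s) {
      series <- sample_dhdl(sys_complex, schedule, n_sweeps = n_sweeps,
                            burn_in = burn_in, step = step, seed = s)
      trapezoid_integrate(series)
    })
    pool_replicates(reps)
  }
  summary <- if (inherits(res, "decoupling_result")) {
    list(mode = "double", dg_bind = res$dg_bind, se = res$se,
         complex_leg = as.list(glance(res$complex)),
         solvent_leg = as.list(glance(res$solvent)))
  } else {
    list(mode = "complex_only", dg_decouple = -res$total, se = res$se,
         stages = as.data.frame(tidy(res)))
  }
  report <- list(
    stage = "ti",
    provenance = provenance_block(config, seed = tc$seed),
    results = summary
  )
  path <- write_report(report, file.path(out, "ti.json"))
  attr(res, "report") <- path
  res
}

#' Generate synthetic study inputs
#'
#' Drives the synthetic-data module: writes the closed/open reference
#' mimics, a set of two-basin ensembles as multi-model PDBs with sidecar
#' ground-truth label TSVs, a toy-complex PDB with its force-field TSV, and
#' a lambda series with known integral.
#'
#' Config keys: `output_dir`; `simulate$seed`; optional
#' `simulate$ensembles` (list of `name`, `open_fraction`, `n_frames`,
#' `sigma`), `simulate$displacement`.
#'
#' @param config YAML path or list.
#' @return Tibble of written files (`what`, `path`), invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_config(config)
  out <- ensure_outdir(config)
  sc <- config$simulate %||% list()
  if (is.null(sc$seed)) stop_config("simulate config needs an explicit `seed`.")
  displacement <- sc$displacement %||% c(6, 6, 0)
  ensembles <- sc$ensembles %||% list(
    list(name = "agonist_like", open_fraction = 0.0, n_frames = 100L, sigma = 0.3),
    list(name = "antagonist_like", open_fraction = 0.3, n_frames = 100L, sigma = 0.3)
  )
  closed <- make_mimic_receptor(open = FALSE, displacement = displacement)
  open <- make_mimic_receptor(open = TRUE, displacement = displacement)
  files <- list()
  add <- function(what, path) files[[length(files) + 1L]] <<- tibble::tibble(what = what, path = path)
  write_pdb(closed, file.path(out, "reference_active.pdb"))
  add("active reference", file.path(out, "reference_active.pdb"))
  write_pdb(open, file.path(out, "reference_inactive.pdb"))
  add("inactive reference", file.path(out, "reference_inactive.pdb"))
  seeds <- derive_seeds(sc$seed, length(ensembles) + 1L)
  for (k in seq_along(ensembles)) {
    e <- ensembles[[k]]
    sim <- gen_two_basin_trajectory(
      closed, n_frames = e$n_frames %||% 100L,
      open_fraction = e$open_fraction %||% 0,
      displacement = displacement, sigma = e$sigma %||% 0.3, seed = seeds[k]
    )
    pdb <- file.path(out, sprintf("ensemble_%s.pdb", e$name))
    lab <- file.path(out, sprintf("ensemble_%s_labels.tsv", e$name))
    write_pdb(sim$trajectory, pdb)
    write_labels(sim$labels, lab)
    add(sprintf("ensemble %s", e$name), pdb)
    add(sprintf("ensemble %s labels", e$name), lab)
  }
  toy <- gen_toy_complex(seed = seeds[length(seeds)])
  write_pdb(toy$structure, file.path(out, "toy_complex.pdb"))
  add("toy complex", file.path(out, "toy_complex.pdb"))
  write_forcefield(toy$ff, file.path(out, "toy_forcefield.tsv"))
  add("toy force field", file.path(out, "toy_forcefield.tsv"))
  series <- gen_lambda_series("quadratic", coef = 3, noise = 0,
                              schedule = single_stage_schedule("charge", 5L))
  write_lambda_series(series, file.path(out, "lambda_series.tsv"))
  add("lambda series", file.path(out, "lambda_series.tsv"))
  invisible(dplyr::bind_rows(files))
}
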