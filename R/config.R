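# Run configuration and the one-shot end-to-end analysis driver.
#
# A run config is a plain named list with per-stage blocks; it
# round-trips losslessly through YAML and unknown keys are rejected so
# typos fail loudly.  The driver mirrors the full analysis shape:
# ensembles -> intrinsic + ensemble-corrected profiles -> candidate sites
# -> saturation scans -> design report, plus strand populations and a
# CV-space free-energy surface.

CONFIG_KEYS <- list(
  profile = c("w_hyd", "w_beta", "w_alpha", "w_chg", "window",
              "gatekeeper", "gatekeeper_reach", "aggregation_threshold"),
  kernel = c("sigma_d", "cutoff", "probe_radius", "n_points"),
  fes = c("temperature", "n_bins"),
  design = c("intrinsic_threshold", "delta_threshold"),
  synth = c("length", "hotspot_start", "hotspot_end", "gatekeepers",
            "n_conformations", "burial", "noise"),
  inputs = c("fasta", "pdb_a", "pdb_b", "weights_a", "weights_b"),
  top = c("profile", "kernel", "fes", "design", "synth", "inputs",
          "seed", "output_dir", "verbosity"))

#' Default run configuration
#'
#' @param seed Integer seed for the synthetic-data path.
#' @param output_dir Directory for report files.
#' @return Nested named list of class `run_config` with blocks `profile`,
#'   `kernel`, `fes`, `design`, `synth`, `inputs`.
#' @export
default_config <- function(seed = 1, output_dir = "aggscape-out") {
  structure(list(
    profile = list(w_hyd = 1.0, w_beta = 0.4, w_alpha = 0.2, w_chg = 0.8,
                   window = 7L, gatekeeper = 0.15, gatekeeper_reach = 3L,
                   aggregation_threshold = 1.0),
    kernel = list(sigma_d = 5.0, cutoff = 8.0, probe_radius = 1.4,
                  n_points = 192L),
    fes = list(temperature = 310, n_bins = 8L),
    design = list(intrinsic_threshold = 1.0, delta_threshold = 0.2),
    synth = list(length = 40L, hotspot_start = 16L, hotspot_end = 22L,
                 gatekeepers = FALSE, n_conformations = 12L,
                 burial = c(0.50, 0.30), noise = 0.3),
    inputs = list(fasta = NULL, pdb_a = NULL, pdb_b = NULL,
                  weights_a = NULL, weights_b = NULL),
    seed = as.integer(seed), output_dir = output_dir, verbosity = 1L),
    class = "run_config")
}

check_config_keys <- function(config) {
  unknown <- setdiff(names(config), CONFIG_KEYS$top)
  if (length(unknown) > 0) {
    config_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  for (block in c("profile", "kernel", "fes", "design", "synth", "inputs")) {
    if (is.null(config[[block]])) next
    unknown <- setdiff(names(config[[block]]), CONFIG_KEYS[[block]])
    if (length(unknown) > 0) {
      config_error(sprintf("unknown key(s) in '%s' block: %s", block,
                           paste(unknown, collapse = ", ")))
    }
  }
  invisible(config)
}

#' Read a run configuration from YAML (or JSON)
#'
#' Values present in the file override the defaults of
#' [default_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML (or JSON) config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(
                    sprintf("cannot parse config '%s': %s", path,
                            conditionMessage(e))))
  if (is.null(raw)) raw <- list()
  check_config_keys(raw)
  cfg <- default_config()
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      for (kk in names(raw[[k]])) cfg[[k]][[kk]] <- raw[[k]][[kk]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  check_config_keys(cfg)
  cfg
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  check_config_keys(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbosity >= 1)) {
    message(sprintf(paste0("[aggscape] ", fmt), ...))
  }
}

#' Run the full analysis pipeline
#'
#' One-shot driver mirroring the complete workflow: obtain a sequence and
#' two conformational ensembles (from the `inputs` block when file paths
#' are given, otherwise generated by the synthetic module under
#' `config$seed`), compute the intrinsic profile and per-variant
#' ensemble-averaged structurally corrected profiles, strand beta
#' populations, a 2-D free-energy surface over the antiparallel-beta and
#' side-chain AlphaBeta CVs, candidate design sites, saturation scans and
#' rankings, and write all tables plus a JSON report and a manifest
#' (config hash, package version; no timestamps, so identical
#' config + seed reproduces the report byte-identically).
#'
#' @param config A `run_config` (see [default_config()],
#'   [read_run_config()]).
#' @return The report list, invisibly; files are written under
#'   `config$output_dir`.
#' @export
run_full_analysis <- function(config = default_config()) {
  check_config_keys(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- do.call(profile_params, config$profile)
  kp <- do.call(kernel_params, config$kernel)

  inp <- config$inputs
  use_files <- !is.null(inp$fasta) && !is.null(inp$pdb_a) &&
    !is.null(inp$pdb_b)
  if (use_files) {
    run_log(config, "loading inputs from files")
    sequence <- read_fasta(inp$fasta)[[1]]
    ens_a <- read_pdb(inp$pdb_a)
    ens_b <- read_pdb(inp$pdb_b)
    for (v in c("a", "b")) {
      wf <- inp[[paste0("weights_", v)]]
      ens <- if (v == "a") ens_a else ens_b
      if (!is.null(wf) && file.exists(wf)) {
        ens$weights <- read_weights(wf, length(ens$structures))
      } else if (!is.null(wf)) {
        warning(sprintf("weights file '%s' missing: using uniform weights",
                        wf))
      }
      if (v == "a") ens_a <- ens else ens_b <- ens
    }
  } else {
    run_log(config, "generating synthetic benchmark (seed %d)", config$seed)
    sp <- do.call(synth_spec, c(config$synth, list(seed = config$seed)))
    pair <- make_ensemble_pair(sp)
    sequence <- pair$sequence
    ens_a <- pair$A
    ens_b <- pair$B
  }

  run_log(config, "intrinsic profile")
  intr <- intrinsic_profile(sequence, pp)
  regions <- aggregation_prone_regions(intr, pp$aggregation_threshold)

  run_log(config, "ensemble-corrected profiles")
  scores_a <- ensemble_average_profile(ens_a, intr, kp)
  scores_b <- ensemble_average_profile(ens_b, intr, kp)

  run_log(config, "beta populations and free-energy surface")
  nres <- length(sequence$residues)
  thirds <- unique(pmin(nres, c(1, floor(nres / 3), floor(nres / 3) + 1,
                                floor(2 * nres / 3),
                                floor(2 * nres / 3) + 1, nres)))
  strands <- data.frame(label = c("N", "M", "C"),
                        start = thirds[c(1, 3, 5)],
                        end = thirds[c(2, 4, 6)])
  pops_a <- strand_beta_populations(ens_a, strands)
  pops_b <- strand_beta_populations(ens_b, strands)
  cv_a <- ensemble_cv_table(ens_a)
  rng <- function(x) range(x) + c(-1e-6, 1e-6)
  edges <- list(seq(rng(cv_a$beta)[1], rng(cv_a$beta)[2],
                    length.out = config$fes$n_bins + 1),
                seq(rng(cv_a$ab)[1], rng(cv_a$ab)[2],
                    length.out = config$fes$n_bins + 1))
  fes <- fes_from_samples(as.matrix(cv_a[, c("beta", "ab")]), edges,
                          temperature = config$fes$temperature)

  run_log(config, "design stage")
  design <- design_mutations(intr, scores_a$profile, scores_b$profile,
                             config$design$intrinsic_threshold,
                             config$design$delta_threshold,
                             params = pp)

  out <- function(f) file.path(config$output_dir, f)
  write_profile_table(intr, out("intrinsic_profile.tsv"))
  write_profile_table(scores_a$profile, out("corrected_profile_A.tsv"))
  write_profile_table(scores_b$profile, out("corrected_profile_B.tsv"))
  report <- list(
    sequence = paste(sequence$residues, collapse = ""),
    intrinsic_total = intr$total,
    aggregation_prone_regions = regions,
    ensemble_scores = list(
      A = list(mean = scores_a$mean, se = scores_a$se,
               per_conformation = scores_a$per_conformation),
      B = list(mean = scores_b$mean, se = scores_b$se,
               per_conformation = scores_b$per_conformation)),
    strand_populations = list(A = pops_a, B = pops_b),
    fes = list(axes = fes$axes, temperature = fes$temperature,
               F = as.vector(fes$F)),
    candidate_sites = design$sites,
    protective = utils::head(design$protective, 10),
    promoting = utils::head(design$promoting, 10),
    box_pooled = if (is.null(design$box_pooled)) NULL else
      unclass(design$box_pooled))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    package = "aggscape",
    version = as.character(utils::packageVersion("aggscape")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  run_log(config, "done: %s", config$output_dir)
  invisible(report)
}
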