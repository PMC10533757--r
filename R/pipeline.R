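#' Run configuration for the end-to-end pipeline
#'
#' A flat YAML file (or list) holding paths, the trait list, the MCMC
#' preset, scenario options and one master seed from which every module's
#' seed stream is derived. Any field omitted takes its default.
#'
#' @param path YAML file path, or `NULL` to build from `...`.
#' @param ... named overrides (see Details in the vignette); commonly
#'   `out_dir`, `seed`, `n_snps`, `traits`, `mcmc_preset`, `scenario`,
#'   `model`, `fraction`, `sampling`, `n_replicates`.
#' @return list of class `run_config` with resolved defaults.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(out_dir = ".", seed = 1L, n_snps = 2000L,
              n_individuals_A = 384L, n_individuals_B = 334L,
              n_checks = 50L, traits = c("FL", "PH", "YLD", "ZN"),
              mcmc_preset = "desk", scenario = "Uni1", model = NULL,
              fraction = 0.5, sampling = "random", n_replicates = 10L,
              log_level = "info")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Derive a named child seed from the master seed
#'
#' Deterministic per-module streams keep every stage independently
#' reproducible; values stay below 2^31.
#'
#' @param master integer master seed.
#' @param stream stream name (`"simulation"`, `"sampler"`, `"cv"`, `"ga"`).
#' @return integer seed.
#' @export
derive_seed <- function(master, stream) {
  off <- c(simulation = 11L, sampler = 23L, cv = 37L, ga = 53L)
  if (!stream %in% names(off)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(master) * 1009 + off[[stream]]) %% 2147483647)
}

sim_config_from_run <- function(config) {
  sim_config(n_individuals_A = config$n_individuals_A,
             n_individuals_B = config$n_individuals_B,
             n_checks = config$n_checks, n_snps = config$n_snps,
             seed = derive_seed(config$seed, "simulation"))
}

#' Simulate a study and write its files
#'
#' Writes `genotypes.vcf`, `genotypes.csv` (dosage) and `trials.csv` to
#' the configured output directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, the [simulate_study()] bundle with a `paths` element.
#' @export
cmd_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(sim_config_from_run(config))
  paths <- file.path(config$out_dir,
                     c("genotypes.vcf", "genotypes.csv", "trials.csv"))
  write_genotypes_vcf(study$markers, paths[1])
  write_dosage_csv(study$markers, paths[2])
  write_trial_records(study$trials, paths[3])
  study$paths <- paths
  message("cmd_simulate: seed ", config$seed, " -> ",
          paste(basename(paths), collapse = ", "))
  invisible(study)
}

#' Stage-1 analysis: descriptive statistics, variance components, BLUEs
#'
#' Reads (or accepts) trial records, writes Table-style reports:
#' `descriptive_stats.csv`, `variance_components.csv`, `blues.csv`.
#'
#' @param config a [run_config()].
#' @param trials optional in-memory `trial_records` (otherwise read from
#'   `<out_dir>/trials.csv`).
#' @return Invisibly, list with `stats`, `vc`, `h2`, `blues`.
#' @export
cmd_analyze <- function(config = run_config(), trials = NULL) {
  if (is.null(trials)) {
    p <- file.path(config$out_dir, "trials.csv")
    if (!file.exists(p)) stop("no trials.csv in ", config$out_dir,
                              "; run cmd_simulate first")
    trials <- read_trial_records(p)
  }
  missing_tr <- setdiff(config$traits, unique(trials$trait))
  if (length(missing_tr))
    stop("trait(s) absent from records: ", paste(missing_tr, collapse = ", "))
  ds <- descriptive_stats(trials)
  # variance decomposition on the validation population's multi-location set
  vs_set <- trials[trials$population == "B" & !trials$is_check, ]
  hm <- harmonic_means(vs_set)
  vc_rows <- list()
  for (tr in config$traits) {
    vc <- fit_variance_model(vs_set, tr)
    vc_rows[[tr]] <- data.frame(
      trait = tr, sigma2_g = vc$sigma2_g, sigma2_gxloc = vc$sigma2_gxloc,
      sigma2_block = vc$sigma2_block, sigma2_e = vc$sigma2_e,
      H2 = heritability(vc, NE = hm["NE"], NR = hm["NR"]),
      converged = vc$converged)
  }
  vc_tab <- do.call(rbind, vc_rows)
  rownames(vc_tab) <- NULL
  blues <- fit_blues_all(trials, config$traits)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$stats,
                   file.path(config$out_dir, "descriptive_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(vc_tab,
                   file.path(config$out_dir, "variance_components.csv"),
                   row.names = FALSE)
  utils::write.csv(blues, file.path(config$out_dir, "blues.csv"),
                   row.names = FALSE)
  invisible(list(stats = ds, vc = vc_tab, h2 = vc_tab$H2, blues = blues))
}

#' Run the configured prediction scenario
#'
#' Builds the genomic relationship from the simulated (or supplied)
#' genotypes, computes BLUEs, runs the configured scenario and writes
#' `scenario_pa.csv` plus a Table-style summary.
#'
#' @param config a [run_config()].
#' @param study optional in-memory [simulate_study()] bundle.
#' @return Invisibly, the `scenario_result`.
#' @export
cmd_predict <- function(config = run_config(), study = NULL) {
  if (is.null(study)) study <- cmd_simulate(config)
  Gr <- vanraden_g(impute_mean(study$markers))
  blues <- fit_blues_all(study$trials, config$traits)
  spec <- build_scenario(config$scenario, model = config$model,
                         fraction = config$fraction,
                         sampling = config$sampling,
                         n_replicates = config$n_replicates,
                         traits = config$traits)
  res <- run_scenario(spec, list(G = Gr, blues = blues),
                      seed = derive_seed(config$seed, "cv"),
                      settings = mcmc_settings(
                        preset = config$mcmc_preset,
                        seed = derive_seed(config$seed, "sampler")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$pa, file.path(config$out_dir, "scenario_pa.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary,
                   file.path(config$out_dir, "scenario_summary.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Optimize the training set for the configured problem
#'
#' @param config a [run_config()].
#' @param problem a [ts_opt_problem()] (required; built by the caller from
#'   a genomic relationship and candidate/target lists).
#' @param ga a [ga_settings()].
#' @return Invisibly, the [ga_select()] result; ids written to
#'   `selected_ts.csv`.
#' @export
cmd_optimize_ts <- function(config = run_config(), problem,
                            ga = ga_settings(seed = derive_seed(config$seed,
                                                                "ga"))) {
  res <- ga_select(problem, ga)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(id = res$selected),
                   file.path(config$out_dir, "selected_ts.csv"),
                   row.names = FALSE)
  utils::write.csv(res$trajectory,
                   file.path(config$out_dir, "ga_trajectory.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Print and return the cost ledger of a scenario
#'
#' @param scenario scenario name.
#' @return Invisibly, the `cost_ledger`.
#' @export
cmd_cost <- function(scenario) {
  led <- scenario_ledger(scenario)
  print(led)
  invisible(led)
}
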