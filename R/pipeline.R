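#' Read a pipeline configuration
#'
#' Configurations are YAML (or JSON) files with one block per stage:
#' `simulate`, `scan`, `stimulate`, `cohort`, `fit`, `survival`, plus a
#' global `seed` and `out_dir`. Missing entries fall back to the package
#' defaults; unknown top-level keys are rejected.
#'
#' @param path YAML or JSON file.
#' @return A named list of class `leukdyn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  as_leukdyn_config(cfg, source = path)
}

#' @rdname read_config
#' @param cfg a plain named list.
#' @param source provenance note stored in the manifest.
#' @export
as_leukdyn_config <- function(cfg, source = "inline") {
  known <- c("seed", "out_dir", "simulate", "scan", "stimulate",
             "cohort", "fit", "survival")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "leukdyn_out"
  structure(cfg, source = source, class = "leukdyn_config")
}

## model_params from a config block (leukemic a/p/d + variant + couplings)
.config_params <- function(block) {
  need <- c("a_l", "p_l", "d_l", "variant")
  if (!all(need %in% names(block)))
    stop("model block must provide: ", paste(need, collapse = ", "))
  healthy <- default_healthy_params()
  if (!is.null(block$healthy))
    healthy <- lineage_params(block$healthy$a, block$healthy$p, block$healthy$d)
  model_params(lineage_params(block$a_l, block$p_l, block$d_l),
               healthy = healthy,
               k = if (is.null(block$k)) 1e-9 else block$k,
               dbar = if (is.null(block$dbar)) 1e-12 else block$dbar,
               variant = block$variant)
}

#' Write a reproducibility manifest
#'
#' Every pipeline stage writes a `manifest.json` recording the
#' configuration (and its MD5 when it came from a file), the seed and the
#' package/R versions, which is sufficient to reproduce the outputs
#' byte-identically.
#'
#' @param config a `leukdyn_config`.
#' @param dir output directory.
#' @param stage stage name.
#' @export
write_manifest <- function(config, dir, stage) {
  src <- attr(config, "source")
  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_source = src,
    config_md5 = if (!is.null(src) && file.exists(src))
      unname(tools::md5sum(src)) else NA,
    config = unclass(config),
    package_version = as.character(packageVersion("leukdyn")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

.stage_dir <- function(config, stage) {
  dir <- file.path(config$out_dir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

#' Run the trajectory-simulation stage
#'
#' Simulates one parameter set (config block `simulate`: `a_l`, `p_l`,
#' `d_l`, `variant`, `t_end`, optional `lsc_seed` and `protocol`
#' (`t_start`, `duration`)) and writes `trajectory.csv`.
#'
#' @param config a `leukdyn_config`.
#' @return Path of the trajectory CSV, invisibly.
#' @export
run_simulate <- function(config) {
  block <- config$simulate
  if (is.null(block)) stop("config has no `simulate` block")
  pars <- .config_params(block)
  t_end <- if (is.null(block$t_end)) 365 else block$t_end
  init <- healthy_equilibrium(pars)
  init["l1"] <- init["l1"] +
    (if (is.null(block$lsc_seed)) 0 else block$lsc_seed)
  protocol <- if (!is.null(block$protocol))
    stimulation_protocol(block$protocol$t_start,
                         if (is.null(block$protocol$duration)) 30
                         else block$protocol$duration)
  traj <- simulate_model(pars, init = init, t_end = t_end, protocol = protocol)
  dir <- .stage_dir(config, "simulate")
  write_trajectory(traj, file.path(dir, "trajectory.csv"))
  write_manifest(config, dir, "simulate")
  message("simulate: wrote ", file.path(dir, "trajectory.csv"))
  invisible(file.path(dir, "trajectory.csv"))
}

#' Run the expansion-scan stage
#'
#' Config block `scan`: `variant` (or `"both"`), optional `a_min`,
#' `a_max`, `n_grid`, `p_l`, `threshold`. Writes `scan.csv` with one row
#' per (variant, self-renewal) pair.
#'
#' @param config a `leukdyn_config`.
#' @return The scan data frame, invisibly.
#' @export
run_scan <- function(config) {
  block <- if (is.null(config$scan)) list() else config$scan
  variant <- if (is.null(block$variant)) "both" else block$variant
  variants <- if (identical(variant, "both")) c("model1", "model2") else variant
  n_grid <- if (is.null(block$n_grid)) 101L else as.integer(block$n_grid)
  a_min <- if (is.null(block$a_min)) 0.505 else block$a_min
  a_max <- if (is.null(block$a_max)) 1 else block$a_max
  if (n_grid < 1L) stop("scan grid must contain at least one point")
  grid <- seq(a_min, a_max, length.out = n_grid)
  p_l <- if (is.null(block$p_l)) 1 else block$p_l
  thr <- if (is.null(block$threshold)) 0.1 else block$threshold
  out <- do.call(rbind, lapply(variants, function(v) {
    sc <- expansion_scan(v, a_grid = grid, p_l = p_l, threshold = thr)
    data.frame(variant = v, a_l = sc$a_l, days = sc$days)
  }))
  dir <- .stage_dir(config, "scan")
  write.csv(out, file.path(dir, "scan.csv"), row.names = FALSE)
  write_manifest(config, dir, "scan")
  message("scan: wrote ", file.path(dir, "scan.csv"))
  invisible(out)
}

#' Run the cytokine-stimulation stage
#'
#' Config block `stimulate`: the model block plus optional
#' `trigger_mature_fraction`, `duration`, `eval_horizon`. Writes the
#' control and stimulated trajectories and a `summary.json` with the
#' outcome classification and the effective-growth-rate prediction.
#'
#' @param config a `leukdyn_config`.
#' @return The `leukdyn_stim` result, invisibly.
#' @export
run_stimulate <- function(config) {
  block <- config$stimulate
  if (is.null(block)) stop("config has no `stimulate` block")
  pars <- .config_params(block)
  res <- stimulation_experiment(
    pars,
    trigger_mature_fraction = if (is.null(block$trigger_mature_fraction)) 0.5
                              else block$trigger_mature_fraction,
    duration = if (is.null(block$duration)) 30 else block$duration,
    eval_horizon = if (is.null(block$eval_horizon)) 60 else block$eval_horizon)
  dir <- .stage_dir(config, "stimulate")
  if (res$triggered) {
    write_trajectory(res$control, file.path(dir, "control.csv"))
    write_trajectory(res$stimulated, file.path(dir, "stimulated.csv"))
  }
  summary <- list(triggered = res$triggered, t_trigger = res$t_trigger,
                  share_change = res$share_change,
                  burden_change = res$burden_change,
                  classification = res$classification,
                  predicted = predict_stimulation_response(pars))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write_manifest(config, dir, "stimulate")
  message("stimulate: ", res$classification)
  invisible(res)
}

#' Run the synthetic-cohort stage
#'
#' Config block `cohort` is passed to [cohort_config()] (the global seed
#' is used unless the block sets its own). Writes the three cohort CSVs.
#'
#' @param config a `leukdyn_config`.
#' @return The `leukdyn_cohort`, invisibly.
#' @export
run_cohort <- function(config) {
  block <- if (is.null(config$cohort)) list() else config$cohort
  if (is.null(block$seed)) block$seed <- config$seed
  cc <- do.call(cohort_config, block)
  cohort <- generate_cohort(cc)
  dir <- .stage_dir(config, "cohort")
  write_cohort(cohort, dir)
  write_manifest(config, dir, "cohort")
  message("cohort: ", length(cohort), " patients written to ", dir)
  invisible(cohort)
}

#' Run the model-fitting and model-selection stage
#'
#' Fits both model variants to every patient in an observation CSV
#' (config block `fit`: `observations` path, optional `n_starts`,
#' `rmse_tol`) and applies the relative-RMSE selection rule. Writes
#' `fits.csv` (per patient and model: best-fit parameters and RMSE) and
#' `groups.csv` (per patient: compatibility and group label).
#'
#' @param config a `leukdyn_config`.
#' @return The groups data frame, invisibly.
#' @export
run_fit <- function(config) {
  block <- if (is.null(config$fit)) list() else config$fit
  obs_path <- if (!is.null(block$observations)) block$observations
              else file.path(config$out_dir, "cohort", "observations.csv")
  if (!file.exists(obs_path)) stop("observation file not found: ", obs_path)
  obs_list <- read_observations(obs_path)
  n_starts <- if (is.null(block$n_starts)) 32L else as.integer(block$n_starts)
  tol <- if (is.null(block$rmse_tol)) 0.05 else block$rmse_tol

  fits <- list(); groups <- list()
  for (pid in names(obs_list)) {
    obs <- obs_list[[pid]]
    f1 <- fit_model("model1", obs, n_starts = n_starts, seed = config$seed)
    f2 <- fit_model("model2", obs, n_starts = n_starts, seed = config$seed)
    sel <- select_model(f1, f2, tol = tol)
    fits[[pid]] <- do.call(rbind, lapply(list(f1, f2), function(f) {
      lc <- if (f$converged) f$params$leukemic else list(a = NA, p = NA, d = NA)
      data.frame(patient_id = pid, variant = f$variant, rmse = f$rmse,
                 a_l = lc$a, p_l = lc$p, d_l = lc$d,
                 l0 = f$l0, converged = f$converged, n_obs = f$n_obs)
    }))
    groups[[pid]] <- data.frame(
      patient_id = pid,
      compatible_model1 = sel$compatible[["model1"]],
      compatible_model2 = sel$compatible[["model2"]],
      preferred = sel$preferred, group = sel$group)
    message(sprintf("fit %s: rmse1 = %.4g, rmse2 = %.4g -> %s",
                    pid, f1$rmse, f2$rmse, sel$group))
  }
  dir <- .stage_dir(config, "fit")
  write.csv(do.call(rbind, fits), file.path(dir, "fits.csv"), row.names = FALSE)
  groups <- do.call(rbind, groups)
  write.csv(groups, file.path(dir, "groups.csv"), row.names = FALSE)
  write_manifest(config, dir, "fit")
  invisible(groups)
}

#' Run the survival-comparison stage
#'
#' Joins the survival CSV with the fitted group labels (config block
#' `survival`: optional `survival` and `groups` paths) and writes the KM
#' tables and the log-rank result.
#'
#' @param config a `leukdyn_config`.
#' @return The [compare_group_survival()] result, invisibly.
#' @export
run_survival <- function(config) {
  block <- if (is.null(config$survival)) list() else config$survival
  surv_path <- if (!is.null(block$survival)) block$survival
               else file.path(config$out_dir, "cohort", "survival.csv")
  grp_path <- if (!is.null(block$groups)) block$groups
              else file.path(config$out_dir, "fit", "groups.csv")
  for (p in c(surv_path, grp_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  surv <- read.csv(surv_path)
  grp <- read.csv(grp_path)
  df <- merge(surv, grp[, c("patient_id", "group")], by = "patient_id")
  res <- compare_group_survival(
    data.frame(time = df$os_days, event = df$event, group = df$group))
  dir <- .stage_dir(config, "survival")
  km_tab <- do.call(rbind, lapply(names(res$km), function(g)
    cbind(group = g, res$km[[g]]$table)))
  write.csv(km_tab, file.path(dir, "km_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(statistic = res$logrank$statistic, df = res$logrank$df,
         p_value = res$logrank$p_value,
         medians = as.list(res$logrank$medians),
         n = as.list(setNames(as.integer(res$logrank$n),
                              names(res$logrank$n)))),
    file.path(dir, "logrank.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  write_manifest(config, dir, "survival")
  message(sprintf("survival: log-rank chi-square %.3g, p = %.3g",
                  res$logrank$statistic, res$logrank$p_value))
  invisible(res)
}

#' Run the full cohort-to-survival pipeline
#'
#' Chains [run_cohort()], [run_fit()] and [run_survival()] on one
#' configuration: generate a synthetic cohort, classify every patient by
#' the two-model fit, and compare survival between the resulting groups.
#'
#' @param config a `leukdyn_config` (or a path to one).
#' @return The survival-comparison result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "leukdyn_config"))
  run_cohort(config)
  run_fit(config)
  run_survival(config)
}
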